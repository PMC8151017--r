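#' Occupied cells of a feature group
#'
#' Every distinct observed code tuple of the group's features becomes one
#' occupied cell (a k-dimensional hypercube); unobserved tuples do not
#' appear. Occupied cells are the categories a feature group contributes to
#' a contingency-kD-lattice.
#'
#' @param coded a \linkS4class{CodedMatrix}.
#' @param features feature names or indices (nonempty).
#' @return a list with `features`, `dtypes`, `codes` (L x k integer matrix,
#'   one row per cell, ordered lexicographically), `counts` (per-cell data
#'   counts), `labels`, and `assign` (per data row, the index of its cell).
#' @export
buildGroupCells <- function(coded, features) {
  .assert(length(features) >= 1L, "feature group must be nonempty")
  idx <- if (is.character(features)) match(features, coded@schema@name)
         else as.integer(features)
  .assert(!anyNA(idx), "unknown feature id")
  codes <- coded@codes[, idx, drop = FALSE]
  key <- apply(codes, 1L, paste, collapse = "\r")
  ord <- do.call(order, as.data.frame(codes))
  uniqKey <- key[ord][!duplicated(key[ord])]
  cellCodes <- codes[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  assign <- match(key, uniqKey)
  counts <- tabulate(assign, nbins = length(uniqKey))
  list(features = coded@schema@name[idx],
       dtypes = coded@schema@dtype[idx],
       codes = cellCodes,
       counts = as.integer(counts),
       labels = apply(cellCodes, 1L, paste, collapse = "."),
       assign = assign)
}

#' Build a contingency-kD-lattice from two feature groups
#'
#' Frames the occupied cells of group A along the row axis and those of
#' group B along the column axis, and counts subjects in each
#' (row-cell, column-cell) pair. Row sums equal the row cells' own counts,
#' column sums the column cells', and the total is N.
#'
#' @param coded a \linkS4class{CodedMatrix}.
#' @param groupA,groupB disjoint nonempty feature sets.
#' @return a \linkS4class{ContingencyLattice}.
#' @export
buildLattice <- function(coded, groupA, groupB) {
  nmA <- if (is.character(groupA)) groupA else coded@schema@name[groupA]
  nmB <- if (is.character(groupB)) groupB else coded@schema@name[groupB]
  .assert(length(intersect(nmA, nmB)) == 0L, "feature groups must be disjoint")
  rc <- buildGroupCells(coded, nmA)
  cc <- buildGroupCells(coded, nmB)
  counts <- matrix(0, length(rc$counts), length(cc$counts),
                   dimnames = list(rc$labels, cc$labels))
  tab <- table(factor(rc$assign, levels = seq_along(rc$counts)),
               factor(cc$assign, levels = seq_along(cc$counts)))
  counts[] <- as.numeric(tab)
  new("ContingencyLattice", counts = counts,
      rowCells = rc[c("features", "dtypes", "codes", "counts", "labels")],
      colCells = cc[c("features", "dtypes", "codes", "counts", "labels")],
      rowAssign = rc$assign, colAssign = cc$assign,
      rowTree = NULL, colTree = NULL, colOrder = integer(0))
}

#' Grid-neighborhood adjacency matrix of occupied cells
#'
#' Treats each occupied cell of a quantitative feature group as a point on
#' the integer bin grid. In `edge` mode two cells are neighbors when they
#' share a (k-1)-dimensional face (Manhattan distance 1, up to 2k
#' neighbors); in `corner` mode when they share at least a corner point
#' (Chebyshev distance 1, up to 3^k - 1 neighbors). Corner mode suits
#' sparsely occupied tables; edge mode suits dense ones.
#'
#' @param cells occupied cells from [buildGroupCells()] (quantitative
#'   features only).
#' @param mode `"corner"` (default) or `"edge"`.
#' @return a binary symmetric L x L matrix with zero diagonal and a
#'   `"neighborMode"` attribute.
#' @export
adjacencyMatrix <- function(cells, mode = c("corner", "edge")) {
  mode <- match.arg(mode)
  .assert(all(.isQuantitative(cells$dtypes)),
          "adjacency requires quantitative features (integer grid)")
  codes <- cells$codes
  L <- nrow(codes)
  maxd <- matrix(0, L, L)
  sumd <- matrix(0, L, L)
  for (k in seq_len(ncol(codes))) {
    d <- abs(outer(codes[, k], codes[, k], "-"))
    maxd <- pmax(maxd, d)
    sumd <- sumd + d
  }
  adj <- if (mode == "edge") (sumd == 1) * 1 else (maxd == 1) * 1
  dimnames(adj) <- list(cells$labels, cells$labels)
  attr(adj, "neighborMode") <- mode
  adj
}

#' HC-tree from a binary adjacency matrix
#'
#' Clusters occupied cells on the graph defined by the adjacency matrix,
#' using geodesic (shortest-path) distances so multiscale neighborhoods are
#' preserved; disconnected pairs are assigned the sentinel distance L + 1,
#' which makes connected components merge before any cross-component join.
#'
#' @param adj binary symmetric adjacency matrix from [adjacencyMatrix()].
#' @param linkage hclust linkage, default `"average"`.
#' @return an `hclust` (or a single-leaf stand-in when L = 1).
#' @export
hcTreeFromAdjacency <- function(adj, linkage = "average") {
  L <- nrow(adj)
  if (L == 1L) return(.leafTree(rownames(adj) %||% "1"))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(g)
  d[is.infinite(d)] <- L + 1
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' HC-tree over lattice axis items as categorical populations
#'
#' Each row (or column) of the lattice is read as a vector of categorical
#' counts from one population; normalising by its total gives a proportion
#' vector, and the axis items are clustered by distances between these
#' proportion vectors (the extreme-K categorical-sample device, used for
#' nominal axes that carry no grid geometry).
#'
#' @param lattice a \linkS4class{ContingencyLattice} or
#'   \linkS4class{ContingencyTable}.
#' @param axis `"rows"` or `"cols"`.
#' @param distance `"hellinger"` (default; bounded in \[0, 1\]),
#'   `"euclidean"`, or `"tv"` (total variation).
#' @param linkage hclust linkage, default `"average"`.
#' @return an `hclust` (or single-leaf stand-in).
#' @export
hcTreeExtremeK <- function(lattice, axis = c("rows", "cols"),
                           distance = c("hellinger", "euclidean", "tv"),
                           linkage = "average") {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  counts <- if (is(lattice, "ContingencyLattice") ||
                is(lattice, "ContingencyTable")) tableCounts(lattice)
            else lattice
  if (axis == "cols") counts <- t(counts)
  tot <- rowSums(counts)
  .assert(all(tot > 0), "axis items with zero total must be excluded")
  P <- counts / tot
  if (nrow(P) == 1L) return(.leafTree(rownames(counts) %||% "1"))
  d <- switch(distance,
    hellinger = stats::dist(sqrt(P)) / sqrt(2),
    euclidean = stats::dist(P),
    tv = stats::dist(P, method = "manhattan") / 2)
  stats::hclust(d, method = linkage)
}

#' Bivariate column order for a mixed qualitative/quantitative cell set
#'
#' Orders occupied bivariate cells lexicographically: qualitative category
#' first (in the given domain order), quantitative bin index second — the
#' arrangement a1, a2, ..., b1, b2, ... used for mixed-type lattice axes.
#'
#' @param qualCategories ordered label vector of the qualitative feature.
#' @param quantBins number of quantitative bins (bins are ordered 1..m).
#' @param cells occupied cells with `codes` columns (category index,
#'   bin index) — as built by [buildGroupCells()] on (qualitative,
#'   quantitative) features.
#' @return integer permutation of the cell indices.
#' @export
bivariateOrder <- function(qualCategories, quantBins, cells) {
  codes <- cells$codes
  .assert(ncol(codes) == 2L, "bivariate cells expected")
  .assert(all(codes[, 1L] >= 1L & codes[, 1L] <= length(qualCategories)),
          "unknown category code")
  .assert(all(codes[, 2L] >= 1L & codes[, 2L] <= quantBins),
          "unknown bin code")
  order(codes[, 1L], codes[, 2L])
}

#' Attach axis trees / explicit orders to a lattice
#'
#' @param lattice a \linkS4class{ContingencyLattice}.
#' @param rowTree,colTree `hclust` objects over the axis cells (or `NULL`).
#' @param colOrder explicit integer column order (for mixed-type columns).
#' @return the updated lattice.
#' @export
attachAxisTrees <- function(lattice, rowTree = NULL, colTree = NULL,
                            colOrder = integer(0)) {
  lattice@rowTree <- rowTree
  lattice@colTree <- colTree
  lattice@colOrder <- as.integer(colOrder)
  lattice
}

#' Permute a lattice into heatmap arrangement
#'
#' Reindexes rows and columns by HC-tree leaf orders (or explicit
#' permutations); every count, both axes' cell sets, and N are preserved.
#'
#' @param lattice a \linkS4class{ContingencyLattice}.
#' @param rowArrangement an `hclust`, an integer permutation, or `NULL`
#'   (use the attached row tree, else identity).
#' @param colArrangement likewise for columns (explicit orders serve
#'   mixed-type axes).
#' @return the permuted \linkS4class{ContingencyLattice} (axis trees are
#'   dropped: their leaf indices refer to the original arrangement).
#' @export
permuteHeatmap <- function(lattice, rowArrangement = NULL,
                           colArrangement = NULL) {
  asOrder <- function(arr, n, attached) {
    if (is.null(arr)) arr <- attached
    if (is.null(arr)) return(seq_len(n))
    if (inherits(arr, "hclust") || .isLeafTree(arr)) return(.treeOrder(arr))
    arr <- as.integer(arr)
    .assert(length(arr) == n && all(sort(arr) == seq_len(n)),
            "arrangement must cover all %d axis items", n)
    arr
  }
  ro <- asOrder(rowArrangement, nrow(lattice@counts), lattice@rowTree)
  co <- asOrder(colArrangement, ncol(lattice@counts),
                if (length(lattice@colOrder)) lattice@colOrder
                else lattice@colTree)
  sub <- function(cells, o) {
    cells$codes <- cells$codes[o, , drop = FALSE]
    cells$counts <- cells$counts[o]
    cells$labels <- cells$labels[o]
    cells
  }
  new("ContingencyLattice",
      counts = lattice@counts[ro, co, drop = FALSE],
      rowCells = sub(lattice@rowCells, ro),
      colCells = sub(lattice@colCells, co),
      rowAssign = match(lattice@rowAssign, ro),
      colAssign = match(lattice@colAssign, co),
      rowTree = NULL, colTree = NULL, colOrder = integer(0))
}

#' Partition a lattice into blocks
#'
#' Cuts the attached row tree into `rowCut` branches and groups columns
#' either by the qualitative feature's category (`"per_category"`, the
#' zone-column style) or by cutting the attached column tree
#' (`list(tree_cut = k)`). Each (row branch x column group) rectangle with
#' at least one occupied cell becomes a block; blocks partition all occupied
#' cells and all data rows, and report per-feature bounding intervals of
#' their member hypercubes.
#'
#' @param lattice a \linkS4class{ContingencyLattice} with the needed
#'   tree(s) attached via [attachAxisTrees()].
#' @param rowCut number of row-tree branches.
#' @param colGrouping `"per_category"` or `list(tree_cut = k)`.
#' @param coded the \linkS4class{CodedMatrix} the lattice came from (used
#'   for hypercube bounds).
#' @return list of blocks: each has `id`, `rowCells`, `colCells` (indices),
#'   `rows` (data row indices), `size`, and `bounds` (per feature: numeric
#'   `c(lo, hi)` or the label set).
#' @export
partitionBlocks <- function(lattice, rowCut, colGrouping = "per_category",
                            coded = NULL) {
  .assert(!is.null(lattice@rowTree), "row tree not attached")
  rowBranch <- .treeCut(lattice@rowTree, rowCut)
  nc <- ncol(lattice@counts)
  if (identical(colGrouping, "per_category")) {
    catPos <- which(!.isQuantitative(lattice@colCells$dtypes))
    .assert(length(catPos) >= 1L,
            "per_category grouping needs a categorical column feature")
    colGroup <- lattice@colCells$codes[, catPos[1L]]
  } else if (is.list(colGrouping) && !is.null(colGrouping$tree_cut)) {
    .assert(!is.null(lattice@colTree), "column tree not attached")
    colGroup <- .treeCut(lattice@colTree, colGrouping$tree_cut)
  } else stop("colGrouping must be 'per_category' or list(tree_cut = k)")
  blocks <- list()
  id <- 0L
  for (rb in sort(unique(rowBranch))) for (cg in sort(unique(colGroup))) {
    rIdx <- which(rowBranch == rb)
    cIdx <- which(colGroup == cg)
    sz <- sum(lattice@counts[rIdx, cIdx, drop = FALSE])
    if (sz == 0) next
    id <- id + 1L
    rows <- which(lattice@rowAssign %in% rIdx & lattice@colAssign %in% cIdx)
    blocks[[id]] <- list(
      id = id, rowBranch = rb, colGroup = cg,
      rowCells = rIdx, colCells = cIdx, rows = rows, size = as.integer(sz),
      bounds = if (is.null(coded)) NULL
               else .blockBounds(lattice, rIdx, cIdx, coded))
  }
  blocks
}

# Per-feature bounding intervals (or label sets) of a block's member
# hypercubes: the union over member cells, feature by feature.
.blockBounds <- function(lattice, rIdx, cIdx, coded) {
  boundsFor <- function(cells, idx) {
    out <- list()
    for (k in seq_along(cells$features)) {
      nm <- cells$features[k]
      coder <- coded@coders[[nm]]
      cd <- cells$codes[idx, k]
      if (is(coder, "GappedHistogram"))
        out[[nm]] <- c(min(coder@left[cd]), max(coder@right[cd]))
      else out[[nm]] <- unique(coder[cd])
    }
    out
  }
  c(boundsFor(lattice@rowCells, rIdx), boundsFor(lattice@colCells, cIdx))
}

#' Export a lattice as CSV counts plus a JSON cell manifest
#'
#' @param lattice a \linkS4class{ContingencyLattice}.
#' @param countsPath CSV output for the count matrix.
#' @param cellsPath JSON output for the cell definitions.
#' @export
writeLattice <- function(lattice, countsPath, cellsPath) {
  utils::write.csv(lattice@counts, countsPath, row.names = TRUE)
  cellJson <- function(cells) list(
    features = cells$features, dtypes = cells$dtypes,
    codes = unname(apply(cells$codes, 1L, as.list)),
    counts = cells$counts, labels = cells$labels)
  jsonlite::write_json(list(rows = cellJson(lattice@rowCells),
                            cols = cellJson(lattice@colCells)),
                       cellsPath, auto_unbox = TRUE, pretty = TRUE)
  invisible(countsPath)
}
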