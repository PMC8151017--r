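#' Contingency table of two coded columns
#'
#' Cross-tabulates two equal-length integer code vectors over the full
#' `1..nx` by `1..ny` grid, so empty bins keep their axis position.
#'
#' @param codesX,codesY integer code vectors of equal length.
#' @param nx,ny numbers of categories on each axis (default: observed max).
#' @param labelsX,labelsY optional axis labels.
#' @return a \linkS4class{ContingencyTable}.
#' @examples
#' contingencyTable(c(1, 1, 2, 2), c(1, 2, 1, 2))
#' @export
contingencyTable <- function(codesX, codesY, nx = max(codesX),
                             ny = max(codesY), labelsX = NULL,
                             labelsY = NULL) {
  .assert(length(codesX) == length(codesY), "code vectors differ in length")
  .assert(length(codesX) >= 1L, "need at least one observation")
  tab <- table(factor(codesX, levels = seq_len(nx)),
               factor(codesY, levels = seq_len(ny)))
  counts <- matrix(as.numeric(tab), nx, ny)
  dimnames(counts) <- list(labelsX %||% as.character(seq_len(nx)),
                           labelsY %||% as.character(seq_len(ny)))
  new("ContingencyTable", counts = counts)
}

#' Contingency table of two features of a coded matrix
#'
#' @param coded a \linkS4class{CodedMatrix}.
#' @param featureX,featureY feature names or indices.
#' @return a \linkS4class{ContingencyTable} with label axes following the
#'   coder order.
#' @export
featurePairTable <- function(coded, featureX, featureY) {
  kx <- if (is.character(featureX)) match(featureX, coded@schema@name) else featureX
  ky <- if (is.character(featureY)) match(featureY, coded@schema@name) else featureY
  .assert(!is.na(kx) && !is.na(ky), "unknown feature")
  labs <- function(k) {
    co <- coded@coders[[k]]
    if (is.character(co)) co else as.character(seq_len(nCategories(co)))
  }
  contingencyTable(coded@codes[, kx], coded@codes[, ky],
                   nx = nCategories(coded@coders[[kx]]),
                   ny = nCategories(coded@coders[[ky]]),
                   labelsX = labs(kx), labelsY = labs(ky))
}

#' Shannon entropy of a count vector
#'
#' Natural-log Shannon entropy of the distribution proportional to `counts`,
#' with the convention 0 log 0 = 0.
#'
#' @param counts non-negative numeric vector with positive sum.
#' @return entropy in nats, in `[0, log(#positive entries)]`.
#' @examples
#' shannonEntropy(c(5, 5))   # log(2)
#' @export
shannonEntropy <- function(counts) {
  .assert(all(counts >= 0), "negative counts")
  .assert(sum(counts) > 0, "all-zero count vector")
  .entropyNats(counts)
}

#' Directional conditional entropy profile of a contingency table
#'
#' For target axis X and conditioning axis X', computes the marginal Shannon
#' entropy H\[X\], the per-category conditional entropies H\[X | X' = b\],
#' their weighted sum H\[X | X'\], and the re-scaled directional conditional
#' entropy E\[X | X'\] = H\[X | X'\] / H\[X\]. Small values mean the
#' conditioning feature constrains (predicts) the target. A constant target
#' (H\[X\] = 0) is flagged degenerate and its ratio set to 1: there is no
#' uncertainty to explain away.
#'
#' @param table a \linkS4class{ContingencyTable}.
#' @param target `"rows"` to condition on columns (E\[row | col\]) or
#'   `"cols"` to condition on rows.
#' @return a list with `overallRatio`, `marginalEntropy`,
#'   `conditionalEntropy`, `degenerate`, and a `perCategory` data.frame
#'   (category, weight, condEntropy, ratio).
#' @export
conditionalEntropyProfile <- function(table, target = c("rows", "cols")) {
  target <- match.arg(target)
  counts <- table@counts
  if (target == "cols") counts <- t(counts)
  n <- sum(counts)
  .assert(n > 0, "empty table")
  margin <- rowSums(counts)                  # target marginal
  condW <- colSums(counts)                   # conditioning marginal
  H <- .entropyNats(margin)
  cat <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
  condH <- vapply(seq_len(ncol(counts)), function(j) {
    cj <- counts[, j]
    if (sum(cj) == 0) 0 else .entropyNats(cj)
  }, numeric(1))
  w <- condW / n
  overallH <- sum(w * condH)
  degenerate <- H == 0
  per <- data.frame(category = cat, weight = w, condEntropy = condH,
                    ratio = if (degenerate) rep(1, length(condH)) else condH / H,
                    row.names = NULL)
  per$ratio[w == 0] <- NA_real_              # unobserved conditioning event
  list(overallRatio = if (degenerate) 1 else overallH / H,
       marginalEntropy = H, conditionalEntropy = overallH,
       degenerate = degenerate, perCategory = per)
}

#' Mutual conditional entropy of a contingency table
#'
#' The simple average (or minimum) of the two directional re-scaled
#' conditional entropies E\[X | X'\] and E\[X' | X\]. 0 indicates
#' deterministic association, 1 independence; unlike mutual information the
#' re-scaling gives the value 1 a fixed meaning. Degenerate marginals give
#' 1 by convention (with a warning).
#'
#' @param table a \linkS4class{ContingencyTable}.
#' @param variant `"average"` (default) or `"min"`.
#' @return a number in `[0, 1]`.
#' @export
mutualConditionalEntropy <- function(table, variant = c("average", "min")) {
  variant <- match.arg(variant)
  pr <- conditionalEntropyProfile(table, "rows")
  pc <- conditionalEntropyProfile(table, "cols")
  if (pr$degenerate || pc$degenerate) {
    warning("degenerate marginal: MCE set to 1")
    return(1)
  }
  r <- c(pr$overallRatio, pc$overallRatio)
  if (variant == "average") mean(r) else min(r)
}

#' Mutual information of a contingency table
#'
#' I(X : X') = H(X) + H(X') - H(X, X') in nats. Provided as the classical
#' contrast to the mutual conditional entropy: it is an unscaled difference,
#' with no fixed reference value for independence strength.
#'
#' @param table a \linkS4class{ContingencyTable}.
#' @return mutual information in nats, `>= 0`.
#' @export
mutualInformation <- function(table) {
  counts <- table@counts
  .assert(sum(counts) > 0, "empty table")
  .entropyNats(rowSums(counts)) + .entropyNats(colSums(counts)) -
    .entropyNats(as.vector(counts))
}

#' Mutual conditional entropy matrix of a coded data matrix
#'
#' Computes MCE for every feature pair, giving the K x K road map of
#' pairwise associations that guides lattice construction.
#'
#' @param coded a \linkS4class{CodedMatrix} with K >= 2 features.
#' @param variant `"average"` or `"min"`.
#' @return an \linkS4class{MCEMatrix}.
#' @export
mceMatrix <- function(coded, variant = c("average", "min")) {
  variant <- match.arg(variant)
  K <- ncol(coded@codes)
  .assert(K >= 2L, "need at least two features")
  nm <- coded@schema@name
  degen <- vapply(seq_len(K), function(k)
    length(unique(coded@codes[, k])) < 2L, logical(1))
  e <- matrix(0, K, K, dimnames = list(nm, nm))
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    if (degen[i] || degen[j]) {
      e[i, j] <- e[j, i] <- 1
    } else {
      tab <- featurePairTable(coded, i, j)
      e[i, j] <- e[j, i] <- mutualConditionalEntropy(tab, variant)
    }
  }
  if (any(degen))
    warning("constant feature(s): ", paste(nm[degen], collapse = ", "),
            "; their MCE entries set to 1")
  new("MCEMatrix", entries = e, variant = variant, degenerate = degen)
}

#' Heatmap permutation of an MCE matrix
#'
#' Treats the MCE matrix as a distance matrix, builds a binary HC-tree
#' (single linkage by default), and permutes rows and columns by the
#' arrangement of tree leaves so synergistic feature-groups appear as
#' diagonal blocks.
#'
#' @param mce an \linkS4class{MCEMatrix}.
#' @param linkage `"single"` (default), `"average"` or `"complete"`.
#' @return a list with `tree` (an `hclust`), `order` (leaf order), and
#'   `permuted` (the reindexed \linkS4class{MCEMatrix}).
#' @export
mceHeatmap <- function(mce, linkage = c("single", "average", "complete")) {
  linkage <- match.arg(linkage)
  e <- mce@entries
  tree <- stats::hclust(stats::as.dist(e), method = linkage)
  ord <- tree$order
  perm <- new("MCEMatrix", entries = e[ord, ord, drop = FALSE],
              variant = mce@variant, degenerate = mce@degenerate[ord])
  list(tree = tree, order = ord, permuted = perm)
}

#' Directional conditional entropy ratios for all ordered pairs
#'
#' @param coded a \linkS4class{CodedMatrix}.
#' @return data.frame with columns `target`, `conditioning`, `ratio`: one
#'   row per ordered feature pair, `ratio` = E\[target | conditioning\].
#' @export
directionalRatios <- function(coded) {
  K <- ncol(coded@codes)
  nm <- coded@schema@name
  grid <- expand.grid(target = seq_len(K), conditioning = seq_len(K))
  grid <- grid[grid$target != grid$conditioning, ]
  ratio <- mapply(function(t, c) {
    tab <- featurePairTable(coded, t, c)
    conditionalEntropyProfile(tab, "rows")$overallRatio
  }, grid$target, grid$conditioning)
  data.frame(target = nm[grid$target], conditioning = nm[grid$conditioning],
             ratio = as.numeric(ratio), row.names = NULL)
}

#' Directed association network from entropy ratios
#'
#' Classifies each ordered feature pair by its directional conditional
#' entropy ratio: a thick edge for strong direction-specific association
#' (ratio below the lower cut), a thin edge for moderate association (ratio
#' in `[lower, upper)`), no edge otherwise. The edge points from the
#' conditioning feature to the target it predicts.
#'
#' @param profiles data.frame from [directionalRatios()].
#' @param thresholds two increasing cut levels, default `c(0.9, 0.95)`.
#' @return data.frame with `from`, `to`, `ratio`, `class` (`thick`/`thin`).
#' @export
directedNetwork <- function(profiles, thresholds = c(0.9, 0.95)) {
  .assert(length(thresholds) == 2L && thresholds[1] < thresholds[2],
          "thresholds must be two increasing cut levels")
  cls <- ifelse(profiles$ratio < thresholds[1], "thick",
                ifelse(profiles$ratio < thresholds[2], "thin", NA))
  keep <- !is.na(cls)
  data.frame(from = profiles$conditioning[keep], to = profiles$target[keep],
             ratio = profiles$ratio[keep], class = cls[keep],
             row.names = NULL)
}

#' Export an MCE matrix as CSV
#' @param mce an \linkS4class{MCEMatrix}.
#' @param path output path.
#' @export
writeMCE <- function(mce, path) {
  utils::write.csv(mce@entries, path, row.names = TRUE)
  invisible(path)
}

#' Export an HC-tree as Newick
#'
#' Converts an `hclust` to a phylogeny (merge heights become branch lengths)
#' and writes Newick text.
#'
#' @param tree an `hclust`.
#' @param path output path.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
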