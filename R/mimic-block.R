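# Fine-scale mimicking of one heatmap block: PCA of the member point cloud,
# kernel-smoothed resampling of each principal component, inversion back to
# feature space, and filtering by the block's member hypercubes.

#' Principal component analysis of a block's member points
#'
#' Eigen-decomposition of the covariance of the m x d matrix of member
#' points (centered at the block mean, mean restored on inversion).
#' Eigenvalues are descending; the eigenvector matrix V stacks transposed
#' eigenvectors as rows, so scores are `eps_i = V (C_i - center)` and the
#' round trip `C_i = t(V) eps_i + center` is exact.
#'
#' @param block a block from [partitionBlocks()].
#' @param data the \linkS4class{CedaMatrix} the block's `rows` index into.
#' @param features continuous feature names to use (default: all numeric
#'   features named in the block's bounds).
#' @return list with `center`, `values` (eigenvalues), `vectors` (V, rows =
#'   transposed eigenvectors), `scores` (m x d), `features`, `m`.
#' @export
blockPCA <- function(block, data, features = NULL) {
  if (is.null(features))
    features <- names(block$bounds)[vapply(block$bounds, is.numeric, logical(1))]
  X <- as.matrix(data@values[block$rows, features, drop = FALSE])
  .assert(nrow(X) >= 2L,
          "block has fewer than 2 member points; keep it intact")
  d <- ncol(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  S <- stats::cov(X)
  if (all(abs(S) < 1e-300)) {
    V <- diag(d)
    vals <- rep(0, d)
  } else {
    eg <- eigen(S, symmetric = TRUE)
    V <- t(.fixSigns(eg$vectors))
    vals <- pmax(eg$values, 0)
  }
  dimnames(V) <- list(NULL, features)
  list(center = center, values = vals, vectors = V,
       scores = Xc %*% t(V), features = features, m = nrow(X))
}

# Kernel-smoothed resampler for one principal component's scores:
# Gaussian kernel, Silverman's rule bandwidth (classical smoothed
# bootstrap draw: resample a score, add kernel noise).
.sampleComponent <- function(scores, n, bandwidthRule = "nrd0") {
  if (stats::sd(scores) == 0) return(rep(scores[1L], n))
  bw <- switch(bandwidthRule,
               nrd0 = stats::bw.nrd0(scores),
               nrd = stats::bw.nrd(scores),
               stop("unknown bandwidth rule"))
  sample(scores, n, replace = TRUE) + stats::rnorm(n, 0, bw)
}

# Are points (n x d) inside at least one member hypercube?
# cubes: list(lo, hi): matrices (#cubes x d), half-open [lo, hi) with the
# histogram's last-bin closure already absorbed into hi.
.insideUnion <- function(points, cubes) {
  n <- nrow(points)
  ok <- rep(FALSE, n)
  for (c in seq_len(nrow(cubes$lo))) {
    inC <- rep(TRUE, n)
    for (k in seq_len(ncol(points)))
      inC <- inC & points[, k] >= cubes$lo[c, k] & points[, k] < cubes$hi[c, k]
    ok <- ok | inC
  }
  ok
}

# Member-cell hypercubes of a block, restricted to continuous features.
.blockCubes <- function(lattice, block, coded, features) {
  occ <- which(lattice@counts[block$rowCells, block$colCells,
                              drop = FALSE] > 0, arr.ind = TRUE)
  nC <- nrow(occ)
  lo <- matrix(NA_real_, nC, length(features),
               dimnames = list(NULL, features))
  hi <- lo
  codeOf <- function(cellSet, cellIdx, nm) {
    k <- match(nm, cellSet$features)
    if (is.na(k)) return(NA_integer_)
    cellSet$codes[cellIdx, k]
  }
  for (i in seq_len(nC)) {
    rI <- block$rowCells[occ[i, 1L]]
    cI <- block$colCells[occ[i, 2L]]
    for (nm in features) {
      cd <- codeOf(lattice@rowCells, rI, nm)
      if (is.na(cd)) cd <- codeOf(lattice@colCells, cI, nm)
      coder <- coded@coders[[nm]]
      lo[i, nm] <- coder@left[cd]
      hi[i, nm] <- coder@right[cd]
    }
  }
  list(lo = lo, hi = hi)
}

#' Mimic the continuous points of one block
#'
#' Draws each principal component independently from its kernel-smoothed
#' score distribution, inverts to feature space, and keeps only candidates
#' lying inside the union of the block's member hypercubes (no per-cell
#' quota is enforced: the boundary constraint filters, it does not
#' re-stratify).
#'
#' @param pca output of [blockPCA()].
#' @param cubes member hypercubes (`list(lo, hi)` matrices) as stored on
#'   the block by the mimicking drivers, or built via the lattice.
#' @param B requested number of accepted points.
#' @param bandwidthRule `"nrd0"` (Silverman, default) or `"nrd"`.
#' @param seed integer seed.
#' @param maxAttempts cap on total candidate draws.
#' @return a B x d matrix of accepted points (fewer if the cap is reached,
#'   with a warning), with an `"attempts"` attribute.
#' @export
mimicBlock <- function(pca, cubes, B, bandwidthRule = "nrd0", seed = 1L,
                       maxAttempts = 100000L) {
  set.seed(seed)
  d <- length(pca$center)
  accepted <- matrix(numeric(0), 0L, d, dimnames = list(NULL, pca$features))
  attempts <- 0L
  batch <- max(B, 64L)
  while (nrow(accepted) < B && attempts < maxAttempts) {
    nDraw <- min(batch, maxAttempts - attempts)
    eps <- vapply(seq_len(d), function(h)
      .sampleComponent(pca$scores[, h], nDraw, bandwidthRule),
      numeric(nDraw))
    if (nDraw == 1L) eps <- matrix(eps, 1L, d)
    cand <- eps %*% pca$vectors +
      matrix(pca$center, nDraw, d, byrow = TRUE)
    keep <- .insideUnion(cand, cubes)
    accepted <- rbind(accepted, cand[keep, , drop = FALSE])
    attempts <- attempts + nDraw
  }
  if (nrow(accepted) < B)
    warning(sprintf("block mimicking: only %d of %d accepted in %d attempts",
                    nrow(accepted), B, attempts))
  out <- accepted[seq_len(min(B, nrow(accepted))), , drop = FALSE]
  attr(out, "attempts") <- attempts
  out
}
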