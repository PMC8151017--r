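# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Shannon entropy of a count (or probability) vector, natural log.
# 0 * log 0 := 0.
.entropyNats <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("all-zero count vector has no entropy")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

# Deterministic sign convention for eigenvectors: first element of largest
# magnitude is made positive, ties broken by earliest index.
.fixSigns <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# Derive a 32-bit child seed from a base seed and an index, without
# consuming the caller's RNG stream.
.childSeed <- function(seed, index) {
  (seed * 48271 + index * 1999) %% 2147483647L
}

# A leaf-only stand-in used where hclust needs >= 2 items.
.leafTree <- function(label) {
  structure(list(labels = as.character(label)), class = "cedaLeafTree")
}

.isLeafTree <- function(x) inherits(x, "cedaLeafTree")

# Leaf order of an hclust (or leaf stand-in) as integer indices.
.treeOrder <- function(tree) {
  if (.isLeafTree(tree)) return(1L)
  tree$order
}

# Cut a tree into k groups; handles the single-leaf stand-in.
.treeCut <- function(tree, k) {
  if (.isLeafTree(tree)) {
    .assert(k == 1L, "cannot cut a single-leaf tree into %d groups", k)
    return(stats::setNames(1L, tree$labels))
  }
  n <- length(tree$labels %||% tree$order)
  .assert(k >= 1L && k <= n, "cut into %d groups infeasible for %d leaves", k, n)
  stats::cutree(tree, k = k)
}
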