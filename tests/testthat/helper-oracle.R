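# Independent brute-force entropy oracles: direct loops over the defining
# sums, kept deliberately separate from the package's vectorised
# implementations. `base` lets base-invariance be probed.

oracleEntropy <- function(counts, base = exp(1)) {
  s <- sum(counts)
  h <- 0
  for (c in counts) if (c > 0) h <- h - (c / s) * log(c / s, base = base)
  h
}

# Directional profile with target on rows, conditioning on columns.
oracleProfile <- function(counts, base = exp(1)) {
  n <- sum(counts)
  H <- oracleEntropy(rowSums(counts), base)
  cond <- 0
  for (j in seq_len(ncol(counts))) {
    cj <- counts[, j]
    if (sum(cj) == 0) next
    cond <- cond + sum(cj) / n * oracleEntropy(cj, base)
  }
  list(H = H, cond = cond, ratio = if (H == 0) 1 else cond / H)
}

oracleMCE <- function(counts, variant = "average", base = exp(1)) {
  r1 <- oracleProfile(counts, base)$ratio
  r2 <- oracleProfile(t(counts), base)$ratio
  if (variant == "average") (r1 + r2) / 2 else min(r1, r2)
}

oracleMI <- function(counts) {
  n <- sum(counts)
  mi <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    nij <- counts[i, j]
    if (nij == 0) next
    mi <- mi + nij / n * log(nij / n / (sum(counts[i, ]) / n *
                                          sum(counts[, j]) / n))
  }
  mi
}

# Random tables with non-degenerate marginals, up to maxDim x maxDim.
randomTable <- function(maxDim = 6L) {
  repeat {
    nr <- sample(2:maxDim, 1L)
    nc <- sample(2:maxDim, 1L)
    counts <- matrix(stats::rpois(nr * nc, lambda = 3), nr, nc)
    if (sum(counts) > 0 && sum(rowSums(counts) > 0) >= 2L &&
        sum(colSums(counts) > 0) >= 2L)
      return(counts)
  }
}

asTable <- function(counts) new("ContingencyTable", counts = counts)
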