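# In-code fixtures shared across test files.

# Uniform m-bin histogram coder on [0, m).
makeHist <- function(m, counts = rep(1L, m)) {
  new("GappedHistogram", left = as.numeric(seq_len(m) - 1L),
      right = as.numeric(seq_len(m)), counts = as.integer(counts),
      gapAfter = rep(FALSE, m))
}

# CodedMatrix straight from a code matrix; quantitative columns get uniform
# grid histograms, categorical ones letter labels.
makeCoded <- function(codes, dtypes = rep("discrete", ncol(codes))) {
  codes <- matrix(as.integer(codes), nrow(codes), ncol(codes))
  K <- ncol(codes)
  nms <- paste0("f", seq_len(K))
  colnames(codes) <- nms
  coders <- lapply(seq_len(K), function(k) {
    m <- max(codes[, k])
    if (dtypes[k] %in% c("continuous", "discrete")) makeHist(m)
    else letters[seq_len(m)]
  })
  names(coders) <- nms
  ord <- lapply(coders[dtypes %in% c("categorical_nominal",
                                     "categorical_ordinal")], identity)
  schema <- FeatureSchema(nms, dtypes, ord)
  new("CodedMatrix", codes = codes, coders = coders, schema = schema)
}

# Two planted clusters in a 4-feature coded matrix: rows live either in the
# low corner (codes 1-2) or the high corner (codes 5-6) of both feature
# pairs, giving a lattice with two dense diagonal blocks.
plantedTwoClusterCoded <- function(n = 200L, seed = 7L) {
  set.seed(seed)
  half <- n %/% 2L
  lowHigh <- function(isLow) ifelse(isLow, sample(1:2, n, TRUE),
                                    sample(5:6, n, TRUE))
  isLow <- rep(c(TRUE, FALSE), c(half, n - half))
  codes <- cbind(lowHigh(isLow), lowHigh(isLow), lowHigh(isLow),
                 lowHigh(isLow))
  makeCoded(codes, rep("continuous", 4L))
}

# A small random mixed-type CedaMatrix for round-trip/property tests.
randomCedaMatrix <- function(n = 20L, seed = 1L) {
  set.seed(seed)
  df <- data.frame(
    x = round(stats::rnorm(n), 6),
    d = sample(1:5, n, TRUE),
    g = sample(c("a", "b", ""), n, TRUE),
    o = sample(c("low", "mid", "high"), n, TRUE),
    stringsAsFactors = FALSE)
  schema <- FeatureSchema(
    c("x", "d", "g", "o"),
    c("continuous", "discrete", "categorical_nominal", "categorical_ordinal"),
    list(o = c("low", "mid", "high")))
  CedaMatrix(df, schema)
}
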