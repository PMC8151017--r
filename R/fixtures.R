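# Synthetic-data generators with planted, known dependency structure, so
# every pipeline stage is testable without external data. Default sizes
# mirror the motivating scale (N = 2118 subjects).

#' Generate a categorical triplet with planted dependence
#'
#' Emulates a zone-like / outcome-like / count-like categorical triple:
#' `X1` uniform over its categories; `X3` equals a fixed permutation image
#' of `X1` with probability `rho` (else uniform); `X2` likewise linked to
#' `X1` with its own independent coin. `rho = 1` plants deterministic
#' coupling, `rho = 0` independence.
#'
#' @param n rows (default 2118).
#' @param rho coupling strength in \[0, 1\] (default 0.7, a moderate
#'   association).
#' @param categoryCounts numbers of categories of the three features
#'   (default `c(13, 11, 12)`).
#' @param seed integer seed; identical specs give identical matrices.
#' @return a \linkS4class{CedaMatrix} with nominal features `zone`,
#'   `result`, `count`.
#' @export
genCategoricalTriplet <- function(n = 2118L, rho = 0.7,
                                  categoryCounts = c(13L, 11L, 12L),
                                  seed = 1L) {
  .assert(rho >= 0 && rho <= 1, "rho must lie in [0, 1]")
  set.seed(seed)
  c1 <- categoryCounts[1L]; c2 <- categoryCounts[2L]; c3 <- categoryCounts[3L]
  x1 <- sample.int(c1, n, replace = TRUE)
  link <- function(src, nCat) {
    # fixed map from X1 categories into the target's categories
    map <- (seq_len(c1) - 1L) %% nCat + 1L
    keep <- stats::runif(n) < rho
    ifelse(keep, map[src], sample.int(nCat, n, replace = TRUE))
  }
  x2 <- link(x1, c2)
  x3 <- link(x1, c3)
  lab <- function(pre, k, idx) sprintf("%s%02d", pre, idx)
  df <- data.frame(zone = lab("z", c1, x1), result = lab("r", c2, x2),
                   count = lab("c", c3, x3), stringsAsFactors = FALSE)
  schema <- FeatureSchema(
    c("zone", "result", "count"),
    rep("categorical_nominal", 3L),
    list(zone = sprintf("z%02d", seq_len(c1)),
         result = sprintf("r%02d", seq_len(c2)),
         count = sprintf("c%02d", seq_len(c3))))
  CedaMatrix(df, schema)
}

#' Generate a synergistic continuous quadruple near a 2D manifold
#'
#' Emulates two synergistic feature pairs whose within-pair association is
#' stronger than the between-pair link: two latent coordinates `u` and `v`
#' drive the cloud, with the second pair's latent `w = sin(pi u)/2 + v`
#' coupled to the first through a sinusoidal ridge. Each observed feature
#' is a linear image of its pair's latent plus measurement noise `sigma`,
#' so at `sigma = 0` the points lie exactly on a 2D plane in 4D (block PCA
#' eigenvalues 3 and 4 vanish) while the point density on that plane stays
#' curved and non-Gaussian.
#'
#' @param n rows (default 2118).
#' @param sigma measurement noise scale, `>= 0` (default 0.05).
#' @param vScale spread of the second latent (default 0.3: the between-pair
#'   link is real but noticeably weaker than the within-pair ones).
#' @param seed integer seed.
#' @return a \linkS4class{CedaMatrix} with continuous features `defl_x`,
#'   `spin_dir`, `defl_z`, `spin_rate`.
#' @export
genManifoldQuadruple <- function(n = 2118L, sigma = 0.05, vScale = 0.3,
                                 seed = 1L) {
  .assert(sigma >= 0, "sigma must be non-negative")
  set.seed(seed)
  # peaked (Gaussian) latent: an exactly uniform marginal has a linear ECDF
  # and would legitimately collapse to a single histogram bin
  u <- stats::rnorm(n, 0, 0.5)
  v <- stats::rnorm(n, 0, vScale)
  w <- sin(pi * u) / 2 + v
  df <- data.frame(
    defl_x = 0.8 * u + stats::rnorm(n, 0, sigma),
    spin_dir = u + stats::rnorm(n, 0, sigma),
    defl_z = -0.6 * w + stats::rnorm(n, 0, sigma),
    spin_rate = w + stats::rnorm(n, 0, sigma))
  schema <- FeatureSchema(colnames(df), rep("continuous", 4L))
  CedaMatrix(df, schema)
}

#' Generate a mixed zone/speed matrix with a planted category-speed shift
#'
#' Emulates a 13-category zone-like nominal feature coupled to one
#' continuous speed-like feature: zones are laid out on a 3 x 3 inner grid
#' plus 4 peripheral positions; zones on the right shift the speed mean
#' upward by `shift` standard deviations, so left/right column-mode
#' patterns certify at the 95% level when the shift is large. Two further
#' continuous release-coordinate features are correlated with each other
#' but only weakly with speed.
#'
#' @param n rows, `>= 100` (default 2118).
#' @param shift speed mean separation between leftmost and rightmost zone
#'   columns, in within-zone standard deviations (default 2; use 0 for the
#'   null).
#' @param seed integer seed.
#' @return a \linkS4class{CedaMatrix} with features `zone`
#'   (nominal, 13 levels), `speed`, `release_x`, `release_z` (continuous).
#' @export
genMixedZone <- function(n = 2118L, shift = 2, seed = 1L) {
  .assert(n >= 100L, "n must be at least 100")
  set.seed(seed)
  zones <- sprintf("z%02d", seq_len(13L))
  # horizontal position of each zone: inner 3x3 grid columns -1, 0, 1 and
  # four peripheral corners
  zoneX <- c(-1, 0, 1, -1, 0, 1, -1, 0, 1, -1.5, 1.5, -1.5, 1.5)
  z <- sample.int(13L, n, replace = TRUE)
  speed <- 90 + shift * zoneX[z] / 1.5 + stats::rnorm(n)
  rx <- zoneX[z] / 3 + stats::rnorm(n, 0, 0.8)
  rz <- 0.6 * rx + stats::rnorm(n, 0, 0.6)
  df <- data.frame(zone = zones[z], speed = speed, release_x = rx,
                   release_z = rz, stringsAsFactors = FALSE)
  schema <- FeatureSchema(
    c("zone", "speed", "release_x", "release_z"),
    c("categorical_nominal", rep("continuous", 3L)),
    list(zone = zones))
  CedaMatrix(df, schema)
}
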