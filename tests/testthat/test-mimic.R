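test_that("table simulation under rules respects support and totals", {
  tab <- asTable(matrix(c(5, 0, 0, 5), 2))
  rs <- certifyRules(extractPatterns(tab, r = 2), tab, B = 200, seed = 2,
                     level = 0)
  sim <- simulateTableUnderRules(tab, rs, seed = 3)
  expect_equal(sum(tableCounts(sim)), 10)
  expect_equal(unname(tableCounts(sim)[1, 2]), 0)
  expect_equal(unname(tableCounts(sim)[2, 1]), 0)
  # empty rule set: a plain multinomial draw accepted at the first try
  simFree <- simulateTableUnderRules(tab, certifyRules(list(), tab, seed = 1),
                                     seed = 4)
  expect_identical(attr(simFree, "tries"), 1L)
  # contradictory hand-written rules are unsatisfiable
  bad <- new("RuleSet", rules = list(
    list(type = "column_mode", scope = "t", column = 1L, modeRow = 1L),
    list(type = "column_mode", scope = "t", column = 1L, modeRow = 2L)),
    rejected = list(), level = 0, B = 1L, scheme = "bootstrap", seed = 1L)
  expect_error(simulateTableUnderRules(tab, bad, seed = 1, maxTries = 50),
               "most-violated")
})

test_that("block PCA is an exact orthonormal round trip", {
  # 4 coplanar points in 4D: two vanishing eigenvalues
  set.seed(8)
  u <- c(0, 1, 2, 3); v <- c(1, -1, 2, 0)
  X <- cbind(u, 2 * u + v, v, u - v)
  df <- as.data.frame(X)
  colnames(df) <- paste0("f", 1:4)
  data <- CedaMatrix(df, FeatureSchema(colnames(df), rep("continuous", 4)))
  block <- list(rows = 1:4, bounds = setNames(
    lapply(1:4, function(k) range(X[, k]) + c(0, 1e-6)), colnames(df)))
  pca <- blockPCA(block, data)
  expect_lt(pca$values[3], 1e-10)
  expect_lt(pca$values[4], 1e-10)
  expect_equal(pca$vectors %*% t(pca$vectors), diag(4), tolerance = 1e-10)
  recon <- pca$scores %*% pca$vectors +
    matrix(pca$center, 4, 4, byrow = TRUE)
  expect_equal(unname(recon), unname(X), tolerance = 1e-10)
  # rank is at most m - 1
  data3 <- CedaMatrix(df[1:3, ], featureSchema(data))
  pca3 <- blockPCA(list(rows = 1:3, bounds = block$bounds), data3)
  expect_lte(sum(pca3$values > 1e-10), 2)
  expect_error(blockPCA(list(rows = 1L, bounds = block$bounds), data),
               "fewer than 2")
})

test_that("block mimicking respects hypercube boundaries and densities", {
  set.seed(3)
  n <- 300
  x <- rnorm(n); y <- 0.5 * x + rnorm(n, 0, 0.3)
  df <- data.frame(a = x, b = y)
  data <- CedaMatrix(df, FeatureSchema(c("a", "b"), rep("continuous", 2)))
  block <- list(rows = seq_len(n),
                bounds = list(a = range(x) + c(0, 1e-9),
                              b = range(y) + c(0, 1e-9)))
  pca <- blockPCA(block, data)
  cubes <- list(lo = matrix(c(min(x), min(y)), 1, 2,
                            dimnames = list(NULL, c("a", "b"))),
                hi = matrix(c(max(x) + 1e-9, max(y) + 1e-9), 1, 2,
                            dimnames = list(NULL, c("a", "b"))))
  pts <- mimicBlock(pca, cubes, B = 2000, seed = 11)
  expect_identical(nrow(pts), 2000L)
  expect_true(all(pts[, 1] >= min(x) & pts[, 1] < max(x) + 1e-9))
  expect_true(all(pts[, 2] >= min(y) & pts[, 2] < max(y) + 1e-9))
  # per-component marginals match the smoothed score distribution
  sc <- sweep(pts, 2, pca$center) %*% t(pca$vectors)
  for (h in 1:2) {
    ks <- suppressWarnings(stats::ks.test(sc[, h], pca$scores[, h]))
    expect_lt(unname(ks$statistic), 0.15)
  }
  # a candidate outside every member hypercube is rejected by construction
  tight <- list(lo = cubes$lo, hi = cubes$lo + 0.5)
  ptsT <- suppressWarnings(mimicBlock(pca, tight, B = 50, seed = 2,
                                      maxAttempts = 2000))
  if (nrow(ptsT) > 0)
    expect_true(all(ptsT[, 1] < tight$hi[1, 1] & ptsT[, 2] < tight$hi[1, 2]))
  # degenerate block: every mimicry equals the repeated point
  dfD <- data.frame(a = rep(1.5, 5), b = rep(-2, 5))
  dataD <- CedaMatrix(dfD, featureSchema(data))
  pcaD <- blockPCA(list(rows = 1:5, bounds = block$bounds), dataD)
  cubesD <- list(lo = matrix(c(1, -3), 1, 2), hi = matrix(c(2, -1), 1, 2))
  colnames(cubesD$lo) <- colnames(cubesD$hi) <- c("a", "b")
  ptsD <- mimicBlock(pcaD, cubesD, B = 10, seed = 1)
  expect_true(all(ptsD[, 1] == 1.5 & ptsD[, 2] == -2))
})

test_that("scenario I preserves support under deterministic coupling", {
  # X3 = X1 = X2: zero rules force the diagonal support exactly
  set.seed(5)
  z <- sample(1:4, 400, TRUE)
  cd <- makeCoded(cbind(z, z, z),
                  rep("categorical_nominal", 3))
  tabs <- list(pair = featurePairTable(cd, "f1", "f2"),
               crossA = featurePairTable(cd, "f3", "f1"),
               crossB = featurePairTable(cd, "f3", "f2"))
  rs <- lapply(tabs, function(tb)
    certifyRules(extractPatterns(tb, types = "zero_occupancy"), tb,
                 B = 200, seed = 6))
  ens <- mimicScenario1(cd, c("f1", "f2"), "f3", rs, nMimicries = 5,
                        seed = 21)
  for (m in mimicries(ens)) {
    codes <- codeMatrix(m)
    expect_true(all(codes[, "f1"] == codes[, "f2"] &
                      codes[, "f2"] == codes[, "f3"]))
    expect_identical(nrow(codes), 400L)
  }
})

test_that("scenario I: vacuous rules accept everything, sums conserved", {
  cd <- makeCoded(cbind(sample(1:3, 200, TRUE), sample(1:3, 200, TRUE),
                        sample(1:3, 200, TRUE)),
                  rep("categorical_nominal", 3))
  ens <- mimicScenario1(cd, c("f1", "f2"), "f3", list(), nMimicries = 10,
                        seed = 33)
  expect_equal(acceptanceRate(ens), 1)
  lat0 <- buildLattice(cd, "f3", c("f1", "f2"))
  for (m in mimicries(ens)) {
    sLat <- attr(m, "lattice")
    sPair <- attr(m, "pairTable")
    # lattice column sums equal the simulated pair-table counts
    expect_equal(unname(colSums(sLat)),
                 unname(sPair[lat0@colCells$codes]))
    expect_equal(sum(sLat), 200)
  }
})

test_that("scenario II: the nT >= N limit is the identity on coded data", {
  d <- genManifoldQuadruple(400, seed = 2)
  ens <- mimicScenario2(d, c("defl_x", "spin_dir"),
                        c("defl_z", "spin_rate"), nMimicries = 2,
                        seed = 5, nT = 400, rowCut = 2, colCut = 2,
                        reliabilityB = 100)
  cd0 <- ens@config$coded
  for (m in mimicries(ens)) {
    expect_equal(dataValues(m), dataValues(d))
    expect_identical(codeMatrix(encodeWithCoders(m, coderList(cd0))),
                     codeMatrix(cd0))
  }
  expect_equal(acceptanceRate(ens), 1)
})

test_that("scenario II preserves per-block counts and satisfies rules", {
  d <- genManifoldQuadruple(1000, seed = 4)
  gA <- c("defl_x", "spin_dir"); gB <- c("defl_z", "spin_rate")
  ens <- mimicScenario2(d, gA, gB, nMimicries = 5, seed = 17,
                        rowCut = 3, colCut = 3, reliabilityB = 200)
  cfg <- ens@config
  lat <- cfg$lattice
  for (m in mimicries(ens)) {
    cdm <- encodeWithCoders(m, coderList(cfg$coded))
    expect_false(is.null(cdm))
    # both governing rule sets hold (hard acceptance contract)
    expect_true(rulesSatisfied(featurePairTable(cdm, gA[1], gA[2]),
                               cfg$rulesets$groupA)$ok)
    expect_true(rulesSatisfied(featurePairTable(cdm, gB[1], gB[2]),
                               cfg$rulesets$groupB)$ok)
    # per-block counts: rows recoding into a block's member cells match
    rowsC <- buildGroupCells(cdm, gA)
    colsC <- buildGroupCells(cdm, gB)
    keyR <- apply(rowsC$codes[rowsC$assign, , drop = FALSE], 1,
                  paste, collapse = ".")
    keyC <- apply(colsC$codes[colsC$assign, , drop = FALSE], 1,
                  paste, collapse = ".")
    for (b in cfg$blocks) {
      inBlock <- keyR %in% lat@rowCells$labels[b$rowCells] &
        keyC %in% lat@colCells$labels[b$colCells]
      expect_identical(sum(inBlock), b$size)
    }
  }
})

test_that("scenario III reproduces the planted coupling's certified rules", {
  d <- genMixedZone(1500, shift = 2, seed = 3)
  ens <- mimicScenario3(d, c("release_x", "release_z"), c("zone", "speed"),
                        nMimicries = 5, seed = 13, rowCut = 4,
                        reliabilityB = 200, maxTries = 2000)
  cfg <- ens@config
  modeRules <- Filter(function(r) r$type == "column_mode",
                      ruleList(cfg$rulesets$mixed))
  expect_gt(length(modeRules), 0)
  for (m in mimicries(ens)) {
    expect_identical(nrow(dataValues(m)), 1500L)
    cdm <- encodeWithCoders(m, coderList(cfg$coded))
    tabM <- featurePairTable(cdm, "speed", "zone")
    tabC <- featurePairTable(cdm, "release_x", "release_z")
    expect_true(rulesSatisfied(tabM, cfg$rulesets$mixed)$ok)
    expect_true(rulesSatisfied(tabC, cfg$rulesets$cont)$ok)
    # mimicked continuous points lie inside their block's member cubes
    for (b in cfg$blocks) {
      if (b$intact) next
      vals <- dataValues(m)
      inside <- rep(FALSE, nrow(vals))
      for (ci in seq_len(nrow(b$cubes$lo))) {
        inC <- rep(TRUE, nrow(vals))
        for (nm in colnames(b$cubes$lo))
          inC <- inC & vals[[nm]] >= b$cubes$lo[ci, nm] &
            vals[[nm]] < b$cubes$hi[ci, nm]
        inside <- inside | inC
      }
      zoneLevel <- coderList(cfg$coded)$zone[b$colGroup]
      expect_true(sum(inside & vals$zone == zoneLevel) > 0 ||
                    sum(tableCounts(cfg$lattice)[b$rowCells, b$colCells]) == 0)
    }
  }
})

test_that("ensembles are reproducible and degenerate cases reduce sanely", {
  cd <- makeCoded(cbind(sample(1:3, 150, TRUE), sample(1:3, 150, TRUE),
                        sample(1:3, 150, TRUE)),
                  rep("categorical_nominal", 3))
  e1 <- mimicScenario1(cd, c("f1", "f2"), "f3", list(), nMimicries = 3,
                       seed = 77)
  e2 <- mimicScenario1(cd, c("f1", "f2"), "f3", list(), nMimicries = 3,
                       seed = 77)
  expect_identical(serialize(mimicries(e1), NULL),
                   serialize(mimicries(e2), NULL))
  stats <- acceptanceStats(e1)
  expect_equal(stats$acceptanceRate, stats$accepted / stats$attempts)
  # single category, single block: scenario III reduces to scenario-II-like
  # behaviour (one category, every block intact at nT >= N)
  set.seed(1)
  df <- data.frame(zone = rep("only", 300),
                   speed = rnorm(300, 90),
                   release_x = rnorm(300), release_z = rnorm(300),
                   stringsAsFactors = FALSE)
  dOne <- CedaMatrix(df, FeatureSchema(
    c("zone", "speed", "release_x", "release_z"),
    c("categorical_nominal", rep("continuous", 3)), list(zone = "only")))
  ensOne <- mimicScenario3(dOne, c("release_x", "release_z"),
                           c("zone", "speed"), nMimicries = 2, seed = 9,
                           rowCut = 2, nT = 300, reliabilityB = 100)
  for (m in mimicries(ensOne))
    expect_equal(dataValues(m)[order(dataValues(m)$speed), ],
                 dataValues(dOne)[order(dataValues(dOne)$speed), ],
                 ignore_attr = TRUE)
})

test_that("unconstrained resampling is accepted less often than mimicking", {
  m <- genCategoricalTriplet(1500, rho = 0.7, seed = 6)
  cd <- encodeMatrix(m)
  pairs <- list(c("zone", "result"), c("count", "zone"), c("count", "result"))
  rs <- lapply(pairs, function(p) {
    tb <- featurePairTable(cd, p[1], p[2])
    certifyRules(extractPatterns(tb), tb, B = 300, seed = 41)
  })
  rate <- resampleAcceptance(cd, pairs, rs, B = 100, seed = 15)
  expect_lt(rate, 1)
  ens <- mimicScenario1(cd, c("zone", "result"), "count",
                        list(pair = rs[[1]], crossA = rs[[2]],
                             crossB = rs[[3]]), nMimicries = 20, seed = 5)
  expect_identical(ens@accepted, 20L)
})
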