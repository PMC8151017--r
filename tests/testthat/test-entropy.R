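test_that("Shannon entropy anchors and error cases", {
  expect_equal(shannonEntropy(c(5, 5)), log(2))
  expect_equal(shannonEntropy(c(10, 0, 0)), 0)
  expect_equal(shannonEntropy(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_error(shannonEntropy(c(0, 0)), "all-zero")
})

test_that("contingency tables count and preserve marginals", {
  t1 <- contingencyTable(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(unname(tableCounts(t1)), matrix(1, 2, 2))
  t2 <- contingencyTable(c(1, 2, 1, 2), c(1, 2, 1, 2))
  expect_equal(unname(tableCounts(t2)), diag(2) * 2)
  t3 <- contingencyTable(1L, 1L)
  expect_equal(sum(tableCounts(t3)), 1)
  expect_error(contingencyTable(1:3, 1:2), "length")
})

test_that("directional profiles hit the analytic anchors", {
  det <- asTable(matrix(c(2, 0, 0, 2), 2))
  expect_equal(conditionalEntropyProfile(det, "rows")$overallRatio, 0)
  expect_equal(conditionalEntropyProfile(det, "cols")$overallRatio, 0)
  ind <- asTable(matrix(4, 2, 2))
  expect_equal(conditionalEntropyProfile(ind, "rows")$overallRatio, 1)
  p <- conditionalEntropyProfile(asTable(matrix(c(2, 1, 1, 2), 2)), "rows")
  expect_equal(p$marginalEntropy, log(2))
  expect_equal(p$conditionalEntropy, oracleProfile(matrix(c(2, 1, 1, 2), 2))$cond)
  expect_equal(p$overallRatio, 0.9182958, tolerance = 1e-7)
  # the overall conditional entropy is the weighted per-category sum
  expect_equal(sum(p$perCategory$weight * p$perCategory$condEntropy),
               p$conditionalEntropy)
})

test_that("degenerate targets flag and return ratio 1", {
  const <- asTable(matrix(c(3, 4), 1, 2))
  p <- conditionalEntropyProfile(const, "rows")
  expect_true(p$degenerate)
  expect_equal(p$overallRatio, 1)
  expect_warning(mutualConditionalEntropy(const), "degenerate")
})

test_that("MCE anchors: identity, independence, symmetric tables", {
  sym <- asTable(matrix(c(2, 1, 1, 2), 2))
  expect_equal(mutualConditionalEntropy(sym, "average"),
               mutualConditionalEntropy(sym, "min"))
  expect_equal(mutualConditionalEntropy(sym), 0.9182958, tolerance = 1e-7)
  expect_equal(mutualConditionalEntropy(asTable(diag(2) * 5)), 0)
  expect_equal(mutualConditionalEntropy(asTable(matrix(4, 2, 2))), 1)
})

test_that("mutual information anchors", {
  expect_equal(mutualInformation(asTable(matrix(c(2, 1, 1, 2), 2))),
               0.05663301, tolerance = 1e-7)
  expect_equal(mutualInformation(asTable(diag(2) * 2)), log(2))
  expect_equal(mutualInformation(asTable(matrix(4, 2, 2))), 0)
})

test_that("implementation agrees with the brute-force oracle on random tables", {
  set.seed(20)
  for (i in 1:200) {
    counts <- randomTable(6)
    tab <- asTable(counts)
    o <- oracleProfile(counts)
    p <- conditionalEntropyProfile(tab, "rows")
    expect_equal(p$overallRatio, o$ratio, tolerance = 1e-12)
    expect_equal(mutualConditionalEntropy(tab), oracleMCE(counts),
                 tolerance = 1e-12)
    expect_equal(mutualConditionalEntropy(tab, "min"),
                 oracleMCE(counts, "min"), tolerance = 1e-12)
    expect_equal(mutualInformation(tab), oracleMI(counts), tolerance = 1e-12)
    # information inequalities
    expect_lte(p$conditionalEntropy, p$marginalEntropy + 1e-12)
    expect_lte(p$conditionalEntropy, oracleEntropy(as.vector(counts)) + 1e-12)
    # min variant never exceeds the average
    expect_lte(mutualConditionalEntropy(tab, "min"),
               mutualConditionalEntropy(tab, "average") + 1e-15)
    # base invariance of the re-scaled ratio
    expect_equal(o$ratio, oracleProfile(counts, base = 2)$ratio,
                 tolerance = 1e-12)
  }
})

test_that("MCE is invariant to row and column permutations", {
  set.seed(4)
  for (i in 1:20) {
    counts <- randomTable(5)
    v <- mutualConditionalEntropy(asTable(counts))
    perm <- counts[sample(nrow(counts)), sample(ncol(counts)), drop = FALSE]
    expect_equal(mutualConditionalEntropy(asTable(perm)), v,
                 tolerance = 1e-12)
  }
})

test_that("mceMatrix is consistent with pairwise MCE and flags constants", {
  cd <- makeCoded(cbind(c(1, 2, 1, 2), c(1, 2, 1, 2), c(1, 1, 2, 2)))
  mc <- mceMatrix(cd)
  expect_equal(unname(mceEntries(mc)[1, 2]), 0)         # duplicated column
  expect_equal(mceEntries(mc), t(mceEntries(mc)))
  tab <- featurePairTable(cd, 1, 3)
  expect_equal(unname(mceEntries(mc)[1, 3]), mutualConditionalEntropy(tab))
  cdConst <- makeCoded(cbind(c(1, 2, 1, 2), c(1, 1, 1, 1) ))
  expect_warning(mcc <- mceMatrix(cdConst), "constant")
  expect_equal(unname(mceEntries(mcc)[1, 2]), 1)
})

test_that("heatmap tree places the closest pair adjacently", {
  e <- matrix(0.9, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  e[1, 2] <- e[2, 1] <- 0.2
  diag(e) <- 0
  mce <- new("MCEMatrix", entries = e, variant = "average",
             degenerate = rep(FALSE, 3))
  hm <- mceHeatmap(mce)
  pos <- match(1:2, hm$order)
  expect_equal(abs(diff(pos)), 1)              # leaves 1,2 adjacent
  # permuted matrix is a simultaneous row/column reindexing
  expect_setequal(as.vector(mceEntries(hm$permuted)), as.vector(e))
  expect_equal(mceEntries(hm$permuted),
               e[hm$order, hm$order, drop = FALSE], ignore_attr = TRUE)
  # K = 2: one merge at the off-diagonal height
  e2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = rep(list(c("u", "v")), 2))
  hm2 <- mceHeatmap(new("MCEMatrix", entries = e2, variant = "average",
                        degenerate = rep(FALSE, 2)))
  expect_equal(hm2$tree$height, 0.4)
})

test_that("directed network classifies ratios by the two cut levels", {
  prof <- data.frame(target = c("y", "y", "y", "y"),
                     conditioning = c("a", "b", "c", "d"),
                     ratio = c(0.85, 0.99, 0.9, 0.949))
  net <- directedNetwork(prof, c(0.9, 0.95))
  expect_identical(net$class[net$from == "a"], "thick")
  expect_false("b" %in% net$from)              # above both cuts: no edge
  expect_identical(net$class[net$from == "c"], "thin")   # boundary is thin
  expect_identical(net$class[net$from == "d"], "thin")
  expect_error(directedNetwork(prof, c(0.95, 0.9)), "increasing")
})
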