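test_that("occupied cells enumerate distinct observed code tuples", {
  cd <- makeCoded(cbind(c(1, 2, 3, 1), c(1, 1, 2, 1)))
  c1 <- buildGroupCells(cd, "f1")
  expect_identical(nrow(c1$codes), 3L)
  expect_identical(sum(c1$counts), 4L)
  both <- buildGroupCells(cd, c("f1", "f2"))
  expect_identical(nrow(both$codes), 3L)       # (1,1), (2,1), (3,2)
  same <- makeCoded(matrix(1L, 4, 2))
  cs <- buildGroupCells(same, c("f1", "f2"))
  expect_identical(nrow(cs$codes), 1L)
  expect_identical(cs$counts, 4L)
  expect_error(buildGroupCells(cd, "nope"), "unknown feature")
})

test_that("lattice marginals are conserved", {
  # constructed determinism: f3 tied to f1
  cd <- makeCoded(cbind(rep(1:2, each = 5), rep(1:2, each = 5),
                        rep(1:2, each = 5)))
  lat <- buildLattice(cd, c("f1", "f2"), "f3")
  expect_equal(unname(tableCounts(lat)), diag(2) * 5)
  # single-column group
  cdc <- makeCoded(cbind(c(1, 2, 1, 2), rep(1L, 4)))
  latc <- buildLattice(cdc, "f1", "f2")
  expect_identical(ncol(tableCounts(latc)), 1L)
  expect_equal(unname(tableCounts(latc)[, 1]), c(2, 2))
  # conservation on random coded matrices
  for (seed in 1:5) {
    set.seed(seed)
    cd <- makeCoded(matrix(sample(1:4, 120, TRUE), 40, 3))
    lat <- buildLattice(cd, c("f1", "f2"), "f3")
    expect_equal(sum(tableCounts(lat)), 40)
    expect_equal(unname(rowSums(tableCounts(lat))),
                 as.numeric(lat@rowCells$counts))
    expect_equal(unname(colSums(tableCounts(lat))),
                 as.numeric(lat@colCells$counts))
  }
  expect_error(buildLattice(cd, c("f1", "f2"), "f2"), "disjoint")
})

test_that("edge and corner adjacency implement the two neighbor systems", {
  cells <- list(features = c("a", "b"), dtypes = c("discrete", "discrete"),
                codes = rbind(c(1, 1), c(1, 2), c(2, 2)),
                counts = c(1L, 1L, 1L), labels = c("1.1", "1.2", "2.2"))
  edge <- adjacencyMatrix(cells, "edge")
  corner <- adjacencyMatrix(cells, "corner")
  expect_equal(unname(edge), rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
               ignore_attr = TRUE)
  expect_equal(unname(corner), matrix(1, 3, 3) - diag(3),
               ignore_attr = TRUE)
  single <- list(features = "a", dtypes = "discrete",
                 codes = matrix(1, 1, 1), counts = 1L, labels = "1")
  expect_equal(unname(adjacencyMatrix(single)), matrix(0, 1, 1),
               ignore_attr = TRUE)
  nom <- list(features = "z", dtypes = "categorical_nominal",
              codes = matrix(1:2), counts = c(1L, 1L), labels = c("a", "b"))
  expect_error(adjacencyMatrix(nom), "quantitative")
  # edge-mode adjacency is a subgraph of corner-mode adjacency
  for (seed in 1:5) {
    set.seed(seed)
    codes <- unique(matrix(sample(1:4, 30, TRUE), ncol = 2))
    cl <- list(features = c("a", "b"), dtypes = rep("discrete", 2),
               codes = codes, counts = rep(1L, nrow(codes)),
               labels = apply(codes, 1, paste, collapse = "."))
    expect_true(all(adjacencyMatrix(cl, "edge") <=
                      adjacencyMatrix(cl, "corner")))
  }
})

test_that("adjacency trees follow geodesic structure", {
  # path graph: adjacent pairs merge at distance 1, the far pair at 2
  cells <- list(features = c("a", "b"), dtypes = rep("discrete", 2),
                codes = rbind(c(1, 1), c(1, 2), c(1, 3)),
                counts = rep(1L, 3), labels = c("A", "B", "C"))
  tr <- hcTreeFromAdjacency(adjacencyMatrix(cells, "edge"))
  expect_equal(tr$height[1], 1)
  expect_gt(tr$height[2], 1)
  # two disconnected cells merge at the sentinel distance L + 1
  far <- list(features = c("a", "b"), dtypes = rep("discrete", 2),
              codes = rbind(c(1, 1), c(5, 5)), counts = rep(1L, 2),
              labels = c("A", "B"))
  trFar <- hcTreeFromAdjacency(adjacencyMatrix(far, "corner"))
  expect_equal(trFar$height, 3)
  # complete adjacency: all merges at distance 1
  comp <- list(features = c("a", "b"), dtypes = rep("discrete", 2),
               codes = rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2)),
               counts = rep(1L, 4), labels = as.character(1:4))
  trC <- hcTreeFromAdjacency(adjacencyMatrix(comp, "corner"))
  expect_true(all(trC$height == 1))
})

test_that("extreme-K trees use proportion-vector distances", {
  lat <- asTable(rbind(c(5, 5, 0), c(10, 10, 0), c(0, 0, 7)))
  tr <- hcTreeExtremeK(lat, "rows")
  # identical profiles (rows 1, 2) merge first at distance 0
  expect_equal(tr$height[1], 0)
  expect_setequal(-tr$merge[1, ], 1:2)
  # orthogonal point masses sit at the maximal Hellinger distance 1
  tr2 <- hcTreeExtremeK(asTable(rbind(c(10, 0), c(0, 10))), "rows")
  expect_equal(tr2$height, 1)
  expect_s3_class(hcTreeExtremeK(asTable(matrix(c(1, 2), 1)), "rows"),
                  "cedaLeafTree")
})

test_that("bivariate order is category-major, bin-minor", {
  cells <- list(codes = rbind(c(2, 1), c(1, 2), c(1, 1)))
  ord <- bivariateOrder(c("a", "b"), 2, cells)
  expect_identical(ord, c(3L, 2L, 1L))         # (a,1), (a,2), (b,1)
  one <- list(codes = rbind(c(1, 3), c(1, 1), c(1, 2)))
  expect_identical(bivariateOrder("a", 3, one), c(2L, 3L, 1L))
  # zone-like: 13 categories coupled with increasing bins
  set.seed(2)
  cd <- makeCoded(cbind(sample(1:13, 300, TRUE), sample(1:5, 300, TRUE)),
                  c("categorical_nominal", "discrete"))
  cells13 <- buildGroupCells(cd, c("f1", "f2"))
  o <- bivariateOrder(letters[1:13], 5, cells13)
  oc <- cells13$codes[o, ]
  expect_true(all(diff(oc[, 1]) >= 0))
  within <- split(oc[, 2], oc[, 1])
  expect_true(all(vapply(within, function(b) all(diff(b) > 0), logical(1))))
})

test_that("heatmap permutation preserves counts, marginals and inverts", {
  set.seed(11)
  cd <- makeCoded(matrix(sample(1:3, 90, TRUE), 30, 3))
  lat <- buildLattice(cd, c("f1", "f2"), "f3")
  idRow <- seq_len(nrow(tableCounts(lat)))
  expect_equal(tableCounts(permuteHeatmap(lat, idRow)), tableCounts(lat))
  ro <- rev(idRow)
  perm <- permuteHeatmap(lat, ro)
  expect_setequal(as.vector(tableCounts(perm)), as.vector(tableCounts(lat)))
  expect_equal(sum(tableCounts(perm)), 30)
  expect_equal(unname(rowSums(tableCounts(perm))),
               unname(rowSums(tableCounts(lat))[ro]))
  back <- permuteHeatmap(perm, match(idRow, ro))
  expect_equal(tableCounts(back), tableCounts(lat))
})

test_that("blocks partition occupied cells and data rows", {
  cd <- plantedTwoClusterCoded(200, seed = 7)
  lat <- buildLattice(cd, c("f1", "f2"), c("f3", "f4"))
  lat <- attachAxisTrees(
    lat,
    rowTree = hcTreeFromAdjacency(adjacencyMatrix(lat@rowCells, "corner")),
    colTree = hcTreeFromAdjacency(adjacencyMatrix(lat@colCells, "corner")))
  # trivial single block
  b1 <- partitionBlocks(lat, 1, list(tree_cut = 1), cd)
  expect_identical(length(b1), 1L)
  expect_identical(b1[[1]]$size, 200L)
  # 2 x 2 cut: blocks partition rows exactly
  b4 <- partitionBlocks(lat, 2, list(tree_cut = 2), cd)
  expect_lte(length(b4), 4L)
  allRows <- sort(unlist(lapply(b4, `[[`, "rows")))
  expect_identical(allRows, 1:200)
  expect_identical(sum(vapply(b4, `[[`, integer(1), "size")), 200L)
  # the two planted clusters land in two dense diagonal blocks
  sizes <- sort(vapply(b4, `[[`, integer(1), "size"), decreasing = TRUE)
  expect_gte(sizes[1], 90)
  expect_gte(sizes[2], 90)
  # each cluster's block captures >= 90% of its cluster's count
  low <- vapply(b4, function(b)
    sum(lat@rowAssign[1:100] %in% b$rowCells &
          lat@colAssign[1:100] %in% b$colCells), numeric(1))
  expect_gte(max(low) / 100, 0.9)
  # per-feature bounding intervals cover member hypercubes
  expect_true(all(vapply(b4, function(b)
    b$bounds$f1[1] < b$bounds$f1[2], logical(1))))
  expect_error(partitionBlocks(lat, 100, list(tree_cut = 2), cd),
               "infeasible")
})
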