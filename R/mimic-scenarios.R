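# The three mimicking protocols. Every accepted mimicry satisfies every
# governing rule set -- that is the hard acceptance contract; the attempt
# counters and per-rule violation tallies quantify how constraining the
# certified structure is.

.addViolations <- function(violations, ids) {
  for (id in ids) {
    if (is.na(violations[id])) violations[id] <- 0
    violations[id] <- violations[id] + 1
  }
  violations
}

.emptyRuleSet <- function() {
  new("RuleSet", rules = list(), rejected = list(), level = 0.95,
      B = 0L, scheme = "bootstrap", seed = 0L)
}

#' Simulate a contingency table under a rule set
#'
#' Multinomial draw of the template's total over the template's cell
#' probabilities (so the support never grows), rejected until every rule is
#' satisfied.
#'
#' @param template the observed \linkS4class{ContingencyTable}.
#' @param ruleset governing \linkS4class{RuleSet}.
#' @param seed integer seed.
#' @param maxTries attempt cap.
#' @return an accepted \linkS4class{ContingencyTable} with a `"tries"`
#'   attribute; errors after `maxTries` naming the most-violated rules.
#' @export
simulateTableUnderRules <- function(template, ruleset, seed = 1L,
                                    maxTries = 10000L) {
  .assert(maxTries >= 1L, "maxTries must be at least 1")
  counts <- template@counts
  N <- sum(counts)
  .assert(N > 0, "empty template")
  p <- as.vector(counts) / N
  set.seed(seed)
  violations <- numeric(0)
  for (t in seq_len(maxTries)) {
    sim <- matrix(stats::rmultinom(1L, N, p), nrow(counts), ncol(counts),
                  dimnames = dimnames(counts))
    chk <- rulesSatisfied(sim, ruleset)
    if (chk$ok) {
      out <- new("ContingencyTable", counts = sim)
      attr(out, "tries") <- t
      return(out)
    }
    violations <- .addViolations(violations, chk$violated)
  }
  worst <- sort(violations, decreasing = TRUE)
  stop(sprintf(
    "no accepted table in %d tries; most-violated rules: %s", maxTries,
    paste(sprintf("%s (%d)", names(worst)[seq_len(min(3, length(worst)))],
                  worst[seq_len(min(3, length(worst)))]), collapse = ", ")),
    call. = FALSE)
}

# Column-by-column lattice simulation: given per-column totals, draw each
# column from its observed column-conditional distribution (columns
# independent given their totals).
.simulateLatticeColumns <- function(obsCounts, colTotals) {
  out <- matrix(0, nrow(obsCounts), ncol(obsCounts),
                dimnames = dimnames(obsCounts))
  for (c in seq_len(ncol(obsCounts))) {
    if (colTotals[c] == 0) next
    pc <- obsCounts[, c]
    if (sum(pc) == 0) return(NULL)          # cannot place mass in a dead column
    out[, c] <- stats::rmultinom(1L, colTotals[c], pc / sum(pc))
  }
  out
}

#' Mimicking protocol, scenario I: all-categorical features
#'
#' Simulates the most-associative pair's contingency table under its
#' certified rules; takes the simulated cell counts as column sums for
#' column-by-column simulation of the (third feature) x (pair cells)
#' contingency-3D-lattice; accepts the draw only when both remaining cross
#' tables (third vs each pair member) satisfy their certified rules.
#'
#' @param coded a \linkS4class{CodedMatrix} of categorical features.
#' @param pairFeatures the two features forming the pair group.
#' @param thirdFeature the remaining feature.
#' @param rulesets list with elements `pair`, `crossA` (third vs first pair
#'   member), `crossB` (third vs second); missing elements mean no
#'   constraint.
#' @param nMimicries ensemble size requested.
#' @param seed master seed; per-attempt substreams derive from it.
#' @param maxTries total attempt cap.
#' @return a \linkS4class{MimicryEnsemble} of \linkS4class{CodedMatrix}
#'   mimicries (each also carries its simulated lattice as attribute
#'   `"lattice"` and pair table as `"pairTable"`).
#' @export
mimicScenario1 <- function(coded, pairFeatures, thirdFeature,
                           rulesets = list(), nMimicries = 1L, seed = 1L,
                           maxTries = 10000L) {
  f1 <- pairFeatures[1L]; f2 <- pairFeatures[2L]; f3 <- thirdFeature
  rsPair <- rulesets$pair %||% .emptyRuleSet()
  rsA <- rulesets$crossA %||% .emptyRuleSet()
  rsB <- rulesets$crossB %||% .emptyRuleSet()
  tPair <- featurePairTable(coded, f1, f2)
  lat <- buildLattice(coded, f3, c(f1, f2))
  obsL <- lat@counts
  rowCodes <- lat@rowCells$codes[, 1L]
  colCodes <- lat@colCells$codes
  m1 <- nCategories(coded@coders[[f1]])
  m2 <- nCategories(coded@coders[[f2]])
  m3 <- nCategories(coded@coders[[f3]])
  indA <- outer(colCodes[, 1L], seq_len(m1), "==") * 1   # col cell -> f1 bin
  indB <- outer(colCodes[, 2L], seq_len(m2), "==") * 1
  p <- as.vector(tPair@counts) / sum(tPair@counts)
  schemaIdx <- match(c(f3, f1, f2), coded@schema@name)
  mim <- list()
  violations <- numeric(0)
  attempts <- 0L
  while (length(mim) < nMimicries && attempts < maxTries) {
    attempts <- attempts + 1L
    set.seed(.childSeed(seed, attempts))
    # step 1: one draw of the pair table; its rules gate the attempt
    sPair <- matrix(stats::rmultinom(1L, sum(tPair@counts), p),
                    nrow(tPair@counts), ncol(tPair@counts))
    chk <- rulesSatisfied(sPair, rsPair)
    if (!chk$ok) { violations <- .addViolations(violations, chk$violated); next }
    # step 2: simulated pair counts become the lattice column sums
    colTot <- sPair[colCodes]
    sLat <- .simulateLatticeColumns(obsL, colTot)
    if (is.null(sLat)) next
    # step 3: both cross tables must satisfy their rules
    t3a <- matrix(0, m3, m1); t3a[rowCodes, ] <- sLat %*% indA
    t3b <- matrix(0, m3, m2); t3b[rowCodes, ] <- sLat %*% indB
    chkA <- rulesSatisfied(t3a, rsA)
    chkB <- rulesSatisfied(t3b, rsB)
    if (!chkA$ok || !chkB$ok) {
      violations <- .addViolations(violations, c(chkA$violated, chkB$violated))
      next
    }
    occ <- which(sLat > 0, arr.ind = TRUE)
    nrep <- sLat[occ]
    codes <- cbind(rep(rowCodes[occ[, 1L]], nrep),
                   rep(colCodes[occ[, 2L], 1L], nrep),
                   rep(colCodes[occ[, 2L], 2L], nrep))
    colnames(codes) <- c(f3, f1, f2)
    ord <- order(schemaIdx)
    sub <- coded@schema@name[sort(schemaIdx)]
    schema <- FeatureSchema(sub, coded@schema@dtype[sort(schemaIdx)],
                            coded@schema@categoryOrder[sub])
    cm <- new("CodedMatrix",
              codes = matrix(as.integer(codes[, ord, drop = FALSE]),
                             nrow(codes), 3L, dimnames = list(NULL, sub)),
              coders = coded@coders[sub], schema = schema)
    attr(cm, "lattice") <- sLat
    attr(cm, "pairTable") <- sPair
    mim[[length(mim) + 1L]] <- cm
  }
  .assert(length(mim) == nMimicries,
          "only %d of %d mimicries accepted within %d attempts",
          length(mim), nMimicries, maxTries)
  new("MimicryEnsemble", scenario = "I", mimicries = mim,
      attempts = attempts, accepted = length(mim), seed = as.integer(seed),
      violations = violations,
      config = list(pairFeatures = pairFeatures, thirdFeature = thirdFeature,
                    rulesets = list(pair = rsPair, crossA = rsA, crossB = rsB),
                    maxTries = maxTries))
}

# Certify the standard pattern families on a pair table (used when the
# caller lets a scenario driver derive its own rule sets).
.autoCertify <- function(table, types, B, level, seed, orderedRows = TRUE) {
  certifyRules(extractPatterns(table, types = types,
                               orderedRows = orderedRows),
               table, B = B, level = level, seed = seed)
}

#' Mimicking protocol, scenario II: all-continuous features
#'
#' Builds the contingency-kD-lattice of two synergistic feature groups,
#' permutes it by HC-trees from the occupied cells' grid adjacency, cuts it
#' into blocks, and mimics each block's point cloud by block PCA with
#' kernel-smoothed component resampling (blocks at or below `nT` points are
#' copied intact). Each assembled N-row matrix is re-coded with the original
#' histograms and accepted only if both within-group pair tables satisfy
#' their certified rules.
#'
#' @param data a \linkS4class{CedaMatrix} of continuous features.
#' @param groupA,groupB the two feature groups (pairs, per the MCE road
#'   map).
#' @param nMimicries ensemble size requested.
#' @param seed master seed.
#' @param nT small-block threshold: blocks with `size <= nT` are kept
#'   intact (default 10).
#' @param rowCut,colCut numbers of row/column tree branches for the block
#'   partition.
#' @param rulesets list with `groupA`, `groupB` rule sets; `NULL` certifies
#'   `ruleTypes` automatically at `level` with `reliabilityB` resamples.
#' @param ruleTypes pattern families for automatic certification.
#' @param reliabilityB,level certification settings.
#' @param neighborMode `"corner"` (default) or `"edge"` cell adjacency.
#' @param poolFactor per-block mimicry pool size as a multiple of the
#'   block's quota.
#' @param maxTries attempt cap for the acceptance loop.
#' @param maxBins,fitTolerance histogram settings.
#' @return a \linkS4class{MimicryEnsemble} of \linkS4class{CedaMatrix}
#'   mimicries; `config` records the lattice, blocks, coded original and
#'   rule sets.
#' @export
mimicScenario2 <- function(data, groupA, groupB, nMimicries = 1L, seed = 1L,
                           nT = 10L, rowCut = 8L, colCut = 8L,
                           rulesets = NULL,
                           ruleTypes = c("zero_occupancy", "column_mode"),
                           reliabilityB = 500L, level = 0.95,
                           neighborMode = "corner", poolFactor = 2,
                           maxTries = 1000L, maxBins = 10L,
                           fitTolerance = 0.05) {
  coded <- encodeMatrix(data, maxBins = maxBins, fitTolerance = fitTolerance)
  tabA <- featurePairTable(coded, groupA[1L], groupA[2L])
  tabB <- featurePairTable(coded, groupB[1L], groupB[2L])
  if (is.null(rulesets)) {
    rulesets <- list(
      groupA = .autoCertify(tabA, ruleTypes, reliabilityB, level,
                            .childSeed(seed, 1L)),
      groupB = .autoCertify(tabB, ruleTypes, reliabilityB, level,
                            .childSeed(seed, 2L)))
  }
  lat <- buildLattice(coded, groupA, groupB)
  lat <- attachAxisTrees(
    lat,
    rowTree = hcTreeFromAdjacency(adjacencyMatrix(lat@rowCells, neighborMode)),
    colTree = hcTreeFromAdjacency(adjacencyMatrix(lat@colCells, neighborMode)))
  blocks <- partitionBlocks(lat, rowCut, list(tree_cut = colCut), coded)
  feats <- c(groupA, groupB)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    blocks[[i]]$cubes <- .blockCubes(lat, b, coded, feats)
    blocks[[i]]$intact <- b$size <= nT || length(b$rows) < 2L
    if (!blocks[[i]]$intact)
      blocks[[i]]$pca <- blockPCA(b, data, feats)
  }
  N <- nrow(data@values)
  mim <- list()
  violations <- numeric(0)
  attempts <- 0L
  while (length(mim) < nMimicries && attempts < maxTries) {
    attempts <- attempts + 1L
    vals <- data@values
    ok <- TRUE
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      if (b$intact) next                     # small block: copied verbatim
      pool <- mimicBlock(b$pca, b$cubes, B = ceiling(poolFactor * b$size),
                         seed = .childSeed(seed, attempts * 1000L + bi))
      if (nrow(pool) < b$size) { ok <- FALSE; break }
      take <- sample(nrow(pool), b$size)     # quota without replacement
      vals[b$rows, b$pca$features] <- pool[take, , drop = FALSE]
    }
    if (!ok) { violations <- .addViolations(violations, "block_pool"); next }
    newCodes <- coded@codes
    for (nm in feats)
      newCodes[, nm] <- binCode(coded@coders[[nm]], vals[[nm]])
    if (anyNA(newCodes)) { violations <- .addViolations(violations, "uncodable"); next }
    newCoded <- new("CodedMatrix", codes = newCodes, coders = coded@coders,
                    schema = coded@schema)
    chkA <- rulesSatisfied(featurePairTable(newCoded, groupA[1L], groupA[2L]),
                           rulesets$groupA)
    chkB <- rulesSatisfied(featurePairTable(newCoded, groupB[1L], groupB[2L]),
                           rulesets$groupB)
    if (!chkA$ok || !chkB$ok) {
      violations <- .addViolations(violations, c(chkA$violated, chkB$violated))
      next
    }
    mim[[length(mim) + 1L]] <- CedaMatrix(vals, data@schema)
  }
  .assert(length(mim) == nMimicries,
          "only %d of %d mimicries accepted within %d attempts",
          length(mim), nMimicries, maxTries)
  new("MimicryEnsemble", scenario = "II", mimicries = mim,
      attempts = attempts, accepted = length(mim), seed = as.integer(seed),
      violations = violations,
      config = list(groupA = groupA, groupB = groupB, nT = nT,
                    rowCut = rowCut, colCut = colCut, rulesets = rulesets,
                    lattice = lat, blocks = blocks, coded = coded,
                    neighborMode = neighborMode, poolFactor = poolFactor))
}

#' Mimicking protocol, scenario III: mixed feature types
#'
#' Combines the two pure protocols: the mixed pair's contingency table
#' (continuous bins by categories) is simulated under its certified rules;
#' the lattice of (continuous-pair cells) by (category, bin) cells is then
#' simulated column by column, with cells belonging to small blocks held at
#' their observed counts and the simulated row sums required to satisfy the
#' continuous pair's rules; continuous coordinates are mimicked per block
#' via PCA and kernel smoothing, and the simulated number of points is
#' simple-random-sampled from each (category-specific) block's mimicked
#' pool. Accepted mimicries are full N-row mixed-type matrices whose
#' re-coded tables satisfy every governing rule set.
#'
#' @param data a \linkS4class{CedaMatrix} with one categorical and several
#'   continuous features.
#' @param contGroup the two continuous features forming the row group.
#' @param mixedGroup `c(categorical, continuous)` forming the column group.
#' @param nMimicries,seed,nT,rowCut,maxTries,poolFactor,neighborMode as in
#'   [mimicScenario2()].
#' @param rulesets list with `cont` (continuous-pair table rules) and
#'   `mixed` (mixed-pair table rules); `NULL` auto-certifies.
#' @param ruleTypes,reliabilityB,level certification settings.
#' @param maxBins,fitTolerance histogram settings.
#' @return a \linkS4class{MimicryEnsemble} of \linkS4class{CedaMatrix}
#'   mimicries.
#' @export
mimicScenario3 <- function(data, contGroup, mixedGroup, nMimicries = 1L,
                           seed = 1L, nT = 10L, rowCut = 4L,
                           rulesets = NULL,
                           ruleTypes = c("zero_occupancy", "column_mode"),
                           reliabilityB = 500L, level = 0.95,
                           neighborMode = "corner", poolFactor = 3,
                           maxTries = 1000L, maxBins = 10L,
                           fitTolerance = 0.05) {
  sch <- data@schema
  catF <- mixedGroup[!.isQuantitative(sch@dtype[match(mixedGroup, sch@name)])]
  .assert(length(catF) == 1L, "mixedGroup needs exactly one categorical feature")
  quantF <- setdiff(mixedGroup, catF)
  coded <- encodeMatrix(data, maxBins = maxBins, fitTolerance = fitTolerance)
  tabCont <- featurePairTable(coded, contGroup[1L], contGroup[2L])
  tabMixed <- featurePairTable(coded, quantF, catF)  # rows: bins, cols: categories
  if (is.null(rulesets)) {
    rulesets <- list(
      cont = .autoCertify(tabCont, ruleTypes, reliabilityB, level,
                          .childSeed(seed, 1L)),
      mixed = .autoCertify(tabMixed, ruleTypes, reliabilityB, level,
                           .childSeed(seed, 2L)))
  }
  lat <- buildLattice(coded, contGroup, c(catF, quantF))
  rowTree <- hcTreeFromAdjacency(adjacencyMatrix(lat@rowCells, neighborMode))
  colOrd <- bivariateOrder(coded@coders[[catF]],
                           nCategories(coded@coders[[quantF]]), lat@colCells)
  lat <- attachAxisTrees(lat, rowTree = rowTree, colOrder = colOrd)
  blocks <- partitionBlocks(lat, rowCut, "per_category", coded)
  contFeats <- c(contGroup, quantF)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    blocks[[i]]$cubes <- .blockCubes(lat, b, coded, contFeats)
    blocks[[i]]$intact <- b$size <= nT || length(b$rows) < 2L
    if (!blocks[[i]]$intact)
      blocks[[i]]$pca <- blockPCA(b, data, contFeats)
  }
  # cell -> block lookup and the small-cell mask
  Lr <- nrow(lat@counts); Lc <- ncol(lat@counts)
  blockOf <- matrix(NA_integer_, Lr, Lc)
  for (bi in seq_along(blocks))
    blockOf[blocks[[bi]]$rowCells, blocks[[bi]]$colCells] <- bi
  intactIdx <- which(vapply(blocks, `[[`, logical(1), "intact"))
  smallMask <- matrix(FALSE, Lr, Lc)
  if (length(intactIdx))
    smallMask[] <- blockOf %in% intactIdx
  colCodes <- lat@colCells$codes                 # (category, bin)
  rowCodes <- lat@rowCells$codes                 # continuous pair bins
  catLevels <- coded@coders[[catF]]
  N <- nrow(data@values)
  # mixed-table cells whose lattice column lies entirely in intact blocks
  # keep their observed counts; only the remaining mass is simulated (in the
  # all-intact limit the mimicry is the original matrix)
  obsBig <- colSums(lat@counts * !smallMask)
  fixedCols <- which(obsBig == 0)
  fixedMixed <- matrix(0, nrow(tabMixed@counts), ncol(tabMixed@counts))
  if (length(fixedCols))
    fixedMixed[cbind(colCodes[fixedCols, 2L], colCodes[fixedCols, 1L])] <-
      lat@colCells$counts[fixedCols]
  freeMixed <- tabMixed@counts - fixedMixed
  .assert(all(freeMixed >= 0), "inconsistent lattice/table occupancy")
  totalFree <- sum(freeMixed)
  pFree <- if (totalFree > 0) as.vector(freeMixed) / totalFree else NULL
  mim <- list()
  violations <- numeric(0)
  attempts <- 0L
  while (length(mim) < nMimicries && attempts < maxTries) {
    attempts <- attempts + 1L
    set.seed(.childSeed(seed, attempts))
    # step 1: simulate the mixed-pair table under its rules (single draw gate)
    sMixed <- fixedMixed
    if (totalFree > 0)
      sMixed <- sMixed + matrix(stats::rmultinom(1L, totalFree, pFree),
                                nrow(tabMixed@counts), ncol(tabMixed@counts))
    chk <- rulesSatisfied(sMixed, rulesets$mixed)
    if (!chk$ok) { violations <- .addViolations(violations, chk$violated); next }
    # step 2: column-by-column lattice simulation; small-block cells stay at
    # their observed counts, the remainder follows the observed conditionals
    sLat <- matrix(0, Lr, Lc)
    ok <- TRUE
    for (c in seq_len(Lc)) {
      tc <- sMixed[colCodes[c, 2L], colCodes[c, 1L]]
      smallRows <- which(smallMask[, c])
      oSmall <- sum(lat@counts[smallRows, c])
      if (tc < oSmall) { ok <- FALSE; break }
      sLat[smallRows, c] <- lat@counts[smallRows, c]
      rest <- tc - oSmall
      if (rest > 0) {
        bigRows <- which(!smallMask[, c])
        pc <- lat@counts[bigRows, c]
        if (sum(pc) == 0) { ok <- FALSE; break }
        sLat[bigRows, c] <- stats::rmultinom(1L, rest, pc / sum(pc))
      }
    }
    if (!ok) { violations <- .addViolations(violations, "column_totals"); next }
    # row-sum check against the continuous pair's certified rules
    tCont <- matrix(0, nrow(tabCont@counts), ncol(tabCont@counts))
    tCont[rowCodes] <- tCont[rowCodes] + rowSums(sLat)
    chk <- rulesSatisfied(tCont, rulesets$cont)
    if (!chk$ok) { violations <- .addViolations(violations, chk$violated); next }
    # step 3: mimic each big block, then simple-random-sample the
    # simulated number of points from the block's mimicked pool (the block
    # is category-specific, so the category label is the block's own; the
    # quantitative bin composition the pool delivers is vetted by the rule
    # checks at acceptance)
    pieces <- list()
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      if (b$intact) {
        pieces[[length(pieces) + 1L]] <- data@values[b$rows, , drop = FALSE]
        next
      }
      need <- sum(sLat[b$rowCells, b$colCells])
      if (need == 0) next
      pool <- mimicBlock(b$pca, b$cubes, B = ceiling(poolFactor * need),
                         seed = .childSeed(seed, attempts * 1000L + bi))
      if (nrow(pool) < need) { ok <- FALSE; break }
      take <- sample.int(nrow(pool), need)
      piece <- as.data.frame(pool[take, , drop = FALSE])
      piece[[catF]] <- rep(catLevels[b$colGroup], need)
      pieces[[length(pieces) + 1L]] <- piece[, sch@name, drop = FALSE]
    }
    if (!ok) { violations <- .addViolations(violations, "block_pool"); next }
    vals <- do.call(rbind, pieces)
    rownames(vals) <- NULL
    if (nrow(vals) != N) { violations <- .addViolations(violations, "row_total"); next }
    mimMat <- CedaMatrix(vals, sch)
    newCoded <- encodeWithCoders(mimMat, coded@coders)
    if (is.null(newCoded)) { violations <- .addViolations(violations, "uncodable"); next }
    chkC <- rulesSatisfied(featurePairTable(newCoded, contGroup[1L],
                                            contGroup[2L]), rulesets$cont)
    chkM <- rulesSatisfied(featurePairTable(newCoded, quantF, catF),
                           rulesets$mixed)
    if (!chkC$ok || !chkM$ok) {
      violations <- .addViolations(violations, c(chkC$violated, chkM$violated))
      next
    }
    mim[[length(mim) + 1L]] <- mimMat
  }
  .assert(length(mim) == nMimicries,
          "only %d of %d mimicries accepted within %d attempts",
          length(mim), nMimicries, maxTries)
  new("MimicryEnsemble", scenario = "III", mimicries = mim,
      attempts = attempts, accepted = length(mim), seed = as.integer(seed),
      violations = violations,
      config = list(contGroup = contGroup, mixedGroup = mixedGroup, nT = nT,
                    rowCut = rowCut, rulesets = rulesets, lattice = lat,
                    blocks = blocks, coded = coded))
}

#' Re-code a data matrix with existing coders
#'
#' Applies a previously fitted set of coders (histograms / label maps) to a
#' new matrix of the same schema — the step that checks a mimicry against
#' the original categorization.
#'
#' @param matrix a \linkS4class{CedaMatrix}.
#' @param coders named coder list from an existing
#'   \linkS4class{CodedMatrix}.
#' @return a \linkS4class{CodedMatrix}, or `NULL` if any value is
#'   uncodable (falls in a gap or outside all bins).
#' @export
encodeWithCoders <- function(matrix, coders) {
  sch <- matrix@schema
  codes <- base::matrix(NA_integer_, nrow(matrix@values), length(sch@name),
                        dimnames = list(NULL, sch@name))
  for (nm in sch@name) {
    co <- coders[[nm]]
    codes[, nm] <- if (is.character(co)) match(matrix@values[[nm]], co)
                   else binCode(co, matrix@values[[nm]])
  }
  if (anyNA(codes)) return(NULL)
  new("CodedMatrix", codes = codes, coders = coders[sch@name], schema = sch)
}

#' Acceptance report of a mimicry ensemble
#'
#' @param ensemble a \linkS4class{MimicryEnsemble}.
#' @return list with `acceptanceRate`, `accepted`, `attempts`, and the
#'   per-rule `violations` tally.
#' @export
acceptanceStats <- function(ensemble) {
  .assert(ensemble@attempts >= 1L, "ensemble has no attempts recorded")
  list(acceptanceRate = ensemble@accepted / ensemble@attempts,
       accepted = ensemble@accepted, attempts = ensemble@attempts,
       violations = ensemble@violations)
}

#' Acceptance rate of unconstrained resampling under certified rules
#'
#' Bootstraps the rows of a coded matrix B times; for each replicate,
#' recomputes the governing pair tables and checks every rule set. The
#' returned rate is the fraction of plain resampled matrices that would be
#' accepted — the diagnostic contrasting simple resampling with rule-guided
#' mimicking.
#'
#' @param coded a \linkS4class{CodedMatrix}.
#' @param pairs list of feature pairs, aligned with `rulesets`.
#' @param rulesets list of \linkS4class{RuleSet} objects.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @return acceptance rate in `[0, 1]`.
#' @export
resampleAcceptance <- function(coded, pairs, rulesets, B = 200L, seed = 1L) {
  .assert(length(pairs) == length(rulesets), "pairs and rulesets must align")
  set.seed(seed)
  N <- nrow(coded@codes)
  okCount <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(N, N, replace = TRUE)
    boot <- new("CodedMatrix", codes = coded@codes[idx, , drop = FALSE],
                coders = coded@coders, schema = coded@schema)
    ok <- TRUE
    for (i in seq_along(pairs)) {
      tab <- featurePairTable(boot, pairs[[i]][1L], pairs[[i]][2L])
      if (!rulesSatisfied(tab, rulesets[[i]])$ok) { ok <- FALSE; break }
    }
    okCount <- okCount + ok
  }
  okCount / B
}
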