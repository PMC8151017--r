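# Categorical patterns as testable rules, certified by bootstrap
# reliability. A rule's predicate is a pure function of a contingency
# table's count matrix.

.ruleId <- function(rule) {
  loc <- if (!is.null(rule$column)) sprintf("[c%d]", rule$column) else ""
  paste0(rule$type, loc, "@", rule$scope)
}

# Predicate dispatcher: does `rule` hold on count matrix `counts`?
.ruleHolds <- function(rule, counts) {
  switch(rule$type,
    zero_occupancy = all(counts[rule$cells] == 0),
    column_mode = {
      cj <- counts[, rule$column]
      rest <- cj[-rule$modeRow]
      cj[rule$modeRow] > 0 && (length(rest) == 0L || cj[rule$modeRow] > max(rest))
    },
    column_top_order = {
      cj <- counts[, rule$column]
      top <- cj[rule$order]
      rest <- cj[-rule$order]
      all(diff(top) < 0) &&
        (length(rest) == 0L || top[length(top)] > max(rest))
    },
    column_unimodal = .isUnimodal(counts[, rule$column]),
    composite_mass = {
      cj <- counts[, rule$column]
      tot <- sum(cj)
      tot == 0 || sum(cj[rule$rows]) / tot >= rule$theta
    },
    tautology = TRUE,
    stop("unknown rule type: ", rule$type))
}

# Strict up-then-down over the contiguous support (leading/trailing zeros
# allowed, internal zeros or plateaus break unimodality).
.isUnimodal <- function(cj) {
  pos <- which(cj > 0)
  if (length(pos) == 0L) return(TRUE)       # empty column: vacuous
  seg <- cj[pos[1L]:pos[length(pos)]]
  if (any(seg == 0)) return(FALSE)
  if (length(seg) == 1L) return(TRUE)
  d <- diff(seg)
  if (any(d == 0)) return(FALSE)
  up <- d > 0
  peak <- which(!up)
  length(peak) == 0L || all(!up[peak[1L]:length(up)])
}

#' Extract candidate categorical patterns from a contingency table
#'
#' Reads off the observed pattern families: zero cells (one rule listing
#' all of them), column-wise strict modes, strict top-r orderings,
#' column-wise unimodality (only meaningful over an ordered row axis), and
#' composite-category mass (the smallest set of top rows capturing at least
#' `theta` of a column's mass). Every emitted rule holds on the observed
#' table by construction; mode and ordering rules are emitted only for
#' strict inequalities, so ties yield no rule.
#'
#' @param table a \linkS4class{ContingencyTable}.
#' @param types subset of `c("zero_occupancy", "column_mode",
#'   "column_top_order", "column_unimodal", "composite_mass")`.
#' @param r top-order depth (default 3).
#' @param theta composite-mass level (default 0.8).
#' @param orderedRows is the row axis ordered (quantitative/ordinal)?
#'   Unimodality rules are emitted only if `TRUE`.
#' @param scope scope id recorded on each rule (default `"table"`).
#' @return list of rule records.
#' @export
extractPatterns <- function(table,
                            types = c("zero_occupancy", "column_mode",
                                      "column_top_order", "column_unimodal",
                                      "composite_mass"),
                            r = 3L, theta = 0.8, orderedRows = FALSE,
                            scope = "table") {
  counts <- table@counts
  .assert(sum(counts) > 0, "empty table")
  if ("column_top_order" %in% types)
    .assert(r >= 1L && r <= nrow(counts), "r larger than column length")
  rules <- list()
  add <- function(rule) rules[[length(rules) + 1L]] <<- rule
  if ("zero_occupancy" %in% types) {
    z <- which(counts == 0, arr.ind = TRUE)
    if (nrow(z)) add(list(type = "zero_occupancy", scope = scope,
                          cells = unname(z)))
  }
  for (j in seq_len(ncol(counts))) {
    cj <- counts[, j]
    if (sum(cj) == 0) next
    if ("column_mode" %in% types) {
      mx <- which(cj == max(cj))
      if (length(mx) == 1L)
        add(list(type = "column_mode", scope = scope, column = j,
                 modeRow = mx))
    }
    if ("column_top_order" %in% types && sum(cj > 0) >= r) {
      ordRows <- order(-cj, seq_along(cj))[seq_len(r)]
      cand <- list(type = "column_top_order", scope = scope, column = j,
                   order = ordRows)
      if (.ruleHolds(cand, counts)) add(cand)
    }
    if ("column_unimodal" %in% types && orderedRows && sum(cj > 0) >= 2L) {
      cand <- list(type = "column_unimodal", scope = scope, column = j)
      if (.ruleHolds(cand, counts)) add(cand)
    }
    if ("composite_mass" %in% types) {
      ordRows <- order(-cj, seq_along(cj))
      cum <- cumsum(cj[ordRows]) / sum(cj)
      need <- which(cum >= theta)[1L]
      if (!is.na(need) && need < nrow(counts))
        add(list(type = "composite_mass", scope = scope, column = j,
                 rows = sort(ordRows[seq_len(need)]), theta = theta))
    }
  }
  rules
}

# Simulate B resampled count matrices from an observed table.
# bootstrap: multinomial over the empirical joint (simple random sampling
# of N rows with replacement); independence: product of the marginals.
.simulateTables <- function(counts, B, scheme = c("bootstrap", "independence")) {
  scheme <- match.arg(scheme)
  N <- sum(counts)
  p <- if (scheme == "bootstrap") as.vector(counts) / N
       else as.vector(outer(rowSums(counts), colSums(counts))) / N^2
  draws <- stats::rmultinom(B, N, p)
  lapply(seq_len(B), function(b)
    matrix(draws[, b], nrow(counts), ncol(counts)))
}

#' Reliability of a rule under resampling
#'
#' Fraction of B resampled datasets (N observations redrawn from the
#' observed joint code distribution; equivalently a row bootstrap) whose
#' recomputed contingency table still satisfies the rule's predicate.
#'
#' @param rule a rule record (from [extractPatterns()] or hand-written).
#' @param table the observed \linkS4class{ContingencyTable}.
#' @param B ensemble size (default 500).
#' @param seed integer seed; reliability is deterministic given
#'   (table, B, seed).
#' @param scheme `"bootstrap"` (default) or `"independence"` (product-null
#'   resampling).
#' @return reliability in `[0, 1]`.
#' @export
ruleReliability <- function(rule, table, B = 500L, seed = 1L,
                            scheme = c("bootstrap", "independence")) {
  .assert(B >= 1L, "B must be at least 1")
  set.seed(seed)
  sims <- .simulateTables(table@counts, B, scheme)
  mean(vapply(sims, function(cm) .ruleHolds(rule, cm), logical(1)))
}

#' Certify candidate rules at a reliability level
#'
#' Computes all candidates' reliabilities on one shared resampling ensemble
#' and retains those at or above `level` (default 95%); rejected candidates
#' are kept, with their reliabilities, for inspection.
#'
#' @param candidates list of rule records.
#' @param table the observed \linkS4class{ContingencyTable}.
#' @param B ensemble size (default 500).
#' @param level certification level (default 0.95).
#' @param seed integer seed.
#' @param scheme resampling scheme, see [ruleReliability()].
#' @return a \linkS4class{RuleSet}.
#' @export
certifyRules <- function(candidates, table, B = 500L, level = 0.95,
                         seed = 1L, scheme = c("bootstrap", "independence")) {
  scheme <- match.arg(scheme)
  if (length(candidates) == 0L)
    return(new("RuleSet", rules = list(), rejected = list(), level = level,
               B = as.integer(B), scheme = scheme, seed = as.integer(seed)))
  set.seed(seed)
  sims <- .simulateTables(table@counts, B, scheme)
  rel <- vapply(candidates, function(rule)
    mean(vapply(sims, function(cm) .ruleHolds(rule, cm), logical(1))),
    numeric(1))
  keep <- rel >= level
  rules <- mapply(function(rule, rl) { rule$reliability <- rl; rule },
                  candidates[keep], rel[keep], SIMPLIFY = FALSE)
  rej <- mapply(function(rule, rl) { rule$reliability <- rl; rule },
                candidates[!keep], rel[!keep], SIMPLIFY = FALSE)
  new("RuleSet", rules = rules, rejected = rej, level = level,
      B = as.integer(B), scheme = scheme, seed = as.integer(seed))
}

#' Check a table against a rule set
#'
#' @param table a \linkS4class{ContingencyTable} (or bare count matrix of
#'   matching shape).
#' @param ruleset a \linkS4class{RuleSet}.
#' @return list with `ok` (all rules hold) and `violated` (ids of failing
#'   rules).
#' @export
rulesSatisfied <- function(table, ruleset) {
  counts <- if (is(table, "ContingencyTable")) table@counts else table
  bad <- character(0)
  for (rule in ruleset@rules)
    if (!.ruleHolds(rule, counts)) bad <- c(bad, .ruleId(rule))
  list(ok = length(bad) == 0L, violated = bad)
}

#' Serialize / read a rule set as JSON
#'
#' @param ruleset a \linkS4class{RuleSet}.
#' @param path JSON path.
#' @export
writeRuleSet <- function(ruleset, path) {
  enc <- function(rule) {
    out <- rule
    if (!is.null(out$cells))
      out$cells <- lapply(seq_len(nrow(out$cells)), function(i)
        as.integer(out$cells[i, ]))
    out
  }
  jsonlite::write_json(list(
    level = ruleset@level, B = ruleset@B, scheme = ruleset@scheme,
    seed = ruleset@seed, rules = lapply(ruleset@rules, enc),
    rejected = lapply(ruleset@rejected, enc)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRuleSet
#' @export
readRuleSet <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dec <- function(rule) {
    if (!is.null(rule$cells))
      rule$cells <- do.call(rbind, lapply(rule$cells, function(x)
        as.integer(unlist(x))))
    for (f in c("column", "modeRow", "order", "rows"))
      if (!is.null(rule[[f]])) rule[[f]] <- as.integer(unlist(rule[[f]]))
    for (f in c("theta", "reliability"))
      if (!is.null(rule[[f]])) rule[[f]] <- as.numeric(unlist(rule[[f]]))
    for (f in c("type", "scope"))
      rule[[f]] <- as.character(unlist(rule[[f]]))
    rule
  }
  new("RuleSet", rules = lapply(js$rules, dec),
      rejected = lapply(js$rejected, dec),
      level = as.numeric(js$level), B = as.integer(js$B),
      scheme = as.character(js$scheme), seed = as.integer(js$seed))
}
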