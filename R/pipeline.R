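#' Run the full CEDA-with-mimicking pipeline
#'
#' Sequences the stages on one data matrix: categorization (possibly-gapped
#' histograms), the MCE matrix with its HC-tree and heatmap permutation,
#' the directed association network, and — when a scenario is requested —
#' rule certification and the corresponding mimicking protocol. All
#' artifacts are written under `config$outDir`; a manifest records every
#' configuration value, the seed, and the acceptance statistics, so a rerun
#' with the same config is byte-identical.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{data}{a \linkS4class{CedaMatrix}, or `dataPath` +
#'       `schemaPath` to read one.}
#'     \item{outDir}{output directory (created).}
#'     \item{seed}{integer seed (mandatory).}
#'     \item{maxBins, fitTolerance}{histogram settings (10, 0.05).}
#'     \item{mceVariant, linkage}{`"average"`/`"min"`; `"single"` etc.}
#'     \item{scenario}{`NULL`, `"I"`, `"II"` or `"III"`.}
#'     \item{scenarioArgs}{list passed to the scenario driver (feature
#'       groups, `nT`, cuts, ...).}
#'     \item{nMimicries}{ensemble size (default 10 when a scenario is
#'       set).}
#'   }
#' @return invisibly, a list with the coded matrix, MCE results, and (if
#'   run) the mimicry ensemble.
#' @export
runPipeline <- function(config) {
  .assert(!is.null(config$seed), "config$seed is mandatory")
  data <- config[["data"]]
  if (is.null(data)) {
    .assert(!is.null(config$dataPath) && !is.null(config$schemaPath),
            "config needs either data or dataPath + schemaPath")
    data <- readMatrix(config$dataPath, config$schemaPath)
  }
  outDir <- config$outDir
  .assert(!is.null(outDir), "config$outDir is mandatory")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  maxBins <- config$maxBins %||% 10L
  fitTol <- config$fitTolerance %||% 0.05
  coded <- encodeMatrix(data, maxBins = maxBins, fitTolerance = fitTol)
  hists <- Filter(function(x) is(x, "GappedHistogram"), coded@coders)
  if (length(hists)) writeHistograms(hists, file.path(outDir, "histograms.json"))
  mce <- mceMatrix(coded, variant = config$mceVariant %||% "average")
  writeMCE(mce, file.path(outDir, "mce.csv"))
  hm <- mceHeatmap(mce, linkage = config$linkage %||% "single")
  writeNewick(hm$tree, file.path(outDir, "tree.nwk"))
  writeMCE(hm$permuted, file.path(outDir, "mce_permuted.csv"))
  net <- directedNetwork(directionalRatios(coded))
  utils::write.csv(net, file.path(outDir, "network.csv"), row.names = FALSE)
  ensemble <- NULL
  if (!is.null(config$scenario)) {
    nM <- config$nMimicries %||% 10L
    args <- config$scenarioArgs %||% list()
    if (config$scenario == "I" && is.null(args$rulesets)) {
      # certify the standard pattern families on the three pair tables
      prs <- list(c(args$pairFeatures[1], args$pairFeatures[2]),
                  c(args$thirdFeature, args$pairFeatures[1]),
                  c(args$thirdFeature, args$pairFeatures[2]))
      certified <- lapply(seq_along(prs), function(i) {
        tb <- featurePairTable(coded, prs[[i]][1], prs[[i]][2])
        certifyRules(extractPatterns(tb), tb,
                     B = config$reliabilityB %||% 500L,
                     level = config$level %||% 0.95,
                     seed = .childSeed(config$seed, 500L + i))
      })
      args$rulesets <- list(pair = certified[[1]], crossA = certified[[2]],
                            crossB = certified[[3]])
    }
    ensemble <- switch(config$scenario,
      I = do.call(mimicScenario1, c(list(coded = coded,
            nMimicries = nM, seed = config$seed), args)),
      II = do.call(mimicScenario2, c(list(data = data,
            nMimicries = nM, seed = config$seed, maxBins = maxBins,
            fitTolerance = fitTol), args)),
      III = do.call(mimicScenario3, c(list(data = data,
            nMimicries = nM, seed = config$seed, maxBins = maxBins,
            fitTolerance = fitTol), args)),
      stop("unknown scenario: ", config$scenario))
    mimDir <- file.path(outDir, "mimicries")
    dir.create(mimDir, showWarnings = FALSE)
    for (i in seq_along(ensemble@mimicries)) {
      m <- ensemble@mimicries[[i]]
      fp <- file.path(mimDir, sprintf("mimicry_%03d.csv", i))
      if (is(m, "CedaMatrix")) writeMatrix(m, fp)
      else utils::write.csv(as.data.frame(m@codes), fp, row.names = FALSE)
    }
    for (nm in names(ensemble@config$rulesets)) {
      rs <- ensemble@config$rulesets[[nm]]
      if (is(rs, "RuleSet"))
        writeRuleSet(rs, file.path(outDir, sprintf("rules_%s.json", nm)))
    }
    stats <- acceptanceStats(ensemble)
    jsonlite::write_json(list(
      seed = config$seed, scenario = config$scenario,
      maxBins = maxBins, fitTolerance = fitTol,
      mceVariant = config$mceVariant %||% "average",
      linkage = config$linkage %||% "single",
      nMimicries = nM,
      scenarioArgs = Filter(function(a) !is.object(a) && !is.list(a),
                            args[setdiff(names(args), "rulesets")]),
      acceptanceRate = stats$acceptanceRate,
      accepted = stats$accepted, attempts = stats$attempts,
      violations = as.list(stats$violations)),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(list(data = data, coded = coded, mce = mce, heatmap = hm,
                 network = net, ensemble = ensemble))
}
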