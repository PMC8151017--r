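#' Number of categories a coder supports
#'
#' @param x a coder: a \linkS4class{GappedHistogram} or a character vector of
#'   category labels.
#' @return integer count of bins/categories.
#' @export
setGeneric("nCategories", function(x) standardGeneric("nCategories"))

#' @rdname nCategories
setMethod("nCategories", "GappedHistogram", function(x) length(x@left))

#' @rdname nCategories
setMethod("nCategories", "character", function(x) length(x))

#' Feature names of a CEDA object
#' @param x a \linkS4class{FeatureSchema}, \linkS4class{CedaMatrix},
#'   \linkS4class{CodedMatrix} or \linkS4class{MCEMatrix}.
#' @return character vector of feature names.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname featureNames
setMethod("featureNames", "FeatureSchema", function(x) x@name)
#' @rdname featureNames
setMethod("featureNames", "CedaMatrix", function(x) x@schema@name)
#' @rdname featureNames
setMethod("featureNames", "CodedMatrix", function(x) x@schema@name)
#' @rdname featureNames
setMethod("featureNames", "MCEMatrix", function(x) rownames(x@entries))

#' Accessors for CEDA containers
#'
#' Slot access for the central classes: `dataValues` (the raw data.frame),
#' `featureSchema`, `codeMatrix` (integer codes), `coderList`,
#' `tableCounts` (counts of a table or lattice), `mceEntries`,
#' `ruleList`, `rejectedRules`, `mimicries`, `acceptanceRate`.
#'
#' @param x the object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dataValues", function(x) standardGeneric("dataValues"))
#' @rdname accessors
setMethod("dataValues", "CedaMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("featureSchema", function(x) standardGeneric("featureSchema"))
#' @rdname accessors
setMethod("featureSchema", "CedaMatrix", function(x) x@schema)
#' @rdname accessors
setMethod("featureSchema", "CodedMatrix", function(x) x@schema)

#' @rdname accessors
#' @export
setGeneric("codeMatrix", function(x) standardGeneric("codeMatrix"))
#' @rdname accessors
setMethod("codeMatrix", "CodedMatrix", function(x) x@codes)

#' @rdname accessors
#' @export
setGeneric("coderList", function(x) standardGeneric("coderList"))
#' @rdname accessors
setMethod("coderList", "CodedMatrix", function(x) x@coders)

#' @rdname accessors
#' @export
setGeneric("tableCounts", function(x) standardGeneric("tableCounts"))
#' @rdname accessors
setMethod("tableCounts", "ContingencyTable", function(x) x@counts)
#' @rdname accessors
setMethod("tableCounts", "ContingencyLattice", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("mceEntries", function(x) standardGeneric("mceEntries"))
#' @rdname accessors
setMethod("mceEntries", "MCEMatrix", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("ruleList", function(x) standardGeneric("ruleList"))
#' @rdname accessors
setMethod("ruleList", "RuleSet", function(x) x@rules)

#' @rdname accessors
#' @export
setGeneric("rejectedRules", function(x) standardGeneric("rejectedRules"))
#' @rdname accessors
setMethod("rejectedRules", "RuleSet", function(x) x@rejected)

#' @rdname accessors
#' @export
setGeneric("mimicries", function(x) standardGeneric("mimicries"))
#' @rdname accessors
setMethod("mimicries", "MimicryEnsemble", function(x) x@mimicries)

#' @rdname accessors
#' @export
setGeneric("acceptanceRate", function(x) standardGeneric("acceptanceRate"))
#' @rdname accessors
setMethod("acceptanceRate", "MimicryEnsemble",
          function(x) x@accepted / x@attempts)

#' @describeIn CedaMatrix dimensions of the data matrix
#' @param x a CedaMatrix
#' @export
setMethod("dim", "CedaMatrix", function(x) dim(x@values))

#' @describeIn CodedMatrix dimensions of the code matrix
#' @param x a CodedMatrix
#' @export
setMethod("dim", "CodedMatrix", function(x) dim(x@codes))

setMethod("show", "FeatureSchema", function(object) {
  cat("FeatureSchema with", length(object@name), "features\n")
  for (k in seq_along(object@name))
    cat(sprintf("  %s <%s>\n", object@name[k], object@dtype[k]))
})

setMethod("show", "CedaMatrix", function(object) {
  cat(sprintf("CedaMatrix: %d subjects x %d features (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(object@schema@dtype, collapse = ", ")))
})

setMethod("show", "GappedHistogram", function(object) {
  cat(sprintf("GappedHistogram: %d bins, %d gaps, n = %d\n",
              length(object@left), sum(object@gapAfter), sum(object@counts)))
})

setMethod("show", "CodedMatrix", function(object) {
  cat(sprintf("CodedMatrix: %d x %d codes\n",
              nrow(object@codes), ncol(object@codes)))
})

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable %d x %d, n = %d\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts)))
})

setMethod("show", "ContingencyLattice", function(object) {
  cat(sprintf("ContingencyLattice %d x %d cells, N = %d, k = %d\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts),
              length(object@rowCells$features) +
                length(object@colCells$features)))
})

setMethod("show", "MCEMatrix", function(object) {
  cat(sprintf("MCEMatrix (%s) over %d features\n", object@variant,
              nrow(object@entries)))
  print(round(object@entries, 3))
})

setMethod("show", "RuleSet", function(object) {
  cat(sprintf("RuleSet: %d certified rules (level %.2f, B = %d, %s)\n",
              length(object@rules), object@level, object@B, object@scheme))
})

setMethod("show", "MimicryEnsemble", function(object) {
  cat(sprintf(
    "MimicryEnsemble scenario %s: %d accepted / %d attempts (rate %.3f)\n",
    object@scenario, object@accepted, object@attempts,
    object@accepted / object@attempts))
})
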