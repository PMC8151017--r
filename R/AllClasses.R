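#' @import methods
NULL

.DTYPES <- c("continuous", "discrete", "categorical_nominal", "categorical_ordinal")

#' Feature schema for a mixed-type data matrix
#'
#' Per-column type declarations for a \linkS4class{CedaMatrix}: each feature
#' is continuous, discrete, categorical-nominal, or categorical-ordinal.
#' Ordinal features must declare the full order of their observed labels;
#' nominal features may declare one (it then fixes axis order).
#'
#' @slot name character vector of unique feature names.
#' @slot dtype character vector, one of `continuous`, `discrete`,
#'   `categorical_nominal`, `categorical_ordinal`.
#' @slot categoryOrder named list; for categorical features an ordered
#'   character vector of labels (mandatory for ordinal).
#' @exportClass FeatureSchema
setClass("FeatureSchema",
  representation(name = "character", dtype = "character",
                 categoryOrder = "list"))

setValidity("FeatureSchema", function(object) {
  msg <- character()
  if (anyDuplicated(object@name)) msg <- c(msg, "feature names must be unique")
  if (length(object@dtype) != length(object@name))
    msg <- c(msg, "dtype and name lengths differ")
  bad <- setdiff(object@dtype, .DTYPES)
  if (length(bad))
    msg <- c(msg, paste0("unknown dtype(s): ", paste(bad, collapse = ", ")))
  ord <- object@name[object@dtype == "categorical_ordinal"]
  noOrder <- ord[!vapply(ord, function(nm)
    length(object@categoryOrder[[nm]]) > 0, logical(1))]
  if (length(noOrder))
    msg <- c(msg, paste0("ordinal feature(s) without category_order: ",
                         paste(noOrder, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' A validated N x K mixed-type data matrix
#'
#' The basic CEDA data container: a rectangular matrix of N subjects by K
#' features, values numeric or labels, together with its
#' \linkS4class{FeatureSchema}. Validation guarantees there are no missing
#' values and that every categorical value appears in its schema's label set.
#'
#' @slot values data.frame, N rows by K columns.
#' @slot schema a \linkS4class{FeatureSchema} covering all K columns.
#' @exportClass CedaMatrix
setClass("CedaMatrix",
  representation(values = "data.frame", schema = "FeatureSchema"))

setValidity("CedaMatrix", function(object) {
  v <- object@values; sch <- object@schema
  msg <- character()
  if (nrow(v) < 1L || ncol(v) < 1L) msg <- c(msg, "need N >= 1 and K >= 1")
  if (!identical(colnames(v), sch@name))
    msg <- c(msg, "column names do not match schema")
  if (anyNA(v)) {
    idx <- which(is.na(v), arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf("missing value at row %d, column '%s'",
                          idx[1L], colnames(v)[idx[2L]]))
  }
  for (k in seq_along(sch@name)) {
    dt <- sch@dtype[k]
    if (dt %in% c("continuous", "discrete")) {
      if (!is.numeric(v[[k]]))
        msg <- c(msg, sprintf("column '%s' declared %s but not numeric",
                              sch@name[k], dt))
    } else {
      lev <- sch@categoryOrder[[sch@name[k]]]
      if (length(lev)) {
        bad <- setdiff(unique(as.character(v[[k]])), lev)
        if (length(bad))
          msg <- c(msg, sprintf("column '%s' has out-of-schema label(s): %s",
                                sch@name[k], paste(bad, collapse = ", ")))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Possibly-gapped histogram of a 1D feature
#'
#' A partition of a feature's observed range into ordered, disjoint
#' half-open bins `[left, right)` (the last bin right-closed so the maximum
#' is covered), allowing empty gaps between consecutive bins. Bins are
#' chosen so each bin's empirical-CDF segment is close to linear.
#'
#' @slot left,right numeric bin edges, ascending, pairwise disjoint.
#' @slot counts integer per-bin data counts, summing to the input size.
#' @slot gapAfter logical; `gapAfter[j]` flags an empty gap between bin j
#'   and bin j+1 (last element always `FALSE`).
#' @exportClass GappedHistogram
setClass("GappedHistogram",
  representation(left = "numeric", right = "numeric",
                 counts = "integer", gapAfter = "logical"))

setValidity("GappedHistogram", function(object) {
  m <- length(object@left)
  msg <- character()
  if (length(object@right) != m || length(object@counts) != m ||
      length(object@gapAfter) != m)
    msg <- c(msg, "slot lengths disagree")
  if (m >= 1L && any(object@right <= object@left))
    msg <- c(msg, "bins must have positive width")
  if (m >= 2L && any(object@left[-1L] < object@right[-m]))
    msg <- c(msg, "bins must be disjoint and ascending")
  if (m >= 1L && object@gapAfter[m]) msg <- c(msg, "last gapAfter must be FALSE")
  if (length(msg)) msg else TRUE
})

#' Categorized (coded) version of a data matrix
#'
#' Integer codes for every cell of a \linkS4class{CedaMatrix}: continuous and
#' discrete columns are coded by their possibly-gapped histograms, categorical
#' columns identity-coded against their label order.
#'
#' @slot codes integer N x K matrix of 1-based bin/category indices.
#' @slot coders named list, one per column: a \linkS4class{GappedHistogram}
#'   or a character vector of ordered category labels.
#' @slot schema the originating \linkS4class{FeatureSchema}.
#' @exportClass CodedMatrix
setClass("CodedMatrix",
  representation(codes = "matrix", coders = "list", schema = "FeatureSchema"))

setValidity("CodedMatrix", function(object) {
  msg <- character()
  if (!is.integer(object@codes)) msg <- c(msg, "codes must be integer")
  if (length(object@coders) != ncol(object@codes))
    msg <- c(msg, "one coder per column required")
  for (k in seq_along(object@coders)) {
    nm <- nCategories(object@coders[[k]])
    ck <- object@codes[, k]
    if (any(ck < 1L | ck > nm))
      msg <- c(msg, sprintf("column %d has codes outside 1..%d", k, nm))
  }
  if (length(msg)) msg else TRUE
})

#' Contingency table of two coded features
#'
#' Counts `n[j, j']` of subjects falling jointly into bin j of the row
#' feature and bin j' of the column feature; the platform on which
#' directional conditional entropies, rules, and mimicking operate.
#'
#' @slot counts non-negative m x m' count matrix with dimnames.
#' @exportClass ContingencyTable
setClass("ContingencyTable", representation(counts = "matrix"))

setValidity("ContingencyTable", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' Mutual conditional entropy matrix
#'
#' Symmetric K x K matrix of mutual conditional entropies (MCE): the average
#' (or minimum) of the two directional re-scaled conditional Shannon
#' entropies of each feature pair. 0 means deterministic association, 1
#' independence. Serves as the distance matrix behind the CEDA road map.
#'
#' @slot entries symmetric numeric matrix in \[0, 1\], zero diagonal.
#' @slot variant `"average"` or `"min"`.
#' @slot degenerate logical per feature: marginal entropy zero (constant
#'   feature), for which the conventions ratio = 1 applies.
#' @exportClass MCEMatrix
setClass("MCEMatrix",
  representation(entries = "matrix", variant = "character",
                 degenerate = "logical"))

setValidity("MCEMatrix", function(object) {
  e <- object@entries
  msg <- character()
  if (nrow(e) != ncol(e)) msg <- c(msg, "entries must be square")
  if (max(abs(e - t(e))) > 1e-12) msg <- c(msg, "entries must be symmetric")
  if (any(abs(diag(e)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (any(e < -1e-12 | e > 1 + 1e-9)) msg <- c(msg, "entries must lie in [0,1]")
  if (!object@variant %in% c("average", "min")) msg <- c(msg, "bad variant")
  if (length(msg)) msg else TRUE
})

#' Contingency-kD-lattice
#'
#' A large contingency table whose row axis carries the occupied cells of one
#' feature group (k1 features) and whose column axis carries the occupied
#' cells of a second, disjoint group (k2 features); displays order-(k1+k2)
#' structural dependency. Axis trees/orders, once attached, drive the heatmap
#' permutation and the block partition.
#'
#' @slot counts |rows| x |cols| count matrix.
#' @slot rowCells,colCells occupied-cell sets as returned by
#'   [buildGroupCells()].
#' @slot rowAssign,colAssign integer per data row: index of its row/column
#'   cell.
#' @slot rowTree,colTree an `hclust` (or single-leaf stand-in) or `NULL`.
#' @slot colOrder integer explicit column order (used for mixed-type column
#'   groups in place of a tree), or length 0.
#' @exportClass ContingencyLattice
setClass("ContingencyLattice",
  representation(counts = "matrix", rowCells = "list", colCells = "list",
                 rowAssign = "integer", colAssign = "integer",
                 rowTree = "ANY", colTree = "ANY", colOrder = "integer"))

setValidity("ContingencyLattice", function(object) {
  msg <- character()
  if (!identical(unname(rowSums(object@counts)),
                 as.numeric(object@rowCells$counts)))
    msg <- c(msg, "row sums must equal row-cell counts")
  if (!identical(unname(colSums(object@counts)),
                 as.numeric(object@colCells$counts)))
    msg <- c(msg, "column sums must equal column-cell counts")
  if (length(msg)) msg else TRUE
})

#' Reliability-certified rule set
#'
#' Categorical patterns observed on a contingency table (zero cells, column
#' modes, top-r orderings, unimodality, composite-category mass) that
#' survived the bootstrap reliability check: a pattern becomes a rule only
#' when at least `level` (default 95%) of B resampled datasets retain it.
#'
#' @slot rules list of rule records (type, scope, payload, reliability).
#' @slot rejected list of candidate rules that failed certification, with
#'   their reliabilities.
#' @slot level numeric certification level in \[0, 1\].
#' @slot B integer ensemble size used.
#' @slot scheme resampling scheme id (`"bootstrap"` or `"independence"`).
#' @slot seed integer seed the certification used.
#' @exportClass RuleSet
setClass("RuleSet",
  representation(rules = "list", rejected = "list", level = "numeric",
                 B = "integer", scheme = "character", seed = "integer"))

setValidity("RuleSet", function(object) {
  rel <- vapply(object@rules, function(r) r$reliability %||% 1, numeric(1))
  if (any(rel < object@level - 1e-12))
    return("all retained rules must have reliability >= level")
  TRUE
})

#' Ensemble of accepted mimicries
#'
#' The output of a mimicking protocol: accepted surrogate objects (coded
#' matrices, data matrices, or tables), with the attempt count and the
#' resulting acceptance rate. Every stored mimicry satisfies every governing
#' rule set by construction.
#'
#' @slot scenario `"I"`, `"II"`, or `"III"`.
#' @slot mimicries list of accepted surrogate objects.
#' @slot attempts,accepted integer counters.
#' @slot seed integer master seed.
#' @slot violations named numeric vector: per-rule rejection attributions.
#' @slot config list of the configuration used.
#' @exportClass MimicryEnsemble
setClass("MimicryEnsemble",
  representation(scenario = "character", mimicries = "list",
                 attempts = "integer", accepted = "integer",
                 seed = "integer", violations = "numeric", config = "list"))

setValidity("MimicryEnsemble", function(object) {
  msg <- character()
  if (object@accepted != length(object@mimicries))
    msg <- c(msg, "accepted count must match stored mimicries")
  if (object@attempts < object@accepted)
    msg <- c(msg, "attempts must be >= accepted")
  if (length(msg)) msg else TRUE
})
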