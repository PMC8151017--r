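#' Construct a feature schema
#'
#' @param name character vector of unique feature names.
#' @param dtype character vector of types: `continuous`, `discrete`,
#'   `categorical_nominal` or `categorical_ordinal`.
#' @param categoryOrder named list of ordered label vectors for categorical
#'   features (mandatory for ordinal ones).
#' @return a \linkS4class{FeatureSchema}.
#' @examples
#' FeatureSchema(c("speed", "zone"), c("continuous", "categorical_nominal"),
#'               list(zone = c("L", "R")))
#' @export
FeatureSchema <- function(name, dtype, categoryOrder = list()) {
  new("FeatureSchema", name = as.character(name), dtype = as.character(dtype),
      categoryOrder = categoryOrder)
}

.isQuantitative <- function(dtype) dtype %in% c("continuous", "discrete")

#' Construct a validated data matrix
#'
#' Builds a \linkS4class{CedaMatrix} from a data.frame and a schema,
#' normalising categorical columns to character, and deriving label sets for
#' nominal features that did not declare one (sorted observed labels).
#' Missing values are a hard error unless `dropIncompleteRows = TRUE`.
#'
#' @param values data.frame of N rows, K columns.
#' @param schema a \linkS4class{FeatureSchema}.
#' @param dropIncompleteRows drop rows containing any `NA` instead of
#'   erroring.
#' @return a \linkS4class{CedaMatrix}.
#' @export
CedaMatrix <- function(values, schema, dropIncompleteRows = FALSE) {
  .assert(is.data.frame(values), "values must be a data.frame")
  missing <- setdiff(colnames(values), schema@name)
  .assert(length(missing) == 0L,
          "column(s) missing from schema: %s", paste(missing, collapse = ", "))
  .assert(all(schema@name %in% colnames(values)),
          "schema feature(s) absent from data: %s",
          paste(setdiff(schema@name, colnames(values)), collapse = ", "))
  values <- values[, schema@name, drop = FALSE]
  if (anyNA(values)) {
    if (dropIncompleteRows) {
      values <- values[stats::complete.cases(values), , drop = FALSE]
      .assert(nrow(values) >= 1L, "no complete rows left after dropping")
    } else {
      idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at row %d, column '%s'",
                   idx[1L], colnames(values)[idx[2L]]), call. = FALSE)
    }
  }
  for (k in seq_along(schema@name)) {
    nm <- schema@name[k]
    if (.isQuantitative(schema@dtype[k])) {
      vk <- values[[nm]]
      if (!is.numeric(vk)) {
        suppressWarnings(num <- as.numeric(vk))
        if (anyNA(num)) {
          bad <- which(is.na(num))[1L]
          stop(sprintf("unparseable numeric cell at row %d, column '%s': '%s'",
                       bad, nm, vk[bad]), call. = FALSE)
        }
        values[[nm]] <- num
      }
      .assert(all(is.finite(values[[nm]])),
              "non-finite value in numeric column '%s'", nm)
    } else {
      values[[nm]] <- as.character(values[[nm]])
      if (is.null(schema@categoryOrder[[nm]]) ||
          !length(schema@categoryOrder[[nm]]))
        schema@categoryOrder[[nm]] <- sort(unique(values[[nm]]))
    }
  }
  new("CedaMatrix", values = values, schema = schema)
}

#' Read a data matrix and its schema from disk
#'
#' Reads a delimited text file with a header row together with a JSON schema
#' file of the form
#' `{"features": [{"name": ..., "dtype": ..., "category_order": [...]}]}`.
#'
#' @param path path to the CSV (or TSV) data file.
#' @param schemaPath path to the JSON schema file.
#' @param sep field delimiter, `","` by default; use `"\t"` for TSV.
#' @param dropIncompleteRows see [CedaMatrix()].
#' @return a validated \linkS4class{CedaMatrix}.
#' @export
readMatrix <- function(path, schemaPath, sep = ",",
                       dropIncompleteRows = FALSE) {
  schema <- readSchema(schemaPath)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           na.strings = "NA", stringsAsFactors = FALSE,
                           comment.char = "")
  CedaMatrix(raw, schema, dropIncompleteRows = dropIncompleteRows)
}

#' Write a data matrix (plus schema sidecar) to disk
#'
#' @param matrix a \linkS4class{CedaMatrix}.
#' @param path output CSV path.
#' @param schemaPath output path for the JSON schema sidecar; defaults to
#'   `path` with a `.schema.json` suffix.
#' @param sep field delimiter.
#' @return invisibly, the data path.
#' @export
writeMatrix <- function(matrix, path,
                        schemaPath = paste0(path, ".schema.json"), sep = ",") {
  out <- matrix@values
  for (k in seq_along(out))   # 17 significant digits: doubles round-trip
    if (is.numeric(out[[k]])) out[[k]] <- sprintf("%.17g", out[[k]])
  utils::write.table(out, path, sep = sep, quote = TRUE,
                     row.names = FALSE, col.names = TRUE)
  writeSchema(matrix@schema, schemaPath)
  invisible(path)
}

#' @rdname readMatrix
#' @export
readSchema <- function(schemaPath) {
  js <- jsonlite::fromJSON(schemaPath, simplifyDataFrame = FALSE)
  .assert(!is.null(js$features), "schema JSON must have a 'features' array")
  name <- vapply(js$features, `[[`, character(1), "name")
  dtype <- vapply(js$features, `[[`, character(1), "dtype")
  ord <- list()
  for (f in js$features)
    if (!is.null(f$category_order))
      ord[[f$name]] <- as.character(unlist(f$category_order))
  FeatureSchema(name, dtype, ord)
}

#' @rdname writeMatrix
#' @param schema a \linkS4class{FeatureSchema}.
#' @export
writeSchema <- function(schema, schemaPath) {
  feats <- lapply(seq_along(schema@name), function(k) {
    f <- list(name = schema@name[k], dtype = schema@dtype[k])
    co <- schema@categoryOrder[[schema@name[k]]]
    if (length(co)) f$category_order <- as.list(co)
    f
  })
  jsonlite::write_json(list(features = feats), schemaPath, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(schemaPath)
}
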