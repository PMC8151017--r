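#' Build a possibly-gapped histogram
#'
#' Gives a 1D sample its categorical nature. Bins come from agglomerative
#' merging of the sorted values (single linkage on inter-point spacings):
#' cutting the merge sequence into m clusters is equivalent to splitting at
#' the m - 1 widest spacings, ties broken at the lower index. m is the
#' smallest bin count for which every bin's empirical-CDF segment deviates
#' from the straight line joining its endpoints by at most `fitTolerance`,
#' capped at `maxBins`. An empty interval between consecutive bins wider
#' than `gapMultiplier` times the median positive inter-point spacing is
#' recorded as a gap.
#'
#' @param values numeric vector, nonempty and finite.
#' @param maxBins maximum number of bins (default 10).
#' @param fitTolerance maximum allowed ECDF deviation per bin, in (0, 1)
#'   (default 0.05).
#' @param gapMultiplier gap decision threshold multiplier (default 5).
#' @return a \linkS4class{GappedHistogram}.
#' @examples
#' buildHistogram(c(0, 0.1, 0.2, 5, 5.1, 5.2))
#' @export
buildHistogram <- function(values, maxBins = 10L, fitTolerance = 0.05,
                           gapMultiplier = 5) {
  .assert(length(values) >= 1L, "empty input")
  .assert(all(is.finite(values)), "non-finite values in input")
  .assert(fitTolerance > 0 && fitTolerance < 1, "fitTolerance must be in (0,1)")
  n <- length(values)
  x <- sort(values)
  if (x[n] == x[1L]) {                       # degenerate spread: one bin
    eps <- max(1e-8, abs(x[1L]) * 1e-8)
    return(new("GappedHistogram", left = x[1L], right = x[1L] + eps,
               counts = n, gapAfter = FALSE))
  }
  gaps <- diff(x)
  # split points ranked by decreasing spacing, ties by lower index
  rank <- order(-gaps, seq_along(gaps))
  m <- 1L
  boundaries <- integer(0)
  repeat {
    if (m > 1L) boundaries <- sort(rank[seq_len(m - 1L)])
    if (.ecdfFitOK(x, boundaries, fitTolerance) || m >= maxBins) break
    m <- m + 1L
  }
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  binMin <- x[starts]
  binMax <- x[ends]
  cnt <- ends - starts + 1L
  # gap decision threshold: scale-free in the data's typical spacing
  posGaps <- gaps[gaps > 0]
  thr <- stats::median(posGaps) * gapMultiplier
  mBins <- length(starts)
  left <- binMin
  right <- numeric(mBins)
  gapAfter <- logical(mBins)
  if (mBins > 1L) {
    for (j in seq_len(mBins - 1L)) {
      hole <- binMin[j + 1L] - binMax[j]
      if (hole > thr) {
        gapAfter[j] <- TRUE
        right[j] <- binMax[j] + 0.5 * thr
      } else {
        right[j] <- binMin[j + 1L]
      }
    }
  }
  eps <- max(1e-8, abs(binMax[mBins]) * 1e-8)
  right[mBins] <- binMax[mBins] + eps
  new("GappedHistogram", left = left, right = right,
      counts = as.integer(cnt), gapAfter = gapAfter)
}

# Piecewise-linear ECDF fit check for one candidate binning of sorted x.
# boundaries: indices i such that a bin ends at x[i].
.ecdfFitOK <- function(x, boundaries, tol) {
  n <- length(x)
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  for (b in seq_along(starts)) {
    i <- starts[b]; j <- ends[b]
    if (j - i < 2L) next                      # <= 2 points: line is exact
    xs <- x[i:j]
    Fs <- (i:j) / n
    if (xs[length(xs)] == xs[1L]) next        # zero-width bin fits exactly
    lin <- Fs[1L] + (Fs[length(Fs)] - Fs[1L]) *
      (xs - xs[1L]) / (xs[length(xs)] - xs[1L])
    if (max(abs(Fs - lin)) > tol) return(FALSE)
  }
  TRUE
}

#' Map values to bin codes of a histogram
#'
#' Bins are half-open `[left, right)`, except the last bin whose right edge
#' is closed so the sample maximum is covered. Values falling in a gap or
#' outside every bin code to `NA`.
#'
#' @param hist a \linkS4class{GappedHistogram}.
#' @param values numeric vector.
#' @return integer codes in `1..m`, `NA` where uncodable.
#' @export
binCode <- function(hist, values) {
  m <- length(hist@left)
  idx <- findInterval(values, hist@left)
  code <- ifelse(idx >= 1L & idx <= m, idx, NA_integer_)
  ok <- !is.na(code)
  # inside the located bin's interval? (gaps fall through)
  up <- hist@right[pmax(code, 1L)]
  inside <- ok & (values < up | (code == m & values <= hist@right[m]))
  ifelse(inside, code, NA_integer_)
}

#' Interval (or label) of a code under a coder
#'
#' @param coder a \linkS4class{GappedHistogram} or character label vector.
#' @param code integer code.
#' @return for a histogram, `c(left, right)`; for categories, the label.
#' @export
decodeCategory <- function(coder, code) {
  if (is(coder, "GappedHistogram")) c(coder@left[code], coder@right[code])
  else coder[code]
}

#' Categorize a whole data matrix
#'
#' Continuous and discrete columns are coded by their possibly-gapped
#' histograms; categorical columns are identity-coded against their
#' (ordered) label set, so a categorical feature's categorized version is
#' itself.
#'
#' @param matrix a \linkS4class{CedaMatrix}.
#' @param maxBins,fitTolerance,gapMultiplier histogram settings, see
#'   [buildHistogram()].
#' @return a \linkS4class{CodedMatrix}.
#' @export
encodeMatrix <- function(matrix, maxBins = 10L, fitTolerance = 0.05,
                         gapMultiplier = 5) {
  sch <- matrix@schema
  K <- length(sch@name)
  N <- nrow(matrix@values)
  codes <- matrix(NA_integer_, N, K, dimnames = list(NULL, sch@name))
  coders <- stats::setNames(vector("list", K), sch@name)
  for (k in seq_len(K)) {
    nm <- sch@name[k]
    if (.isQuantitative(sch@dtype[k])) {
      h <- buildHistogram(matrix@values[[nm]], maxBins = maxBins,
                          fitTolerance = fitTolerance,
                          gapMultiplier = gapMultiplier)
      coders[[k]] <- h
      codes[, k] <- binCode(h, matrix@values[[nm]])
    } else {
      lev <- sch@categoryOrder[[nm]]
      coders[[k]] <- lev
      codes[, k] <- match(matrix@values[[nm]], lev)
    }
  }
  new("CodedMatrix", codes = codes, coders = coders, schema = sch)
}

#' Export / import histograms as JSON
#'
#' @param hists named list of \linkS4class{GappedHistogram} objects.
#' @param path output (input) JSON path.
#' @return `writeHistograms`: the path, invisibly; `readHistograms`: the
#'   named list.
#' @export
writeHistograms <- function(hists, path) {
  out <- lapply(hists, function(h)
    list(left = h@left, right = h@right, counts = h@counts,
         gap_after = h@gapAfter))
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeHistograms
#' @export
readHistograms <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(js, function(h)
    new("GappedHistogram", left = as.numeric(unlist(h$left)),
        right = as.numeric(unlist(h$right)),
        counts = as.integer(unlist(h$counts)),
        gapAfter = as.logical(unlist(h$gap_after))))
}
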