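#' Length-frequency data
#'
#' Container for date-stamped binned length counts, the input to ELEFAN
#' and catch-curve analyses.
#'
#' @param bin_lower ascending lower bin edges (mm); must be uniformly
#'   spaced.
#' @param dates sample dates, either \code{Date}s (converted with
#'   \code{\link{decimal_year}}) or decimal years; strictly increasing.
#' @param counts integer matrix of counts, \code{length(bin_lower)} rows by
#'   \code{length(dates)} columns.
#' @return An object of class \code{"lfq"}: list with \code{bin_lower},
#'   \code{bin_width}, \code{dates} (decimal years), \code{counts}.
#' @seealso \code{\link{bin_lengths}} to build one from raw measurements.
#' @export
lfq <- function(bin_lower, dates, counts) {
  bin_lower <- as.numeric(bin_lower)
  if (length(bin_lower) < 1L) stop("need at least one length bin")
  if (inherits(dates, "Date") || is.character(dates))
    dates <- decimal_year(dates)
  dates <- as.numeric(dates)
  counts <- as.matrix(counts)
  if (length(bin_lower) > 1L) {
    w <- diff(bin_lower)
    if (any(w <= 0)) stop("bin edges must be strictly increasing")
    if (max(abs(w - w[1])) > 1e-8 * w[1])
      stop("length bins must have uniform width")
    bin_width <- w[1]
  } else {
    bin_width <- attr(bin_lower, "width")
    if (is.null(bin_width)) bin_width <- 1
  }
  if (any(diff(dates) <= 0)) stop("sample dates must be strictly increasing")
  if (nrow(counts) != length(bin_lower) || ncol(counts) != length(dates))
    stop("'counts' must be a [bin x sample] matrix matching bins and dates")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  structure(list(bin_lower = bin_lower, bin_width = bin_width,
                 dates = dates, counts = counts),
            class = "lfq")
}

#' Bin raw length measurements into a length-frequency object
#'
#' Bins per-date length lists into uniform half-open bins
#' \eqn{[\ell, \ell + \Delta)}: a length exactly on an edge belongs to the
#' upper bin. Bins span the observed length range; lower edges are aligned
#' to multiples of the bin width.
#'
#' @param lengths a named list, one numeric vector of lengths (mm) per
#'   sample date; names are ISO dates or decimal years.
#' @param bin_mm bin width (mm), > 0.
#' @return an \code{\link{lfq}} object; column sums equal the per-date
#'   sample sizes.
#' @examples
#' bin_lengths(list(`2019-01-20` = c(131, 139, 145)), bin_mm = 10)
#' @export
bin_lengths <- function(lengths, bin_mm) {
  if (!is.list(lengths) || length(lengths) == 0L)
    stop("'lengths' must be a non-empty list of per-date length vectors")
  if (!is.finite(bin_mm) || bin_mm <= 0) stop("'bin_mm' must be > 0")
  all_len <- unlist(lengths, use.names = FALSE)
  if (length(all_len) == 0L) stop("no length measurements supplied")
  if (any(!is.finite(all_len)) || any(all_len < 0))
    stop("lengths must be finite and non-negative")
  lo <- floor(min(all_len) / bin_mm) * bin_mm
  hi <- floor(max(all_len) / bin_mm) * bin_mm
  edges <- seq(lo, hi, by = bin_mm)
  counts <- vapply(lengths, function(x) {
    idx <- floor((x - lo) / bin_mm) + 1L
    tabulate(idx, nbins = length(edges))
  }, integer(length(edges)))
  counts <- matrix(counts, nrow = length(edges),
                   dimnames = list(NULL, names(lengths)))
  dts <- names(lengths)
  dts <- if (suppressWarnings(all(!is.na(as.numeric(dts))))) {
    as.numeric(dts)
  } else {
    decimal_year(dts)
  }
  ord <- order(dts)
  lfq(edges, dts[ord], counts[, ord, drop = FALSE])
}

#' @export
print.lfq <- function(x, ...) {
  cat(sprintf("Length-frequency data: %d bins of %g mm x %d samples\n",
              length(x$bin_lower), x$bin_width, length(x$dates)))
  cat(sprintf("  lengths %g-%g mm, dates %.3f-%.3f, n = %d\n",
              min(x$bin_lower), max(x$bin_lower) + x$bin_width,
              min(x$dates), max(x$dates), sum(x$counts)))
  invisible(x)
}

#' @export
plot.lfq <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$dates)), mar = c(4, 2, 2, 0.5))
  on.exit(graphics::par(op))
  for (j in seq_along(x$dates)) {
    graphics::barplot(x$counts[, j], horiz = TRUE, space = 0,
                      names.arg = NULL, main = sprintf("%.2f", x$dates[j]),
                      xlab = "count", ...)
  }
  invisible(x)
}

# bin midpoints
.lfq_mids <- function(x) x$bin_lower + x$bin_width / 2
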