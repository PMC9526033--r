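#' Goodness-of-fit score Rn of a growth curve through restructured peaks
#'
#' Traces the seasonalized VBGF trajectories of successive annual cohorts
#' through the restructured length-frequency matrix and scores how well
#' they intersect its peaks. Each cohort is born at
#' \code{year + t_anchor} for every calendar year whose fish could appear
#' in the sampled window; at each sample date the cohort's predicted
#' length selects a length bin, whose restructured value is accumulated
#' into the explained sum of peaks (ESP). A "peak" (a maximal run of
#' adjacent positive bins within one sample) is creditable at most once,
#' by the first trajectory that intersects it; negative scores count every
#' time a trajectory crosses them. With ASP the sum of all positive
#' restructured values, the score is
#' \deqn{R_n = 10^{ESP/ASP} / 10,}
#' so \eqn{R_n \in (0, 1]}, reaching 1 only when the curves collect every
#' peak in full and cross no troughs.
#'
#' @param restr an \code{\link{lfq_restructured}} object.
#' @param params a \code{\link{vbgf_params}} object.
#' @return list with \code{rn}, \code{esp}, \code{asp}.
#' @export
score_rn <- function(restr, params) {
  stopifnot(inherits(restr, "lfq_restructured"), inherits(params, "vbgf"))
  asp <- sum(restr$values[restr$values > 0])
  if (asp <= 0) stop("ASP is zero: no peaks in the restructured data")
  esp <- .esp(restr, params)
  list(rn = 10^(esp / asp) / 10, esp = esp, asp = asp)
}

# Explained sum of peaks for one parameter set (vectorized over all
# cohort x sample crossings; peaks deduplicated in sample-major order).
.esp <- function(restr, params) {
  v <- restr$values
  nb <- nrow(v)
  dates <- restr$dates
  peak_id <- restr$peak_id
  if (is.null(peak_id)) peak_id <- .peak_ids(v)
  # cohorts possibly present: born up to max_age before the last sample
  max_age <- min(log(1000) / params$k, 50)
  births <- (floor(min(dates) - max_age):floor(max(dates))) +
    params$t_anchor
  age <- outer(-births, dates, `+`)      # [cohort x sample] = date - birth
  ok <- age > 0 & age <= max_age
  if (!any(ok)) return(0)
  aa <- age[ok]
  jj <- col(age)[ok]
  bb <- births[row(age)[ok]]
  len <- vbgf_length(params, aa, birth = bb)
  bin <- floor((len - restr$bin_lower[1]) / restr$bin_width) + 1L
  ins <- bin >= 1L & bin <= nb
  if (!any(ins)) return(0)
  idx <- cbind(bin[ins], jj[ins])
  val <- v[idx]
  pos <- val > 0
  first <- !duplicated(peak_id[idx][pos])
  sum(val[!pos]) + sum(val[pos][first])
}

# label maximal runs of positive values with unique ids (column-wise)
.peak_ids <- function(v) {
  id <- matrix(0L, nrow(v), ncol(v))
  nxt <- 0L
  for (j in seq_len(ncol(v))) {
    inpeak <- FALSE
    for (i in seq_len(nrow(v))) {
      if (v[i, j] > 0) {
        if (!inpeak) { nxt <- nxt + 1L; inpeak <- TRUE }
        id[i, j] <- nxt
      } else inpeak <- FALSE
    }
  }
  id
}
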