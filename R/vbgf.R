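#' Seasonalized von Bertalanffy growth parameters
#'
#' Constructor and validator for the parameter set of the seasonally
#' oscillating von Bertalanffy growth function (soVBGF),
#' \deqn{L(t) = L_\infty \left(1 - e^{-\left(K (t - t_0) +
#'   \frac{CK}{2\pi}\left[\sin 2\pi(t - t_s) - \sin 2\pi(t_0 - t_s)\right]
#'   \right)}\right)}{L(t) = Linf (1 - exp(-(K (t - t0) + (C K / 2 pi)
#'   (sin 2 pi (t - ts) - sin 2 pi (t0 - ts)))))}
#' with asymptotic length \code{linf} (mm), growth coefficient \code{k}
#' (1/yr), seasonal amplitude \code{c} (0 = no oscillation, 1 = growth
#' stalls once a year), summer point \code{ts} (fraction of year at which
#' growth is fastest) and age at zero length \code{t0} (yr). For
#' length-frequency work absolute ages are unknown; \code{t_anchor}
#' (fraction of year) anchors the recruitment pulse of each cohort on the
#' calendar axis and \code{t0} may be left \code{NA}.
#'
#' @param linf asymptotic length (mm), > 0.
#' @param k von Bertalanffy growth coefficient (1/yr), > 0.
#' @param t_anchor fraction of the year (in [0, 1)) at which cohorts are
#'   born; used when tracing growth curves through calendar-dated samples.
#' @param c_amp amplitude of the seasonal growth oscillation, in \[0, 1\].
#' @param ts summer point (fraction of year, in [0, 1)).
#' @param t0 theoretical age at zero length (yr); optional, only needed to
#'   convert relative ages to absolute ages.
#' @return An object of class \code{"vbgf"}: a list with the validated
#'   components above.
#' @examples
#' p <- vbgf_params(linf = 434, k = 0.43, t0 = -0.06)
#' vbgf_length(p, age = 1)
#' @export
vbgf_params <- function(linf, k, t_anchor = 0, c_amp = 0, ts = 0, t0 = NA_real_) {
  vals <- c(linf = linf, k = k, t_anchor = t_anchor, c_amp = c_amp, ts = ts)
  if (any(!is.finite(vals)))
    stop("non-finite growth parameter: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (linf <= 0) stop("'linf' must be > 0")
  if (k <= 0) stop("'k' must be > 0")
  if (c_amp < 0 || c_amp > 1)
    stop("seasonal amplitude 'c_amp' must lie in [0, 1]")
  if (ts < 0 || ts >= 1) stop("'ts' must lie in [0, 1)")
  if (t_anchor < 0 || t_anchor >= 1) stop("'t_anchor' must lie in [0, 1)")
  structure(list(linf = linf, k = k, t_anchor = t_anchor,
                 c_amp = c_amp, ts = ts, t0 = t0),
            class = "vbgf")
}

#' @export
print.vbgf <- function(x, ...) {
  cat("Seasonalized von Bertalanffy growth parameters\n")
  cat(sprintf("  Linf = %.1f mm, K = %.3f 1/yr, t_anchor = %.3f\n",
              x$linf, x$k, x$t_anchor))
  cat(sprintf("  C = %.3f, ts = %.3f, t0 = %s\n", x$c_amp, x$ts,
              if (is.na(x$t0)) "NA" else sprintf("%.3f yr", x$t0)))
  invisible(x)
}

# seasonal phase integral term, (C K / 2 pi) * sin(2 pi (t - ts))
.vbgf_season <- function(t, k, c_amp, ts) {
  (c_amp * k / (2 * pi)) * sin(2 * pi * (t - ts))
}

#' Length-at-age under the seasonalized VBGF
#'
#' Evaluates the soVBGF at age(s) \code{age} (years since the age of zero
#' length). With \code{c_amp = 0} this is the ordinary VBGF
#' \eqn{L_\infty (1 - e^{-K(t - t_0)})}. Length is non-decreasing in age
#' for any amplitude \eqn{C \le 1}.
#'
#' @param params a \code{\link{vbgf_params}} object.
#' @param age age (yr). When \code{t0} is set this is absolute age \eqn{t}
#'   (so \code{age = t0} gives length 0); when \code{t0} is \code{NA} it is
#'   relative age measured from length zero.
#' @param birth optional calendar time (decimal year) of cohort birth; when
#'   given, \code{age} is years since birth and the seasonal oscillation is
#'   evaluated at absolute calendar time \code{birth + age} so that cohorts
#'   born at different times of year grow through the seasons in phase with
#'   the calendar.
#' @return numeric vector of lengths (mm).
#' @export
vbgf_length <- function(params, age, birth = NULL) {
  stopifnot(inherits(params, "vbgf"))
  if (is.null(birth)) {
    t0 <- if (is.na(params$t0)) 0 else params$t0
    expo <- params$k * (age - t0) +
      .vbgf_season(age, params$k, params$c_amp, params$ts) -
      .vbgf_season(t0, params$k, params$c_amp, params$ts)
  } else {
    expo <- params$k * age +
      .vbgf_season(birth + age, params$k, params$c_amp, params$ts) -
      .vbgf_season(birth, params$k, params$c_amp, params$ts)
  }
  params$linf * (1 - exp(-expo))
}

#' Relative age at length (inverse VBGF)
#'
#' Inverts the non-seasonal VBGF, \eqn{t(L) = t_0 - \ln(1 - L/L_\infty)/K}.
#' The seasonal oscillation has no closed-form inverse; the non-seasonal
#' inverse is the standard approximation used in length-converted catch
#' curves even when the growth fit is seasonal.
#'
#' @param params a \code{\link{vbgf_params}} object.
#' @param length length (mm), must be < \code{linf}.
#' @return relative age (yr); ages are relative to length zero when
#'   \code{t0} is \code{NA}.
#' @export
vbgf_age <- function(params, length) {
  stopifnot(inherits(params, "vbgf"))
  if (any(length >= params$linf))
    stop("length at or above Linf has no finite age")
  t0 <- if (is.na(params$t0)) 0 else params$t0
  t0 - log(1 - length / params$linf) / params$k
}

#' Convert calendar dates to decimal years
#'
#' Mid-day convention: \code{year + (day_of_year - 0.5) / 365.25}.
#'
#' @param dates a \code{Date} vector (or strings coercible via
#'   \code{as.Date}).
#' @return numeric vector of decimal years.
#' @export
decimal_year <- function(dates) {
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  yr + (doy - 0.5) / 365.25
}
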