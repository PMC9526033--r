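#' Length-converted catch curve
#'
#' Estimates total mortality Z from pooled length frequencies and a growth
#' fit. Bins are converted to relative age with the (non-seasonal) inverse
#' VBGF \eqn{t(L) = t_0 - \ln(1 - L/L_\infty)/K}; the regression
#' \eqn{\ln(N_i/\Delta t_i) = a - Z\, t_i} is fitted by OLS over the
#' descending limb, where \eqn{\Delta t_i} is the time a cohort needs to
#' grow through bin i and \eqn{t_i} the relative age at the bin midpoint.
#' The descending limb is auto-selected as the first bin strictly after
#' the peak of \eqn{\ln(N/\Delta t)} through the last bin with at least
#' \code{min_count} fish; bins reaching \code{linf} are excluded with a
#' warning.
#'
#' @param x an \code{\link{lfq}} object (samples are pooled).
#' @param growth a \code{\link{vbgf_params}} object.
#' @param points optional integer vector of bin indices to use instead of
#'   the automatic descending-limb selection.
#' @param min_count terminal bins with fewer fish are dropped (default 5).
#' @return An object of class \code{"catch_curve"}: list with \code{z},
#'   \code{se} (OLS standard error of the slope), \code{points}
#'   (data.frame of all bins: midpoint length, relative age, dt, count,
#'   log N/dt, used flag), \code{fit} (the \code{lm}), \code{growth}.
#' @examples
#' p <- vbgf_params(linf = 434, k = 0.43)
#' @export
catch_curve <- function(x, growth, points = NULL, min_count = 5) {
  stopifnot(inherits(x, "lfq"), inherits(growth, "vbgf"))
  n <- rowSums(x$counts)
  lo <- x$bin_lower
  hi <- lo + x$bin_width
  keep <- hi < growth$linf
  if (!all(keep)) {
    warning(sum(!keep), " bin(s) at or above Linf excluded")
  }
  mid <- lo + x$bin_width / 2
  t_lo <- t_hi <- t_mid <- rep(NA_real_, length(lo))
  t_lo[keep] <- vbgf_age(growth, lo[keep])
  t_hi[keep] <- vbgf_age(growth, hi[keep])
  t_mid[keep] <- vbgf_age(growth, mid[keep])
  dt <- t_hi - t_lo
  y <- ifelse(keep & n > 0, log(n / dt), NA_real_)
  if (is.null(points)) {
    peak <- which.max(y)
    last <- max(which(keep & n >= min_count))
    if (!is.finite(peak) || last <= peak + 1L)
      stop("no usable descending limb")
    points <- seq(peak + 1L, last)
    points <- points[is.finite(y[points])]
  }
  if (length(points) < 3L)
    stop("need at least 3 points on the descending limb")
  if (any(!is.finite(y[points])))
    stop("selected points include empty or unusable bins")
  fit <- stats::lm(y[points] ~ t_mid[points])
  sm <- suppressWarnings(summary(fit))  # exact expected counts are legitimate
  z <- -unname(stats::coef(fit)[2])
  se <- sm$coefficients[2, 2]
  pts <- data.frame(bin_lower = lo, length = mid, t = t_mid, dt = dt,
                    n = n, log_n_dt = y,
                    used = seq_along(lo) %in% points)
  structure(list(z = z, se = se, points = pts, fit = fit,
                 growth = growth, min_count = min_count),
            class = "catch_curve")
}

#' @export
print.catch_curve <- function(x, ...) {
  cat(sprintf("Length-converted catch curve: Z = %.3f 1/yr (SE %.3f), %d points\n",
              x$z, x$se, sum(x$points$used)))
  invisible(x)
}

#' @export
coef.catch_curve <- function(object, ...) c(z = object$z)

#' @export
plot.catch_curve <- function(x, ...) {
  p <- x$points
  graphics::plot(p$t, p$log_n_dt, pch = ifelse(p$used, 19, 1),
                 xlab = "relative age (yr)", ylab = "ln(N / dt)", ...)
  graphics::abline(x$fit, lty = 2)
  invisible(x)
}

#' Empirical natural mortality estimators
#'
#' \code{"pauly_T"}: Pauly's temperature-dependent formula,
#' \eqn{\log_{10} M = -0.0066 - 0.279 \log_{10} L_\infty(cm)
#' + 0.6543 \log_{10} K + 0.4634 \log_{10} T}.
#' \code{"then_growth"}: Then et al.'s growth-based updated estimator,
#' \eqn{M = 4.118\, K^{0.73} L_\infty(cm)^{-0.33}}.
#' \code{"user"}: pass a literature value through unchanged.
#'
#' @param growth a \code{\link{vbgf_params}} object (\code{linf} in mm).
#' @param method one of \code{"user"}, \code{"pauly_T"},
#'   \code{"then_growth"}.
#' @param temp_c mean water temperature (deg C) for \code{"pauly_T"}.
#' @param m user-supplied M (1/yr) for \code{"user"}.
#' @return natural mortality M (1/yr), with attribute \code{"method"}.
#' @export
natural_mortality <- function(growth, method = c("user", "pauly_T", "then_growth"),
                              temp_c = NULL, m = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(growth, "vbgf"))
  linf_cm <- growth$linf / 10
  out <- switch(method,
    user = {
      if (is.null(m) || !is.finite(m) || m < 0)
        stop("method 'user' needs a non-negative 'm'")
      m
    },
    pauly_T = {
      if (is.null(temp_c) || !is.finite(temp_c) || temp_c <= 0)
        stop("method 'pauly_T' needs a positive 'temp_c'")
      10^(-0.0066 - 0.279 * log10(linf_cm) + 0.6543 * log10(growth$k) +
            0.4634 * log10(temp_c))
    },
    then_growth = 4.118 * growth$k^0.73 * linf_cm^(-0.33))
  structure(out, method = method)
}

#' Fishing mortality and exploitation rate
#'
#' Partitions total mortality into natural and fishing components:
#' \eqn{F = Z - M} and \eqn{E = F/Z}. A stock is conventionally considered
#' fully or over-exploited as E exceeds 0.5.
#'
#' @param z total mortality (1/yr), > 0; or a \code{catch_curve} object.
#' @param m natural mortality (1/yr), with \eqn{0 \le M \le Z}.
#' @param z_se optional standard error of Z (carried through).
#' @return An object of class \code{"mortality"}: list with \code{z},
#'   \code{z_se}, \code{m}, \code{m_method}, \code{f}, \code{e}.
#' @examples
#' exploitation(z = 1.87, m = 0.30)   # F = 1.57, E = 0.84
#' @export
exploitation <- function(z, m, z_se = NA_real_) {
  if (inherits(z, "catch_curve")) { z_se <- z$se; z <- z$z }
  if (!is.finite(z) || z <= 0) stop("'z' must be positive")
  m_method <- attr(m, "method")
  m <- as.numeric(m)
  if (!is.finite(m) || m < 0) stop("'m' must be non-negative")
  if (m > z)
    stop("implausible estimates: natural mortality M exceeds total Z")
  f <- z - m
  structure(list(z = z, z_se = z_se, m = m,
                 m_method = if (is.null(m_method)) "user" else m_method,
                 f = f, e = f / z),
            class = "mortality")
}

#' @export
print.mortality <- function(x, ...) {
  cat("Mortality and exploitation estimates (1/yr)\n")
  cat(sprintf("  Z = %.2f%s  M = %.2f (%s)  F = %.2f  E = %.2f\n",
              x$z, if (is.finite(x$z_se)) sprintf(" (SE %.2f)", x$z_se) else "",
              x$m, x$m_method, x$f, x$e))
  invisible(x)
}

#' Probability-of-capture ogive from a catch curve
#'
#' Back-extrapolates the catch-curve regression over the ascending limb to
#' obtain the numbers expected under full selection; the ratio
#' observed/expected (clipped to \[0, 1\]) estimates the probability of
#' capture per bin. A logistic in relative age is then fitted by OLS on
#' the logit scale using bins with probabilities inside
#' \code{[p_tol, 1 - p_tol]} (near-saturated bins carry no information
#' about the ogive and amplify extrapolation error on the logit scale),
#' giving the age at 50% and 95% capture probability and, through the
#' growth curve, the corresponding lengths.
#'
#' @param cc a \code{\link{catch_curve}} object.
#' @param p_tol probabilities closer than this to 0 or 1 are excluded
#'   from the logistic fit (default 0.005).
#' @return An object of class \code{"ogive"}: list with \code{t50},
#'   \code{t95} (yr, relative age), \code{l50}, \code{l95} (mm),
#'   \code{prob} (data.frame of bin, t, observed probability), and the
#'   logit-line coefficients \code{a}, \code{b}.
#' @export
catch_ogive <- function(cc, p_tol = 0.005) {
  stopifnot(inherits(cc, "catch_curve"))
  p <- cc$points
  first_used <- min(which(p$used))
  asc <- which(seq_len(nrow(p)) < first_used & is.finite(p$t) & p$dt > 0)
  if (length(asc) == 0L) stop("no ascending limb before the catch curve")
  co <- stats::coef(cc$fit)
  expected <- exp(co[1] + co[2] * p$t[asc]) * p$dt[asc]
  prob <- pmin(pmax(p$n[asc] / expected, 0), 1)
  use <- prob >= p_tol & prob <= 1 - p_tol
  if (sum(use) < 2L)
    stop("fewer than 2 interior capture probabilities; cannot fit ogive")
  lg <- stats::lm(stats::qlogis(prob[use]) ~ p$t[asc][use])
  a <- unname(stats::coef(lg)[1]); b <- unname(stats::coef(lg)[2])
  if (b <= 0) stop("ogive slope not positive; no usable ascending limb")
  t50 <- -a / b
  t95 <- (log(19) - a) / b
  g <- cc$growth
  structure(list(t50 = t50, t95 = t95,
                 l50 = vbgf_length(g, t50), l95 = vbgf_length(g, t95),
                 prob = data.frame(bin_lower = p$bin_lower[asc],
                                   t = p$t[asc], prob = prob),
                 a = a, b = b),
            class = "ogive")
}

#' @export
print.ogive <- function(x, ...) {
  cat(sprintf("Capture ogive: t50 = %.3f yr (L50 = %.1f mm), t95 = %.3f yr (L95 = %.1f mm)\n",
              x$t50, x$l50, x$t95, x$l95))
  invisible(x)
}

#' Length-weight relationship
#'
#' Fits the allometric model \eqn{w = a L^b} by OLS on
#' \eqn{\log w = \log a + b \log L}.
#'
#' @param length lengths (mm), > 0.
#' @param weight weights (g), > 0.
#' @return An object of class \code{"length_weight"}: list with \code{a}
#'   (g mm^-b), \code{b}, \code{r2}, \code{n}, \code{fit}.
#' @examples
#' L <- seq(100, 400, by = 50)
#' fit_length_weight(L, 2.6e-6 * L^3.26)
#' @export
fit_length_weight <- function(length, weight) {
  if (length(length) != length(weight)) stop("length/weight size mismatch")
  if (length(length) < 3L) stop("need at least 3 length-weight pairs")
  if (any(length <= 0) || any(weight <= 0))
    stop("lengths and weights must be positive")
  fit <- stats::lm(log(weight) ~ log(length))
  co <- stats::coef(fit)
  structure(list(a = exp(unname(co[1])), b = unname(co[2]),
                 r2 = summary(fit)$r.squared, n = length(length),
                 fit = fit),
            class = "length_weight")
}

#' @export
print.length_weight <- function(x, ...) {
  cat(sprintf("Length-weight fit: w = %.3g * L^%.3f (n = %d, R2 = %.3f)\n",
              x$a, x$b, x$n, x$r2))
  invisible(x)
}
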