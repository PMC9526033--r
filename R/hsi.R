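#' Standardize abundance to a suitability index observation
#'
#' Scales per-cell catch (or abundance) to \[0, 1\] by dividing by the
#' maximum over the dataset, giving the observed suitability-index
#' response used to fit SI curves.
#'
#' @param catch non-negative catches/abundances.
#' @return numeric vector in \[0, 1\].
#' @examples standardize_abundance(c(2, 5, 10))
#' @export
standardize_abundance <- function(catch) {
  if (length(catch) == 0L || any(!is.finite(catch)) || any(catch < 0))
    stop("catch must be finite and non-negative")
  mx <- max(catch)
  if (mx <= 0) stop("all-zero catch cannot be standardized")
  catch / mx
}

#' Winter-mean environmental fields
#'
#' Averages the monthly fields over one overwintering season: December of
#' \code{year} plus January and February of \code{year + 1} (a winter
#' belongs to its December year). Invariant to the ordering of months.
#'
#' @param grid an \code{env_grid}.
#' @param year the winter year.
#' @return data.frame with lon, lat, depth_m, sst_c, sss (winter means).
#' @export
winter_mean <- function(grid, year) {
  stopifnot(inherits(grid, "env_grid"))
  m <- grid$monthly
  want <- list(c(year, 12L), c(year + 1L, 1L), c(year + 1L, 2L))
  parts <- lapply(want, function(w) {
    rows <- m[m$year == w[1] & m$month == w[2], , drop = FALSE]
    if (nrow(rows) == 0L)
      stop(sprintf("missing month %d-%02d for winter %d", w[1], w[2], year))
    rows[order(rows$lat, rows$lon), , drop = FALSE]
  })
  out <- parts[[1]][, c("lon", "lat")]
  out$sst_c <- (parts[[1]]$sst_c + parts[[2]]$sst_c + parts[[3]]$sst_c) / 3
  out$sss <- (parts[[1]]$sss + parts[[2]]$sss + parts[[3]]$sss) / 3
  cells <- grid$cells[order(grid$cells$lat, grid$cells$lon), ]
  out$depth_m <- cells$depth_m
  out[, c("lon", "lat", "depth_m", "sst_c", "sss")]
}

#' Per-cell-year observations for habitat model fitting
#'
#' Joins winter-mean environmental fields with the annual winter catch
#' for the requested years.
#'
#' @param grid an \code{env_grid} carrying catch records.
#' @param years winter years to include.
#' @return data.frame with lon, lat, year, depth, sst, sss, catch.
#' @export
hsi_observations <- function(grid, years) {
  stopifnot(inherits(grid, "env_grid"))
  if (is.null(grid$catch)) stop("grid carries no catch records")
  do.call(rbind, lapply(years, function(y) {
    wm <- winter_mean(grid, y)
    cr <- grid$catch[grid$catch$year == y, , drop = FALSE]
    if (nrow(cr) == 0L) stop("no catch records for winter ", y)
    idx <- match(paste(wm$lon, wm$lat), paste(cr$lon, cr$lat))
    data.frame(lon = wm$lon, lat = wm$lat, year = y,
               depth = wm$depth_m, sst = wm$sst_c, sss = wm$sss,
               catch = cr$catch_t[idx])
  }))
}

#' Fit a suitability-index curve for one environmental variable
#'
#' Two forms are supported.
#' \describe{
#'   \item{\code{"fitting"}}{the empirical envelope method: the variable
#'     is split into \code{bins} equal-width bins, the maximum observed SI
#'     per non-empty bin (paired with the variable value attaining it) is
#'     taken as the suitability envelope, and the curve
#'     \eqn{y = A e^{-(x-\mu)^2 / 2\sigma^2} + D} (a Gaussian response
#'     over a baseline suitability \eqn{D \ge 0}) is fitted by nonlinear
#'     least squares, then normalized to peak at 1.}
#'   \item{\code{"regression"}}{an OLS polynomial (default cubic) of the
#'     SI observations on the variable; predictions are clipped to \[0, 1\]
#'     and normalized to peak at 1 over the observed domain; the
#'     regression F-test p-value is recorded.}
#' }
#' The optimal range reported is \eqn{\{x : SI(x) \ge} \code{threshold}
#' \eqn{\}} intersected with the observed domain.
#'
#' @param x variable values (one per observation).
#' @param si_obs standardized abundance in \[0, 1\] (same length).
#' @param variable label (\code{"depth"}, \code{"sst"}, \code{"sss"}).
#' @param form \code{"fitting"} or \code{"regression"}.
#' @param bins number of envelope bins for \code{"fitting"}.
#' @param degree polynomial degree for \code{"regression"}.
#' @param threshold SI cut defining the optimal range (default 0.8).
#' @return An object of class \code{"si_curve"}: list with
#'   \code{variable}, \code{form}, \code{params}, \code{domain},
#'   \code{optimal_range}, \code{p_value} (regression form), \code{norm}.
#' @export
fit_si <- function(x, si_obs, variable = "x",
                   form = c("fitting", "regression"),
                   bins = 10, degree = 3, threshold = 0.8) {
  form <- match.arg(form)
  ok <- is.finite(x) & is.finite(si_obs)
  x <- x[ok]; si_obs <- si_obs[ok]
  if (length(unique(x)) < 5L)
    stop("need at least 5 distinct values of '", variable, "'")
  if (stats::sd(x) == 0 || stats::sd(si_obs) == 0)
    stop("degenerate variance in '", variable, "' or the SI response")
  domain <- range(x)
  if (form == "fitting") {
    edges <- seq(domain[1], domain[2], length.out = bins + 1)
    bi <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
               bins)
    env_x <- env_y <- numeric(0)
    for (b in unique(bi)) {
      in_b <- which(bi == b)
      top <- in_b[which.max(si_obs[in_b])]
      env_x <- c(env_x, x[top]); env_y <- c(env_y, si_obs[top])
    }
    if (length(env_x) < 4L) stop("too few envelope bins for '", variable, "'")
    mu0 <- env_x[which.max(env_y)]
    sig0 <- max(stats::sd(env_x), diff(domain) / 6)
    d0 <- max(min(env_y), 1e-4)
    a0 <- max(max(env_y) - d0, 1e-3)
    fit <- minpack.lm::nlsLM(
      env_y ~ A * exp(-(env_x - mu)^2 / (2 * sigma^2)) + D,
      start = list(A = a0, mu = mu0, sigma = sig0, D = d0),
      lower = c(A = 1e-8, mu = -Inf, sigma = 1e-8, D = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14))
    co <- stats::coef(fit)
    pars <- c(mode = unname(co["mu"]), width = unname(co["sigma"]),
              amp = unname(co["A"]), base = unname(co["D"]))
    norm <- unname(co["A"] + co["D"])
    curve <- structure(list(variable = variable, form = "fitting",
                            params = pars, domain = domain, norm = norm,
                            p_value = NA_real_),
                       class = "si_curve")
  } else {
    X <- stats::poly(x, degree = min(degree, length(unique(x)) - 1L),
                     raw = TRUE)
    fit <- stats::lm(si_obs ~ X)
    if (any(is.na(stats::coef(fit))))
      stop("rank-deficient polynomial design for '", variable, "'")
    fs <- suppressWarnings(summary(fit))$fstatistic  # exact fits allowed
    pval <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    curve <- structure(list(variable = variable, form = "regression",
                            params = stats::coef(fit), domain = domain,
                            norm = 1, p_value = unname(pval)),
                       class = "si_curve")
    # normalize: peak of the clipped polynomial over the domain = 1
    gx <- seq(domain[1], domain[2], length.out = 512)
    mx <- max(.si_raw(curve, gx))
    if (mx <= 0) stop("degenerate polynomial SI for '", variable, "'")
    curve$norm <- mx
  }
  curve$optimal_range <- .si_optimal_range(curve, threshold)
  curve$threshold <- threshold
  curve
}

# unnormalized prediction (regression form: clipped to [0, 1])
.si_raw <- function(curve, x) {
  if (curve$form == "fitting") {
    p <- curve$params
    unname(p["amp"] * exp(-(x - p["mode"])^2 / (2 * p["width"]^2)) +
             p["base"])
  } else {
    co <- curve$params
    deg <- length(co) - 1L
    y <- drop(outer(x, 0:deg, `^`) %*% co)
    pmin(pmax(y, 0), 1)
  }
}

#' Evaluate a suitability-index curve
#'
#' @param curve an \code{si_curve}.
#' @param x variable values.
#' @return suitability in \[0, 1\] (normalized to peak at 1 over the
#'   observed domain).
#' @export
si_predict <- function(curve, x) {
  stopifnot(inherits(curve, "si_curve"))
  pmin(pmax(.si_raw(curve, x) / curve$norm, 0), 1)
}

.si_optimal_range <- function(curve, threshold) {
  gx <- seq(curve$domain[1], curve$domain[2], length.out = 2048)
  ok <- si_predict(curve, gx) >= threshold
  if (!any(ok)) return(c(NA_real_, NA_real_))
  c(min(gx[ok]), max(gx[ok]))
}

#' @export
print.si_curve <- function(x, ...) {
  cat(sprintf("SI curve (%s-based) for %s\n", x$form, x$variable))
  if (x$form == "fitting")
    cat(sprintf("  mode = %.3f, width = %.3f, baseline = %.3f\n",
                x$params["mode"], x$params["width"],
                x$params["base"] / x$norm))
  cat(sprintf("  optimal range (SI >= %.2f): %.2f-%.2f\n",
              x$threshold, x$optimal_range[1], x$optimal_range[2]))
  invisible(x)
}

#' Combine per-variable suitabilities into an HSI
#'
#' @param si matrix (or data.frame) of per-variable suitabilities in
#'   \[0, 1\], one column per variable.
#' @param combiner \code{"am"} (arithmetic mean) or \code{"gm"}
#'   (geometric mean). The AM-GM inequality guarantees GM <= AM.
#' @return numeric HSI vector in \[0, 1\]; rows with any missing value give
#'   \code{NA}.
#' @examples combine_hsi(cbind(0.4, 0.8), "am")
#' @export
combine_hsi <- function(si, combiner = c("am", "gm")) {
  combiner <- match.arg(combiner)
  si <- as.matrix(si)
  if (combiner == "am") rowMeans(si)
  else exp(rowMeans(log(pmax(si, 0))))
}

# small-sample corrected AIC for a Gaussian linear model with k parameters
.aicc <- function(rss, n, k = 3) {
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit and select a habitat-suitability-index model
#'
#' Enumerates candidate HSI models -- every non-empty subset of
#' \code{variables}, crossed with the two SI forms and the two combiners
#' -- fits the SI curves on the training winters, predicts HSI for the
#' testing winters, and scores each candidate by the linear regression of
#' observed (standardized) abundance on predicted HSI: \eqn{R^2} and
#' \eqn{AICc = n \ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)} with \eqn{k = 3}
#' (intercept, slope, residual variance). The candidate with maximum
#' \eqn{R^2} wins; ties (within 1e-9) are decided by minimum AICc. The
#' winner's SI curves are refitted on the pooled training + testing
#' winters.
#'
#' @param grid an \code{env_grid} with catch records.
#' @param train_years,test_years winter years for fitting and validation.
#' @param variables variables to enumerate subsets of.
#' @param forms,combiners candidate SI forms and combiners.
#' @param bins,degree,threshold forwarded to \code{\link{fit_si}}.
#' @return An object of class \code{"hsi_model"}: list with
#'   \code{si_curves} (winner, refitted on all years), \code{combiner},
#'   \code{variables}, \code{form}, \code{validation} (all candidates,
#'   ranked), \code{r2}, \code{aicc}, \code{n_test}, \code{train_years},
#'   \code{test_years}.
#' @export
hsi_select <- function(grid, train_years, test_years,
                       variables = c("depth", "sst", "sss"),
                       forms = c("fitting", "regression"),
                       combiners = c("am", "gm"),
                       bins = 10, degree = 3, threshold = 0.8) {
  if (length(train_years) == 0L || length(test_years) == 0L)
    stop("train and test year sets must be non-empty")
  train <- hsi_observations(grid, train_years)
  test <- hsi_observations(grid, test_years)
  k <- 3
  if (nrow(test) <= k + 1)
    stop("testing set too small for AICc with k = 3")
  train$si_obs <- standardize_abundance(train$catch)
  test$si_obs <- standardize_abundance(test$catch)
  subsets <- unlist(lapply(seq_along(variables), function(m)
    utils::combn(variables, m, simplify = FALSE)), recursive = FALSE)
  cand <- expand.grid(form = forms, combiner = combiners,
                      subset = seq_along(subsets),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cand))
  fits <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    vars <- subsets[[cand$subset[i]]]
    curves <- tryCatch(
      lapply(vars, function(v)
        fit_si(train[[v]], train$si_obs, variable = v,
               form = cand$form[i], bins = bins, degree = degree,
               threshold = threshold)),
      error = function(e) NULL)
    if (is.null(curves)) {
      rows[[i]] <- data.frame(form = cand$form[i],
                              combiner = cand$combiner[i],
                              variables = paste(vars, collapse = "+"),
                              r2 = NA_real_, aicc = NA_real_)
      next
    }
    si_mat <- vapply(curves, function(cv) si_predict(cv, test[[cv$variable]]),
                     numeric(nrow(test)))
    pred <- combine_hsi(matrix(si_mat, nrow = nrow(test)), cand$combiner[i])
    val <- .hsi_validate(test$si_obs, pred, k)
    fits[[i]] <- curves
    rows[[i]] <- data.frame(form = cand$form[i], combiner = cand$combiner[i],
                            variables = paste(vars, collapse = "+"),
                            r2 = val$r2, aicc = val$aicc)
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$r2))) stop("no candidate HSI model could be fitted")
  top <- which(tab$r2 >= max(tab$r2, na.rm = TRUE) - 1e-9)
  best <- top[which.min(tab$aicc[top])]
  ord <- order(-tab$r2, tab$aicc)
  vars <- strsplit(tab$variables[best], "+", fixed = TRUE)[[1]]
  full <- rbind(train, test)
  final_curves <- lapply(vars, function(v)
    fit_si(full[[v]], standardize_abundance(full$catch), variable = v,
           form = tab$form[best], bins = bins, degree = degree,
           threshold = threshold))
  names(final_curves) <- vars
  structure(list(si_curves = final_curves, combiner = tab$combiner[best],
                 variables = vars, form = tab$form[best],
                 validation = data.frame(tab[ord, ], row.names = NULL),
                 r2 = tab$r2[best], aicc = tab$aicc[best],
                 n_test = nrow(test), train_years = train_years,
                 test_years = test_years, threshold = threshold),
            class = "hsi_model")
}

.hsi_validate <- function(obs, pred, k = 3) {
  fit <- stats::lm(obs ~ pred)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((obs - mean(obs))^2)
  n <- length(obs)
  list(r2 = 1 - rss / tss, aicc = .aicc(max(rss, 0), n, k))
}

#' @export
print.hsi_model <- function(x, ...) {
  cat(sprintf("HSI model: %s-based %s of {%s}\n", x$form,
              if (x$combiner == "am") "arithmetic mean" else "geometric mean",
              paste(x$variables, collapse = ", ")))
  cat(sprintf("  validation (train %d-%d, test %d-%d, n = %d): R2 = %.4f, AICc = %.2f\n",
              min(x$train_years), max(x$train_years), min(x$test_years),
              max(x$test_years), x$n_test, x$r2, x$aicc))
  for (cv in x$si_curves)
    cat(sprintf("  %s optimal range: %.2f-%.2f\n", cv$variable,
                cv$optimal_range[1], cv$optimal_range[2]))
  invisible(x)
}

#' @export
summary.hsi_model <- function(object, ...) {
  print(object)
  cat("Candidate ranking (top 6):\n")
  print(utils::head(object$validation, 6))
  invisible(object)
}

#' @export
coef.hsi_model <- function(object, ...) {
  lapply(object$si_curves, `[[`, "params")
}

#' Predict HSI on a grid or data frame
#'
#' @param object an \code{hsi_model}.
#' @param newdata an \code{env_grid} (HSI is computed on winter means for
#'   \code{years}) or a data.frame with one column per model variable.
#' @param years winter years (when \code{newdata} is a grid).
#' @param ... unused.
#' @return data.frame with lon/lat/year (grid input) and \code{hsi}.
#' @export
predict.hsi_model <- function(object, newdata, years = NULL, ...) {
  if (inherits(newdata, "env_grid")) {
    if (is.null(years)) years <- newdata$years
    out <- do.call(rbind, lapply(years, function(y) {
      wm <- winter_mean(newdata, y)
      df <- data.frame(depth = wm$depth_m, sst = wm$sst_c, sss = wm$sss)
      data.frame(lon = wm$lon, lat = wm$lat, year = y,
                 hsi = .hsi_eval(object, df))
    }))
    return(out)
  }
  data.frame(hsi = .hsi_eval(object, newdata))
}

.hsi_eval <- function(model, df) {
  si <- vapply(model$variables, function(v) {
    if (is.null(df[[v]])) stop("missing variable '", v, "' in newdata")
    si_predict(model$si_curves[[v]], df[[v]])
  }, numeric(nrow(df)))
  combine_hsi(matrix(si, nrow = nrow(df)), model$combiner)
}

#' @export
plot.hsi_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$si_curves)))
  on.exit(graphics::par(op))
  for (cv in x$si_curves) {
    gx <- seq(cv$domain[1], cv$domain[2], length.out = 200)
    graphics::plot(gx, si_predict(cv, gx), type = "l", ylim = c(0, 1),
                   xlab = cv$variable, ylab = "SI", ...)
    graphics::abline(h = cv$threshold, lty = 3)
  }
  invisible(x)
}

#' Classify habitat quality and compute area percentages
#'
#' Cells with HSI >= 0.7 are optimal, >= 0.3 average, otherwise poor
#' (closed upper boundaries; configurable). Cell areas are weighted by
#' cos(latitude) so that equal-angle cells contribute their true relative
#' area; percentages are of total (non-missing) area and sum to 100.
#'
#' @param hsi HSI values per cell (NA = missing, excluded).
#' @param lat cell-centre latitudes (degrees), same length.
#' @param thresholds \code{c(average, optimal)} HSI cuts.
#' @return list with \code{class} (factor per cell), \code{pct} (named
#'   percentages: optimal, average, poor).
#' @export
classify_habitat <- function(hsi, lat, thresholds = c(0.3, 0.7)) {
  if (length(hsi) == 0L) stop("empty HSI grid")
  if (length(lat) != length(hsi)) stop("'lat' must match 'hsi'")
  cls <- ifelse(hsi >= thresholds[2], "optimal",
                ifelse(hsi >= thresholds[1], "average", "poor"))
  cls <- factor(cls, levels = c("optimal", "average", "poor"))
  w <- cos(lat * pi / 180)
  ok <- !is.na(hsi)
  if (!any(ok)) stop("no non-missing HSI cells")
  tot <- sum(w[ok])
  pct <- vapply(levels(cls), function(lv)
    100 * sum(w[ok][cls[ok] == lv]) / tot, numeric(1))
  list(class = cls, pct = pct)
}

#' Yearly habitat-class area percentages under an HSI model
#'
#' @param model an \code{hsi_model}.
#' @param grid an \code{env_grid}.
#' @param years winter years to evaluate.
#' @param thresholds forwarded to \code{\link{classify_habitat}}.
#' @return data.frame with year, pct_optimal, pct_average, pct_poor.
#' @export
habitat_timeseries <- function(model, grid, years = grid$years,
                               thresholds = c(0.3, 0.7)) {
  pred <- predict(model, grid, years = years)
  do.call(rbind, lapply(split(pred, pred$year), function(d) {
    p <- classify_habitat(d$hsi, d$lat, thresholds)$pct
    data.frame(year = d$year[1], pct_optimal = p[["optimal"]],
               pct_average = p[["average"]], pct_poor = p[["poor"]])
  }))
}

#' One-way ANOVA with Scheffe post-hoc contrasts across decades
#'
#' Tests whether yearly habitat-class areas differ between decades using
#' a fixed-effects one-way ANOVA (via \code{stats::aov}) followed by
#' Scheffe's simultaneous pairwise contrasts,
#' \eqn{F_s = (\bar y_i - \bar y_j)^2 / [MSE (1/n_i + 1/n_j)]} compared
#' against \eqn{(g-1) F_{g-1, N-g}}. Scheffe p-values are always at least
#' the unadjusted pairwise p-values.
#'
#' @param value numeric response (e.g. yearly percentage of optimal area).
#' @param group grouping factor (e.g. decade label); at least 2 levels
#'   with at least 2 observations each.
#' @return list with \code{f}, \code{p}, \code{df}, \code{scheffe}
#'   (data.frame of pairwise contrasts with adjusted p), and the
#'   \code{aov} fit.
#' @export
decadal_anova <- function(value, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs >= 2 observations")
  fit <- stats::aov(value ~ group)
  tab <- summary(fit)[[1]]
  g <- nlevels(group)
  N <- length(value)
  mse <- tab["Residuals", "Mean Sq"]
  fval <- tab[1, "F value"]
  pval <- tab[1, "Pr(>F)"]
  means <- tapply(value, group, mean)
  ns <- tapply(value, group, length)
  pairs <- utils::combn(levels(group), 2)
  sch <- apply(pairs, 2, function(pr) {
    d <- unname(means[pr[1]] - means[pr[2]])
    fs <- unname(d^2 / (mse * (1 / ns[pr[1]] + 1 / ns[pr[2]])))
    c(diff = d,
      p = stats::pf(fs / (g - 1), g - 1, N - g, lower.tail = FALSE))
  })
  scheffe <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        diff = sch["diff", ], p_scheffe = sch["p", ])
  list(f = fval, p = pval, df = c(g - 1, N - g), scheffe = scheffe,
       fit = fit)
}

#' Linear trend of a winter-mean SST series
#'
#' OLS of area-mean winter SST on year. A constant series returns slope 0
#' with \code{r2 = NA} and a flag.
#'
#' @param year winter years.
#' @param sst area-mean winter SST (deg C), same length.
#' @return list with \code{slope} (deg C / yr), \code{r2}, \code{p},
#'   \code{constant} (logical flag), and the \code{lm} fit (or NULL).
#' @export
winter_sst_trend <- function(year, sst) {
  if (length(year) < 3L) stop("need at least 3 years")
  if (length(sst) != length(year)) stop("'sst' must match 'year'")
  if (stats::sd(sst) == 0)
    return(list(slope = 0, r2 = NA_real_, p = NA_real_, constant = TRUE,
                fit = NULL))
  fit <- stats::lm(sst ~ year)
  sm <- suppressWarnings(summary(fit))  # exact lines are legitimate here
  list(slope = unname(stats::coef(fit)[2]), r2 = sm$r.squared,
       p = unname(sm$coefficients[2, 4]), constant = FALSE, fit = fit)
}

#' Area-mean winter SST series from a grid
#'
#' @param grid an \code{env_grid}.
#' @param years winter years.
#' @return data.frame with year and area-mean (cos-latitude weighted)
#'   winter SST.
#' @export
winter_sst_series <- function(grid, years = grid$years) {
  do.call(rbind, lapply(years, function(y) {
    wm <- winter_mean(grid, y)
    w <- cos(wm$lat * pi / 180)
    data.frame(year = y, sst = sum(wm$sst_c * w) / sum(w))
  }))
}
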