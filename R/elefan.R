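#' Fit seasonalized VBGF growth parameters by ELEFAN
#'
#' Electronic length frequency analysis: the length-frequency data are
#' restructured into signed peak scores (\code{\link{restructure}}) and
#' candidate growth curves are scored by \code{\link{score_rn}}; the
#' workflow chosen by \code{method} searches for the parameter set
#' maximizing \eqn{R_n}.
#'
#' Four workflows are provided:
#' \describe{
#'   \item{\code{"kscan"}}{grid scan over \code{k_grid} at a fixed
#'     \code{linf}; ties go to the smaller K.}
#'   \item{\code{"rsa"}}{response surface analysis: exhaustive evaluation
#'     of \code{linf_grid} x \code{k_grid}; the full surface is returned in
#'     \code{$surface}. Ties go to the smaller (Linf, K).}
#'   \item{\code{"sa"}}{simulated annealing over (Linf, K, C, ts) within
#'     \code{bounds}; geometric cooling.}
#'   \item{\code{"ga"}}{generational genetic algorithm over the same space:
#'     tournament selection, blend crossover, Gaussian mutation, elitism.}
#' }
#' In every workflow the cohort anchor \code{t_anchor} -- a nuisance
#' parameter aligning cohort birthdays with the calendar -- is profiled
#' out on a grid (\code{anchor_grid}; for \code{"sa"}/\code{"ga"} set it
#' via \code{control$anchor_grid}): each candidate is scored at its best
#' anchor. \code{"sa"} and \code{"ga"} require a \code{seed} and are
#' reproducible given one.
#'
#' @param x an \code{\link{lfq}} object.
#' @param method one of \code{"kscan"}, \code{"rsa"}, \code{"sa"},
#'   \code{"ga"}.
#' @param ma odd moving-average window for restructuring.
#' @param linf fixed asymptotic length (mm) for \code{"kscan"}.
#' @param k_grid grid of K values (1/yr) for \code{"kscan"}/\code{"rsa"}.
#' @param linf_grid grid of Linf values (mm) for \code{"rsa"}.
#' @param bounds for \code{"sa"}/\code{"ga"}: a list with elements
#'   \code{linf}, \code{k}, and optionally \code{c_amp} and \code{ts},
#'   each a \code{c(lower, upper)} pair. Omitted seasonal elements are
#'   fixed at 0 (non-seasonal fit).
#' @param seed integer seed (mandatory for \code{"sa"}/\code{"ga"}).
#' @param control list of optimizer settings overriding the defaults
#'   \code{sa_control()}/\code{ga_control()}.
#' @param anchor_grid t_anchor profile grid for grid workflows.
#' @return An object of class \code{"elefan_fit"} with components
#'   \code{params} (\code{\link{vbgf_params}}), \code{rn}, \code{esp},
#'   \code{asp}, \code{workflow}, \code{ma_window}, \code{bin_width},
#'   \code{seed}, and for \code{"rsa"} the score \code{surface}.
#' @examples
#' set.seed(1)
#' lens <- replicate(4, 100 + 40 * rexp(80), simplify = FALSE)
#' names(lens) <- c("2019-01-15", "2019-04-15", "2019-07-15", "2019-10-15")
#' lf <- bin_lengths(lens, bin_mm = 20)
#' fit <- elefan(lf, method = "kscan", linf = 300, k_grid = seq(0.2, 1, 0.2))
#' coef(fit)
#' @export
elefan <- function(x, method = c("sa", "ga", "kscan", "rsa"), ma = 5,
                   linf = NULL, k_grid = NULL, linf_grid = NULL,
                   bounds = NULL, seed = NULL, control = list(),
                   anchor_grid = seq(0, 23 / 24, by = 1 / 24)) {
  stopifnot(inherits(x, "lfq"))
  method <- match.arg(method)
  restr <- restructure(x, ma_window = ma)
  fit <- switch(method,
    kscan = .elefan_kscan(restr, linf, k_grid, anchor_grid),
    rsa   = .elefan_rsa(restr, linf_grid, k_grid, anchor_grid),
    sa    = .elefan_sa(restr, bounds, seed, control),
    ga    = .elefan_ga(restr, bounds, seed, control))
  fit$workflow <- toupper(method)
  fit$ma_window <- ma
  fit$bin_width <- x$bin_width
  fit$restr <- restr
  fit$lfq <- x
  class(fit) <- "elefan_fit"
  fit
}

.rn_at <- function(restr, linf, k, t_anchor, c_amp = 0, ts = 0) {
  p <- vbgf_params(linf = linf, k = k, t_anchor = t_anchor,
                   c_amp = c_amp, ts = ts)
  score_rn(restr, p)
}

# profile Rn over the anchor grid; returns best list(rn, esp, asp, t_anchor)
.rn_profiled <- function(restr, linf, k, anchor_grid, c_amp = 0, ts = 0) {
  best <- NULL
  for (a in anchor_grid) {
    s <- .rn_at(restr, linf, k, a, c_amp, ts)
    if (is.null(best) || s$rn > best$rn) { best <- s; best$t_anchor <- a }
  }
  best
}

.elefan_kscan <- function(restr, linf, k_grid, anchor_grid) {
  if (is.null(linf) || !is.finite(linf) || linf <= 0)
    stop("'kscan' needs a fixed positive 'linf'")
  if (is.null(k_grid) || length(k_grid) == 0L || any(k_grid <= 0))
    stop("'k_grid' must be a non-empty positive grid")
  k_grid <- sort(k_grid)
  best <- NULL
  rns <- numeric(length(k_grid))
  for (i in seq_along(k_grid)) {
    s <- .rn_profiled(restr, linf, k_grid[i], anchor_grid)
    rns[i] <- s$rn
    if (is.null(best) || s$rn > best$rn) { best <- s; best$k <- k_grid[i] }
  }
  params <- vbgf_params(linf = linf, k = best$k, t_anchor = best$t_anchor)
  list(params = params, rn = best$rn, esp = best$esp, asp = best$asp,
       k_scan = data.frame(k = k_grid, rn = rns), seed = NA_integer_)
}

.elefan_rsa <- function(restr, linf_grid, k_grid, anchor_grid) {
  if (is.null(linf_grid) || length(linf_grid) == 0L || any(linf_grid <= 0))
    stop("'linf_grid' must be a non-empty positive grid")
  if (is.null(k_grid) || length(k_grid) == 0L || any(k_grid <= 0))
    stop("'k_grid' must be a non-empty positive grid")
  linf_grid <- sort(linf_grid); k_grid <- sort(k_grid)
  surface <- matrix(NA_real_, length(linf_grid), length(k_grid),
                    dimnames = list(linf = as.character(linf_grid),
                                    k = as.character(k_grid)))
  best <- NULL
  for (i in seq_along(linf_grid)) for (j in seq_along(k_grid)) {
    s <- .rn_profiled(restr, linf_grid[i], k_grid[j], anchor_grid)
    surface[i, j] <- s$rn
    # strict > keeps the smallest (Linf, K) on ties (grids are sorted)
    if (is.null(best) || s$rn > best$rn) {
      best <- s; best$linf <- linf_grid[i]; best$k <- k_grid[j]
    }
  }
  params <- vbgf_params(linf = best$linf, k = best$k,
                        t_anchor = best$t_anchor)
  list(params = params, rn = best$rn, esp = best$esp, asp = best$asp,
       surface = surface, seed = NA_integer_)
}

#' Optimizer settings for the stochastic ELEFAN workflows
#'
#' Defaults: simulated annealing runs \code{n_temp} temperature stages of
#' \code{n_prop} proposals with geometric cooling \code{cooling}, Gaussian
#' proposal steps of \code{step_frac} of each bound range. The genetic
#' algorithm runs \code{generations} generations of a population of
#' \code{pop_size} with tournament selection (size \code{tournament}),
#' blend crossover (\code{alpha}), Gaussian mutation (sd
#' \code{mut_frac} of range, probability \code{mut_prob}) and one elite.
#'
#' @param n_temp,n_prop,cooling,t_init,step_frac simulated-annealing knobs.
#' @param pop_size,generations,tournament,alpha,mut_frac,mut_prob genetic
#'   algorithm knobs.
#' @return a list of settings.
#' @export
sa_control <- function(n_temp = 200, n_prop = 50, cooling = 0.95,
                       t_init = 0.2, step_frac = 0.08) {
  list(n_temp = n_temp, n_prop = n_prop, cooling = cooling,
       t_init = t_init, step_frac = step_frac)
}

#' @rdname sa_control
#' @export
ga_control <- function(pop_size = 50, generations = 100, tournament = 2,
                       alpha = 0.5, mut_frac = 0.02, mut_prob = 0.3) {
  list(pop_size = pop_size, generations = generations,
       tournament = tournament, alpha = alpha, mut_frac = mut_frac,
       mut_prob = mut_prob)
}

# normalize bounds: list(linf=c(lo,hi), k=c(lo,hi), [t_anchor], [c_amp], [ts])
.norm_bounds <- function(bounds) {
  if (is.null(bounds$linf) || is.null(bounds$k))
    stop("'bounds' must contain 'linf' and 'k' ranges")
  if (is.null(bounds$t_anchor)) bounds$t_anchor <- c(0, 1 - 1e-9)
  if (is.null(bounds$c_amp)) bounds$c_amp <- c(0, 0)
  if (is.null(bounds$ts)) bounds$ts <- c(0, 0)
  b <- bounds[c("linf", "k", "t_anchor", "c_amp", "ts")]
  for (nm in names(b)) {
    r <- b[[nm]]
    if (length(r) != 2L || any(!is.finite(r)))
      stop("bound '", nm, "' must be a finite c(lower, upper) pair")
    if (r[2] < r[1]) stop("bound '", nm, "' is inverted")
  }
  b
}

# Rn of (linf, k, c_amp, ts) with the cohort anchor profiled out on a
# grid: t_anchor is a nuisance alignment parameter, so the stochastic
# searches optimize the same anchor-profiled objective as the grid
# workflows, which keeps the score surface tractable.
.rn_free <- function(restr, par, anchor_grid) {
  .rn_profiled(restr, par[1], par[2], anchor_grid, par[3], par[4])$rn
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# run expr with a private RNG stream; global .Random.seed untouched
.with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed)) stop("a 'seed' is required")
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

.sa_ga_bounds <- function(bounds) {
  b <- .norm_bounds(bounds)
  b <- b[c("linf", "k", "c_amp", "ts")]
  list(lo = vapply(b, `[`, numeric(1), 1L),
       hi = vapply(b, `[`, numeric(1), 2L))
}

.sa_ga_result <- function(restr, par, anchor_grid, seed, ctrl) {
  par <- unname(par)
  s <- .rn_profiled(restr, par[1], par[2], anchor_grid, par[3], par[4])
  params <- vbgf_params(linf = par[1], k = par[2], t_anchor = s$t_anchor,
                        c_amp = par[3], ts = par[4])
  list(params = params, rn = s$rn, esp = s$esp, asp = s$asp,
       seed = as.integer(seed), control = ctrl)
}

.elefan_sa <- function(restr, bounds, seed, control) {
  ctrl <- utils::modifyList(sa_control(), control)
  ag <- ctrl$anchor_grid
  if (is.null(ag)) ag <- seq(0, 23 / 24, by = 1 / 24)
  bb <- .sa_ga_bounds(bounds)
  lo <- bb$lo; hi <- bb$hi
  rng <- hi - lo
  free <- rng > 0
  .with_seed(seed, {
    par <- lo + stats::runif(4) * rng
    cur_rn <- .rn_free(restr, par, ag)
    best_par <- par; best_rn <- cur_rn
    temp <- ctrl$t_init
    for (it in seq_len(ctrl$n_temp)) {
      for (pr in seq_len(ctrl$n_prop)) {
        cand <- par
        cand[free] <- .clamp(par[free] +
                               stats::rnorm(sum(free), 0,
                                            ctrl$step_frac * rng[free]),
                             lo[free], hi[free])
        rn <- .rn_free(restr, cand, ag)
        if (rn >= cur_rn ||
            stats::runif(1) < exp((rn - cur_rn) / temp)) {
          par <- cand; cur_rn <- rn
          if (rn > best_rn) { best_rn <- rn; best_par <- cand }
        }
      }
      temp <- temp * ctrl$cooling
    }
    .sa_ga_result(restr, best_par, ag, seed, ctrl)
  })
}

.elefan_ga <- function(restr, bounds, seed, control) {
  ctrl <- utils::modifyList(ga_control(), control)
  ag <- ctrl$anchor_grid
  if (is.null(ag)) ag <- seq(0, 23 / 24, by = 1 / 24)
  bb <- .sa_ga_bounds(bounds)
  lo <- bb$lo; hi <- bb$hi
  rng <- hi - lo
  free <- rng > 0
  np <- ctrl$pop_size
  .with_seed(seed, {
    pop <- t(vapply(seq_len(np), function(i) lo + stats::runif(4) * rng,
                    numeric(4)))
    fit <- apply(pop, 1, function(p) .rn_free(restr, p, ag))
    for (g in seq_len(ctrl$generations)) {
      elite_i <- which.max(fit)
      newpop <- matrix(NA_real_, np, 4)
      newpop[1, ] <- pop[elite_i, ]
      for (m in seq(2, np)) {
        p1 <- .ga_tournament(fit, ctrl$tournament)
        p2 <- .ga_tournament(fit, ctrl$tournament)
        # blend crossover
        gamma <- stats::runif(4, -ctrl$alpha, 1 + ctrl$alpha)
        child <- gamma * pop[p1, ] + (1 - gamma) * pop[p2, ]
        # Gaussian mutation
        mut <- stats::runif(4) < ctrl$mut_prob
        mut <- mut & free
        if (any(mut))
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0, ctrl$mut_frac * rng[mut])
        child <- .clamp(child, lo, hi)
        newpop[m, ] <- child
      }
      pop <- newpop
      fit <- apply(pop, 1, function(p) .rn_free(restr, p, ag))
    }
    best <- which.max(fit)
    .sa_ga_result(restr, pop[best, ], ag, seed, ctrl)
  })
}

.ga_tournament <- function(fit, size) {
  cand <- sample.int(length(fit), size, replace = TRUE)
  cand[which.max(fit[cand])]
}

#' @export
print.elefan_fit <- function(x, ...) {
  cat(sprintf("ELEFAN %s fit (bin = %g mm, MA = %d)\n",
              x$workflow, x$bin_width, x$ma_window))
  p <- x$params
  cat(sprintf("  Linf = %.1f mm, K = %.3f 1/yr, t_anchor = %.3f, C = %.2f, ts = %.2f\n",
              p$linf, p$k, p$t_anchor, p$c_amp, p$ts))
  cat(sprintf("  Rn = %.3f (ESP = %.2f, ASP = %.2f)\n", x$rn, x$esp, x$asp))
  invisible(x)
}

#' @export
summary.elefan_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  data: %d fish, %d samples, %.3f-%.3f\n",
              sum(object$lfq$counts), length(object$lfq$dates),
              min(object$lfq$dates), max(object$lfq$dates)))
  invisible(object)
}

#' @export
coef.elefan_fit <- function(object, ...) {
  p <- object$params
  c(linf = p$linf, k = p$k, t_anchor = p$t_anchor,
    c_amp = p$c_amp, ts = p$ts)
}

#' Predicted length-at-age from an ELEFAN fit
#'
#' @param object an \code{elefan_fit}.
#' @param age relative ages (yr from length zero).
#' @param ... unused.
#' @return predicted lengths (mm).
#' @export
predict.elefan_fit <- function(object, age, ...) {
  vbgf_length(object$params, age)
}

#' @export
plot.elefan_fit <- function(x, ...) {
  v <- x$restr$values
  graphics::image(x = x$restr$dates, y = .lfq_mids(x$restr),
                  z = t(v), col = grDevices::hcl.colors(21, "Blue-Red 2"),
                  xlab = "year", ylab = "length (mm)", ...)
  max_age <- min(log(1000) / x$params$k, 50)
  births <- (floor(min(x$restr$dates) - max_age):floor(max(x$restr$dates))) +
    x$params$t_anchor
  tt <- seq(min(x$restr$dates) - 0.05, max(x$restr$dates) + 0.05,
            length.out = 200)
  for (b in births) {
    a <- tt - b
    keep <- a > 0
    if (any(keep))
      graphics::lines(tt[keep], vbgf_length(x$params, a[keep], birth = b))
  }
  invisible(x)
}

#' Run the full ELEFAN scenario sweep
#'
#' Fits every combination of bin width, moving-average window and workflow
#' to raw per-date length lists and ranks the fits by \eqn{R_n}
#' (descending; ties keep input order).
#'
#' @param lengths named list of per-date length vectors (as in
#'   \code{\link{bin_lengths}}).
#' @param bins bin widths (mm) to try.
#' @param mas moving-average windows to try.
#' @param workflows subset of \code{c("kscan", "rsa", "sa", "ga")}.
#' @param seed base seed; each stochastic fit uses a distinct seed derived
#'   from it.
#' @param linf,k_grid,linf_grid,bounds,control forwarded to
#'   \code{\link{elefan}}; \code{linf} defaults to the midpoint of
#'   \code{bounds$linf}, the grids to 15-point grids over \code{bounds}.
#' @return An object of class \code{"elefan_sweep"}: list with
#'   \code{fits} (all fits, ranked by Rn), \code{table} (data.frame of
#'   scenario metadata and Rn) and \code{best}.
#' @export
elefan_sweep <- function(lengths, bins = c(10, 20), mas = c(5, 7, 9, 11),
                         workflows = c("kscan", "rsa", "sa", "ga"),
                         seed = 1, bounds, linf = NULL, k_grid = NULL,
                         linf_grid = NULL, control = list()) {
  b <- .norm_bounds(bounds)
  if (is.null(linf)) linf <- mean(b$linf)
  if (is.null(k_grid)) k_grid <- seq(b$k[1], b$k[2], length.out = 15)
  if (is.null(linf_grid))
    linf_grid <- seq(b$linf[1], b$linf[2], length.out = 15)
  grid <- expand.grid(bin = bins, ma = mas, workflow = workflows,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    lf <- bin_lengths(lengths, bin_mm = grid$bin[i])
    fits[[i]] <- elefan(lf, method = grid$workflow[i], ma = grid$ma[i],
                        linf = linf, k_grid = k_grid,
                        linf_grid = linf_grid, bounds = bounds,
                        seed = seed + i, control = control)
  }
  rn <- vapply(fits, `[[`, numeric(1), "rn")
  ord <- order(rn, decreasing = TRUE)
  tab <- data.frame(grid[ord, , drop = FALSE], rn = rn[ord],
                    row.names = NULL)
  structure(list(fits = fits[ord], table = tab, best = fits[[ord[1]]]),
            class = "elefan_sweep")
}

#' @export
print.elefan_sweep <- function(x, ...) {
  cat(sprintf("ELEFAN scenario sweep: %d fits\n", nrow(x$table)))
  print(utils::head(x$table, 10))
  cat("Best fit:\n")
  print(x$best)
  invisible(x)
}
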