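#' Population scenario for length-frequency simulation
#'
#' Bundles the ground-truth life history used by
#' \code{\link{simulate_length_frequencies}}: seasonal VBGF growth, total
#' mortality, logistic gear selectivity, recruitment pulsing and the
#' sampling design. Defaults are the assessment's study conditions: the
#' growth and mortality of the current large yellow croaker stock and a
#' seasonal bottom-trawl survey.
#'
#' @param linf,k,t0,c_amp,ts seasonal VBGF parameters (mm, 1/yr, yr,
#'   unitless in \[0, 1\], year fraction).
#' @param z total mortality (1/yr), > 0.
#' @param sel_l50,sel_l95 logistic selectivity lengths (mm),
#'   \code{sel_l95 > sel_l50}; set \code{sel_l50 = 0} for a fully selected
#'   (knife-edge at zero) gear.
#' @param recruit_pulses 1 or 2 recruitment pulses per year.
#' @param t_anchor fraction of year at which the (first) pulse is born.
#' @param sample_dates calendar dates of the surveys.
#' @param n_per_sample fish measured per survey.
#' @param cv_length CV of individual length about mean length-at-age.
#' @param seed integer seed.
#' @return a \code{"population_scenario"} list.
#' @export
population_scenario <- function(linf = 434, k = 0.43, t0 = -0.06,
                                c_amp = 0, ts = 0, z = 1.87,
                                sel_l50 = 0, sel_l95 = 50,
                                recruit_pulses = 1, t_anchor = 0,
                                sample_dates = c("2018-11-18", "2019-01-20",
                                                 "2019-04-18", "2019-07-17",
                                                 "2019-09-28", "2019-11-18"),
                                n_per_sample = 350, cv_length = 0.06,
                                seed = 1) {
  nums <- c(linf = linf, k = k, t0 = t0, c_amp = c_amp, ts = ts, z = z,
            sel_l50 = sel_l50, sel_l95 = sel_l95, cv_length = cv_length)
  if (any(!is.finite(nums)))
    stop("invalid scenario: non-finite parameter(s) ",
         paste(names(nums)[!is.finite(nums)], collapse = ", "))
  if (linf <= 0 || k <= 0 || z <= 0)
    stop("invalid scenario: linf, k, z must be positive")
  if (c_amp < 0 || c_amp > 1) stop("invalid scenario: c_amp outside [0, 1]")
  if (sel_l95 <= sel_l50)
    stop("invalid scenario: sel_l95 must exceed sel_l50")
  if (!recruit_pulses %in% c(1L, 2L))
    stop("invalid scenario: recruit_pulses must be 1 or 2")
  if (n_per_sample < 1) stop("invalid scenario: n_per_sample must be >= 1")
  if (cv_length < 0) stop("invalid scenario: cv_length must be >= 0")
  structure(list(linf = linf, k = k, t0 = t0, c_amp = c_amp, ts = ts,
                 z = z, sel_l50 = sel_l50, sel_l95 = sel_l95,
                 recruit_pulses = as.integer(recruit_pulses),
                 t_anchor = t_anchor,
                 sample_dates = as.Date(sample_dates),
                 n_per_sample = as.integer(n_per_sample),
                 cv_length = cv_length, seed = as.integer(seed)),
            class = "population_scenario")
}

#' Simulate date-stamped length samples from a cohort population
#'
#' For each sample date, fish are generated by (1) drawing cohort ages
#' from the equilibrium exponential age distribution with rate \code{z}
#' (truncated where survival falls below 1e-4), cohorts being born at
#' \code{year + t_anchor} (plus a half-year offset for the second pulse);
#' (2) mapping age to mean length through the seasonal VBGF, in calendar
#' phase with the cohort's birth date; (3) adding Gaussian individual
#' variation with CV \code{cv_length} (non-positive draws are discarded);
#' (4) retaining fish with logistic selectivity probability in length.
#' Rejection sampling continues until exactly \code{n_per_sample} fish are
#' retained per date. Identical seeds give identical output.
#'
#' @param scenario a \code{\link{population_scenario}}.
#' @return named list (ISO date names) of measured lengths (mm), with the
#'   scenario attached as attribute \code{"scenario"}; feed to
#'   \code{\link{bin_lengths}}.
#' @export
simulate_length_frequencies <- function(scenario) {
  stopifnot(inherits(scenario, "population_scenario"))
  sc <- scenario
  growth <- vbgf_params(linf = sc$linf, k = sc$k,
                        t_anchor = sc$t_anchor %% 1,
                        c_amp = sc$c_amp, ts = sc$ts)
  offsets <- if (sc$recruit_pulses == 2L) c(0, 0.5) else 0
  t_max <- log(1e4) / sc$z
  dates <- decimal_year(sc$sample_dates)
  .with_seed(sc$seed, {
    out <- lapply(dates, function(d) {
      births <- as.vector(outer(seq(floor(d - t_max) - 1, floor(d)),
                                sc$t_anchor + offsets, `+`))
      ages <- d - births
      okc <- ages > 0 & ages <= t_max
      births <- births[okc]; ages <- ages[okc]
      wts <- exp(-sc$z * ages)
      kept <- numeric(0)
      while (length(kept) < sc$n_per_sample) {
        need <- sc$n_per_sample - length(kept)
        draw <- max(2L * need, 32L)
        ci <- sample.int(length(ages), draw, replace = TRUE, prob = wts)
        mu <- vbgf_length(growth, ages[ci], birth = births[ci])
        len <- if (sc$cv_length > 0)
          stats::rnorm(draw, mu, sc$cv_length * mu) else mu
        psel <- .logistic_sel(len, sc$sel_l50, sc$sel_l95)
        acc <- len > 0 & stats::runif(draw) < psel
        kept <- c(kept, len[acc])
      }
      kept[seq_len(sc$n_per_sample)]
    })
    names(out) <- as.character(sc$sample_dates)
    attr(out, "scenario") <- sc
    out
  })
}

.logistic_sel <- function(len, l50, l95) {
  if (l50 <= 0) return(rep(1, length(len)))
  1 / (1 + exp(-log(19) * (len - l50) / (l95 - l50)))
}

#' Habitat scenario for environment/catch grid simulation
#'
#' Ground truth for \code{\link{simulate_environment_and_catch}}: a 0.5
#' degree grid over the mid-southern East China Sea overwintering ground,
#' with a static depth field (deepening offshore), monthly SST carrying a
#' meridional gradient, a seasonal cycle, a linear long-term trend and
#' fixed per-cell spatial structure, monthly SSS, and annual winter catch
#' whose expectation is proportional to a known true habitat suitability
#' index built as the arithmetic mean of unimodal (Gaussian) suitability
#' curves. The default suitability modes and widths place the optimal
#' ranges at 36-72 m depth, 18.2-20.5 deg C SST, and 33.89-34.27 SSS (the
#' width of a Gaussian whose value is 0.8 at the range endpoints).
#'
#' @param lon_range,lat_range extent (degrees east/north).
#' @param resolution grid step (degrees).
#' @param years winter years (a winter is December of \code{year} through
#'   February of \code{year + 1}).
#' @param si_true named list (\code{depth}, \code{sst}, \code{sss}) of
#'   \code{c(mode, width)} pairs for the true Gaussian suitability curves.
#' @param hsi_vars variables actually entering the true HSI.
#' @param catch_noise_cv lognormal CV of the catch observation noise.
#' @param sst_trend_per_yr linear SST drift (deg C / yr).
#' @param depth_noise_sd,sst_noise_sd,sss_noise_sd standard deviations of
#'   the fixed per-cell spatial structure superimposed on the smooth
#'   depth/SST/SSS gradients (same offsets every year and month).
#' @param q_catch catch (tons) in a perfectly suitable cell.
#' @param seed integer seed.
#' @return a \code{"habitat_scenario"} list.
#' @export
habitat_scenario <- function(lon_range = c(120, 126), lat_range = c(25, 29),
                             resolution = 0.5, years = 1971:1982,
                             si_true = list(depth = c(mode = 54, width = 26.9),
                                            sst = c(mode = 19.35, width = 1.72),
                                            sss = c(mode = 34.08, width = 0.28)),
                             hsi_vars = c("depth", "sst"),
                             catch_noise_cv = 0.3,
                             sst_trend_per_yr = -0.028,
                             depth_noise_sd = 4, sst_noise_sd = 0.3,
                             sss_noise_sd = 0.05,
                             q_catch = 100, seed = 1) {
  if (length(years) == 0L) stop("'years' must be non-empty")
  if (resolution <= 0) stop("'resolution' must be > 0")
  if (catch_noise_cv < 0) stop("'catch_noise_cv' must be >= 0")
  widths <- vapply(si_true, `[`, numeric(1), 2L)
  if (any(widths <= 0)) stop("every true SI width must be > 0")
  if (!all(hsi_vars %in% names(si_true)))
    stop("'hsi_vars' must name entries of 'si_true'")
  if (depth_noise_sd < 0 || sst_noise_sd < 0 || sss_noise_sd < 0)
    stop("spatial noise standard deviations must be >= 0")
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 resolution = resolution, years = as.integer(years),
                 si_true = si_true, hsi_vars = hsi_vars,
                 catch_noise_cv = catch_noise_cv,
                 sst_trend_per_yr = sst_trend_per_yr,
                 depth_noise_sd = depth_noise_sd,
                 sst_noise_sd = sst_noise_sd, sss_noise_sd = sss_noise_sd,
                 q_catch = q_catch, seed = as.integer(seed)),
            class = "habitat_scenario")
}

#' Simulate an environmental/catch grid with known true HSI
#'
#' Builds the gridded fields described in \code{\link{habitat_scenario}}
#' and, per winter year, an annual catch per cell: expected catch =
#' \code{q_catch} x true HSI (arithmetic mean of the true Gaussian
#' suitability curves evaluated on the winter-mean fields), multiplied by
#' mean-one lognormal noise with CV \code{catch_noise_cv}. The per-cell
#' spatial structure (depth noise, SST/SSS offsets) is drawn once and held
#' fixed across all years and months, so the SST trend is exactly
#' estimable from winter means. The true HSI is stored per cell-year for
#' recovery tests.
#'
#' @param scenario a \code{\link{habitat_scenario}}.
#' @return An object of class \code{"env_grid"}: list with \code{cells}
#'   (lon, lat, depth_m), \code{monthly} (lon, lat, year, month, sst_c,
#'   sss), \code{catch} (lon, lat, year, catch_t, true_hsi),
#'   \code{resolution}, \code{years}, and the scenario.
#' @export
simulate_environment_and_catch <- function(scenario) {
  stopifnot(inherits(scenario, "habitat_scenario"))
  sc <- scenario
  res <- sc$resolution
  lon <- seq(sc$lon_range[1] + res / 2, sc$lon_range[2] - res / 2, by = res)
  lat <- seq(sc$lat_range[1] + res / 2, sc$lat_range[2] - res / 2, by = res)
  cells <- expand.grid(lon = lon, lat = lat)
  nc <- nrow(cells)
  .with_seed(sc$seed, {
    # smooth shelf deepening offshore; per-cell bathymetric roughness
    depth <- pmax(5, 18 + 16 * (cells$lon - sc$lon_range[1]) +
                    stats::rnorm(nc, 0, sc$depth_noise_sd))
    sst_off <- stats::rnorm(nc, 0, sc$sst_noise_sd)
    sss_off <- stats::rnorm(nc, 0, sc$sss_noise_sd)
    # monthly SST anomalies about the annual mean (deg C), peak in August
    mon_eff <- c(-3.5, -3.5, -2.5, -1, 1, 2.5, 3.5, 4, 3, 1.5, -0.5, -2)
    cells$depth_m <- depth
    # monthly fields for every winter month of every year
    mon_tab <- unique(rbind(
      data.frame(year = sc$years, month = 12L),
      data.frame(year = sc$years + 1L, month = 1L),
      data.frame(year = sc$years + 1L, month = 2L)))
    monthly <- do.call(rbind, lapply(seq_len(nrow(mon_tab)), function(i) {
      y <- mon_tab$year[i]; m <- mon_tab$month[i]
      tt <- y + (m - 0.5) / 12
      sst <- 25.5 + mon_eff[m] - 1.4 * (cells$lat - sc$lat_range[1]) +
        sc$sst_trend_per_yr * (tt - sc$years[1]) + sst_off
      sss <- 34.0 + 0.03 * (cells$lat - sc$lat_range[1]) +
        0.05 * cos(2 * pi * (m - 3) / 12) + sss_off
      data.frame(lon = cells$lon, lat = cells$lat, year = y, month = m,
                 sst_c = sst, sss = sss)
    }))
    grid <- structure(list(cells = cells, monthly = monthly,
                           catch = NULL, resolution = res,
                           years = sc$years, scenario = sc),
                      class = "env_grid")
    sdlog <- sqrt(log(1 + sc$catch_noise_cv^2))
    catch <- do.call(rbind, lapply(sc$years, function(y) {
      wm <- winter_mean(grid, y)
      si <- vapply(sc$hsi_vars, function(v) {
        pr <- sc$si_true[[v]]
        x <- switch(v, depth = cells$depth_m, sst = wm$sst_c, sss = wm$sss)
        exp(-(x - pr[1])^2 / (2 * pr[2]^2))
      }, numeric(nc))
      hsi <- rowMeans(matrix(si, nrow = nc))
      noise <- if (sc$catch_noise_cv > 0)
        exp(stats::rnorm(nc, -sdlog^2 / 2, sdlog)) else 1
      data.frame(lon = cells$lon, lat = cells$lat, year = y,
                 catch_t = sc$q_catch * hsi * noise, true_hsi = hsi)
    }))
    grid$catch <- catch
    grid
  })
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("Environmental grid: %d cells at %g deg, winters %d-%d\n",
              nrow(x$cells), x$resolution, min(x$years), max(x$years)))
  if (!is.null(x$catch))
    cat(sprintf("  catch records: %d cell-years\n", nrow(x$catch)))
  invisible(x)
}
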