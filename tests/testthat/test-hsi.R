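test_that("abundance standardization scales to the dataset maximum", {
  expect_equal(standardize_abundance(c(2, 5, 10)), c(0.2, 0.5, 1.0))
  expect_equal(standardize_abundance(7), 1)
  expect_equal(standardize_abundance(c(3, 3, 1)), c(1, 1, 1 / 3))
  expect_error(standardize_abundance(c(0, 0)), "all-zero")
  expect_error(standardize_abundance(c(-1, 2)), "non-negative")
})

test_that("fitting-based SI recovers a Gaussian suitability curve", {
  # SI = 0.8 exactly at 18.2 and 20.5 degC (mode 19.35)
  sigma <- (20.5 - 18.2) / 2 / sqrt(2 * log(1 / 0.8))
  x <- seq(15, 24, length.out = 300)
  y <- exp(-(x - 19.35)^2 / (2 * sigma^2))
  cv <- fit_si(x, y, variable = "sst", form = "fitting")
  expect_equal(unname(cv$params["mode"]), 19.35, tolerance = 0.05)
  expect_equal(cv$optimal_range[1], 18.2, tolerance = 0.1)
  expect_equal(cv$optimal_range[2], 20.5, tolerance = 0.1)
  # peak suitability is 1 after normalization
  expect_equal(si_predict(cv, unname(cv$params["mode"])), 1)
  # degenerate response is rejected
  expect_error(fit_si(x, rep(1, length(x)), form = "fitting"), "degenerate")
  expect_error(fit_si(rep(5, 10), runif(10), form = "fitting"), "distinct")
})

test_that("regression-based SI reduces to OLS and clips predictions", {
  x <- seq(0, 10, 0.5)
  y <- 1 - 0.01 * (x - 5)^2             # exact quadratic peak
  cv <- fit_si(x, y, variable = "depth", form = "regression", degree = 2)
  expect_equal(unname(cv$params[3]), -0.01, tolerance = 1e-10)
  # linear data, degree 1: slope equals the simple OLS slope
  yl <- 0.05 + 0.08 * x
  cl <- fit_si(x, yl, form = "regression", degree = 1)
  expect_equal(unname(cl$params[2]), 0.08, tolerance = 1e-10)
  # predictions outside [0, 1] are clipped
  neg <- fit_si(x, pmax(0, 0.9 - 0.2 * x), form = "regression", degree = 1)
  expect_gte(min(si_predict(neg, seq(0, 10, 0.1))), 0)
  expect_lte(max(si_predict(neg, seq(0, 10, 0.1))), 1)
})

test_that("HSI combiners obey their definitions and the AM-GM inequality", {
  expect_equal(combine_hsi(cbind(0.4, 0.8), "am"), 0.6)
  expect_equal(combine_hsi(cbind(0.25, 1.0), "gm"), 0.5)
  expect_equal(combine_hsi(cbind(0, 0.9, 0.9), "gm"), 0)
  set.seed(2)
  si <- matrix(runif(3e5), ncol = 3)
  am <- combine_hsi(si, "am")
  gm <- combine_hsi(si, "gm")
  expect_true(all(gm <= am + 1e-12))
  expect_true(all(am >= 0 & am <= 1))
})

test_that("winter means average Dec/Jan/Feb and name missing months", {
  hs <- zero_noise_habitat()
  g <- simulate_environment_and_catch(hs)
  wm <- winter_mean(g, 1975)
  m <- g$monthly
  pick <- function(yr, mo) {
    d <- m[m$year == yr & m$month == mo, ]
    d[order(d$lat, d$lon), "sst_c"]
  }
  expect_equal(wm[order(wm$lat, wm$lon), "sst_c"],
               (pick(1975, 12) + pick(1976, 1) + pick(1976, 2)) / 3)
  # order invariance: shuffling monthly rows changes nothing
  g2 <- g
  set.seed(1)
  g2$monthly <- g$monthly[sample(nrow(g$monthly)), ]
  expect_equal(winter_mean(g2, 1975), wm)
  # the winter after the last simulated one lacks its January
  expect_error(winter_mean(g, max(hs$years) + 1), "missing month")
})

test_that("habitat classification weights area by latitude and sums to 100", {
  cls <- classify_habitat(c(0.75, 0.5, 0.2), lat = c(27, 27, 27))
  expect_equal(unname(cls$pct), rep(100 / 3, 3))
  expect_equal(sum(cls$pct), 100)
  expect_equal(unname(classify_habitat(rep(0.8, 5), rep(26, 5))$pct[1]), 100)
  # closed upper boundaries: 0.7 is optimal, 0.3 is average
  b <- classify_habitat(c(0.7, 0.3), c(25, 25))
  expect_equal(as.character(b$class), c("optimal", "average"))
  # cos(lat) weighting: equal split only at equal latitudes
  w <- classify_habitat(c(0.9, 0.1), lat = c(0, 60))
  expect_equal(unname(w$pct[["optimal"]]), 100 * cos(0) / (cos(0) + cos(pi / 3)))
  expect_error(classify_habitat(numeric(0), numeric(0)), "empty")
})

test_that("one-way ANOVA matches a hand computation and Scheffe is conservative", {
  value <- c(12, 14, 13, 18, 19, 21, 25, 24, 26)
  group <- rep(c("a", "b", "c"), each = 3)
  an <- decadal_anova(value, group)
  gm <- mean(value)
  means <- tapply(value, group, mean)
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((value - means[group])^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(an$f, f_hand)
  expect_equal(an$p, pf(f_hand, 2, 6, lower.tail = FALSE))
  # Scheffe adjusted p >= unadjusted pairwise p
  mse <- ssw / 6
  for (r in seq_len(nrow(an$scheffe))) {
    d <- an$scheffe$diff[r]
    t_un <- abs(d) / sqrt(mse * (2 / 3))
    p_un <- 2 * pt(t_un, 6, lower.tail = FALSE)
    expect_gte(an$scheffe$p_scheffe[r], p_un - 1e-12)
  }
  # identical groups carry no between-group signal
  an0 <- decadal_anova(rep(c(1, 2), 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(an0$f, 0)
  expect_error(decadal_anova(1:3, c("a", "a", "b")), ">= 2")
})

test_that("trend regression is exact on a noise-free line and flags constants", {
  yr <- 1971:2019
  tr <- winter_sst_trend(yr, 20 - 0.028 * (yr - 1971))
  expect_equal(tr$slope, -0.028, tolerance = 1e-12)
  cst <- winter_sst_trend(yr, rep(19, length(yr)))
  expect_equal(cst$slope, 0)
  expect_true(cst$constant)
  expect_error(winter_sst_trend(1:2, c(1, 2)), "3 years")
  # noisy series: estimate within 3 standard errors of truth
  set.seed(8)
  s <- 20 - 0.028 * (yr - 1971) + rnorm(length(yr), 0, 0.3)
  trn <- winter_sst_trend(yr, s)
  se <- summary(trn$fit)$coefficients[2, 2]
  expect_lt(abs(trn$slope + 0.028), 3 * se)
})

test_that("AICc penalizes parameters and decreases with RSS", {
  expect_equal(stockhab:::.aicc(24, 24, 3), 24 * log(1) + 6 + 24 / 20)
  expect_equal(stockhab:::.aicc(24, 24, 3), 7.2)
  expect_lt(stockhab:::.aicc(10, 24, 3), stockhab:::.aicc(20, 24, 3))
})

test_that("model selection recovers the generating HSI structure without noise", {
  g <- simulate_environment_and_catch(zero_noise_habitat())
  m <- hsi_select(g, train_years = 1971:1980, test_years = 1981:1982)
  expect_equal(m$form, "fitting")
  expect_equal(m$combiner, "am")
  expect_setequal(m$variables, c("depth", "sst"))
  expect_equal(m$r2, 1, tolerance = 1e-9)
  expect_equal(unname(m$si_curves[["depth"]]$params["mode"]), 54,
               tolerance = 0.01 * 54)
  expect_equal(unname(m$si_curves[["sst"]]$params["mode"]), 19.35,
               tolerance = 0.01 * 19.35)
  # predictions live in [0, 1] and respond to the model variables
  pr <- predict(m, g, years = 1981)
  expect_true(all(pr$hsi >= 0 & pr$hsi <= 1))
  # the validation table ranks all 28 candidates
  expect_equal(nrow(m$validation), 28)
  expect_error(hsi_select(g, integer(0), 1981:1982), "non-empty")
})
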