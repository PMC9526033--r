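# exact expected bin counts of an equilibrium cohort decaying at rate z
.expected_lfq <- function(growth, z, bin = 10, lmin = 30, scale = 1e6,
                          sel_t50 = NULL, sel_t95 = NULL) {
  bl <- seq(lmin, growth$linf - bin - growth$linf %% bin, bin)
  t_lo <- vbgf_age(growth, bl)
  t_hi <- vbgf_age(growth, bl + bin)
  n <- scale * (exp(-z * t_lo) - exp(-z * t_hi)) / z
  if (!is.null(sel_t50)) {
    t_mid <- vbgf_age(growth, bl + bin / 2)
    n <- n * stats::plogis(log(19) * (t_mid - sel_t50) / (sel_t95 - sel_t50))
  }
  lfq(bl, 2019, matrix(n, ncol = 1))
}

test_that("catch curve recovers Z from exact expected counts within 1%", {
  g <- vbgf_params(linf = 434, k = 0.43)
  lf <- .expected_lfq(g, z = 1.87)
  cc <- catch_curve(lf, g)
  expect_lt(abs(cc$z / 1.87 - 1), 0.01)
  expect_true(is.finite(cc$se))
  # slope estimator equals closed-form OLS on the same points
  p <- cc$points[cc$points$used, ]
  y <- p$log_n_dt; x <- p$t
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(cc$z, -slope)
})

test_that("a population with no mortality gives slope zero", {
  g <- vbgf_params(linf = 434, k = 0.43)
  bl <- seq(30, 400, 10)
  t_lo <- vbgf_age(g, bl); t_hi <- vbgf_age(g, bl + 10)
  lf <- lfq(bl, 2019, matrix(1000 * (t_hi - t_lo), ncol = 1))
  cc <- catch_curve(lf, g, points = seq(5, 35))
  expect_equal(cc$z, 0, tolerance = 1e-10)
})

test_that("degenerate descending limbs are rejected", {
  g <- vbgf_params(linf = 434, k = 0.43)
  lf <- .expected_lfq(g, z = 1.87)
  expect_error(catch_curve(lf, g, points = c(4, 5)), "at least 3")
  # bins at or above Linf are excluded with a warning
  bl <- seq(380, 440, 10)
  lf2 <- lfq(bl, 2019, matrix(c(100, 60, 30, 20, 10, 5, 2), ncol = 1))
  expect_warning(try(catch_curve(lf2, g), silent = TRUE), "Linf")
})

test_that("empirical M estimators match their closed formulas", {
  g <- vbgf_params(linf = 434, k = 0.43)
  m_user <- natural_mortality(g, "user", m = 0.30)
  expect_equal(as.numeric(m_user), 0.30)
  m_p <- natural_mortality(g, "pauly_T", temp_c = 19)
  expect_equal(as.numeric(m_p),
               10^(-0.0066 - 0.279 * log10(43.4) + 0.6543 * log10(0.43) +
                     0.4634 * log10(19)))
  m_t <- natural_mortality(g, "then_growth")
  expect_equal(as.numeric(m_t), 4.118 * 0.43^0.73 * 43.4^(-0.33))
  expect_error(natural_mortality(g, "pauly_T"), "temp_c")
  expect_error(natural_mortality(g, "user"), "'m'")
})

test_that("mortality partition reproduces the assessment identities", {
  # current stock: Z = 1.87 with M = 0.30
  cur <- exploitation(z = 1.87, m = 0.30)
  expect_equal(cur$f, 1.57)
  expect_equal(round(cur$e, 2), 0.84)
  expect_equal(cur$z, cur$f + cur$m)
  # 1980s stock: Z = 1.02 with M = 0.18
  his <- exploitation(z = 1.02, m = 0.18)
  expect_equal(his$f, 0.84)
  expect_equal(round(his$e, 3), 0.824)
  expect_equal(his$z, his$f + his$m)
  # boundary and error cases
  eq <- exploitation(z = 0.5, m = 0.5)
  expect_equal(eq$f, 0)
  expect_equal(eq$e, 0)
  expect_error(exploitation(z = 0.5, m = 0.6), "implausible")
})

test_that("capture ogive recovers an exact logistic to high precision", {
  g <- vbgf_params(linf = 434, k = 0.43)
  # counts exactly on the catch-curve line times an exact logistic ogive
  bl <- seq(30, 420, 10)
  t_mid <- vbgf_age(g, bl + 5)
  dt <- vbgf_age(g, bl + 10) - vbgf_age(g, bl)
  P <- stats::plogis(log(19) * (t_mid - 0.37) / (0.49 - 0.37))
  lf <- lfq(bl, 2019, matrix(exp(10 - 1.87 * t_mid) * dt * P, ncol = 1))
  cc <- catch_curve(lf, g, points = which(t_mid >= 1.3))
  og <- catch_ogive(cc)
  expect_equal(og$t50, 0.37, tolerance = 1e-6)
  expect_equal(og$t95, 0.49, tolerance = 1e-6)
  expect_gt(og$t95, og$t50)
  # P(t50) = 0.5 on the fitted curve by construction
  expect_equal(og$a + og$b * og$t50, 0)
  # lengths follow the growth curve
  expect_equal(og$l50, vbgf_length(g, og$t50))
  # probabilities above the extrapolated line clip to 1
  expect_true(all(og$prob$prob <= 1))
})

test_that("ogive ages always order t95 above t50 on simulated selective catches", {
  g <- vbgf_params(linf = 434, k = 0.43)
  set.seed(14)
  for (i in 1:5) {
    t50 <- runif(1, 0.3, 0.8)
    t95 <- t50 + runif(1, 0.1, 0.4)
    lf <- .expected_lfq(g, z = runif(1, 0.8, 2), sel_t50 = t50, sel_t95 = t95)
    cc <- try(catch_curve(lf, g), silent = TRUE)
    if (inherits(cc, "try-error")) next
    og <- try(catch_ogive(cc), silent = TRUE)
    if (inherits(og, "try-error")) next
    expect_gt(og$t95, og$t50)
  }
})

test_that("length-weight fit inverts exact allometric data", {
  L <- seq(80, 420, 20)
  w <- 2.60e-6 * L^3.26
  fit <- fit_length_weight(L, w)
  expect_equal(fit$a, 2.60e-6)
  expect_equal(fit$b, 3.26)
  expect_equal(fit$r2, 1)
  expect_equal(fit$n, length(L))
  # isometric growth
  fit3 <- fit_length_weight(L, L^3 * 1e-6)
  expect_equal(fit3$b, 3)
  expect_error(fit_length_weight(c(100, 200), c(10, 80)), "at least 3")
  expect_error(fit_length_weight(c(100, 200, 0), c(10, 80, 1)), "positive")
})
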