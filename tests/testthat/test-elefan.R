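# a small, fast fixture shared across the workflow tests
.elefan_fixture <- local({
  lf <- NULL
  function() {
    if (is.null(lf))
      lf <<- bin_lengths(simulate_length_frequencies(recovery_scenario()), 10)
    lf
  }
})

test_that("K-scan returns the grid maximum with ties to the smaller K", {
  lf <- .elefan_fixture()
  # single-element grid is returned as-is
  f1 <- elefan(lf, method = "kscan", linf = 434, k_grid = 0.5)
  expect_equal(unname(coef(f1)["k"]), 0.5)
  # tie rule: duplicated grid values share Rn; the first (smaller) wins
  f2 <- elefan(lf, method = "kscan", linf = 434, k_grid = c(0.5, 0.5 + 1e-12))
  expect_equal(unname(coef(f2)["k"]), 0.5)
  expect_error(elefan(lf, method = "kscan", linf = 434, k_grid = numeric(0)),
               "k_grid")
  expect_error(elefan(lf, method = "kscan", k_grid = 0.4), "linf")
})

test_that("K-scan recovers the growth coefficient at the true Linf", {
  lf <- .elefan_fixture()
  f <- elefan(lf, method = "kscan", linf = 434, k_grid = seq(0.2, 0.8, 0.01))
  expect_lt(abs(coef(f)["k"] - 0.43), 0.011)   # within one grid step
})

test_that("response surface analysis equals a naive double-loop oracle", {
  lf <- .elefan_fixture()
  linf_grid <- seq(380, 500, 30)
  k_grid <- seq(0.3, 0.6, 0.1)
  anchor_grid <- seq(0, 23 / 24, by = 1 / 24)
  f <- elefan(lf, method = "rsa", linf_grid = linf_grid, k_grid = k_grid)
  # oracle: literal nested loops over the same grid and anchor profile
  r <- restructure(lf, 5)
  best <- -Inf; best_linf <- NA; best_k <- NA
  surf <- matrix(NA_real_, length(linf_grid), length(k_grid))
  for (i in seq_along(linf_grid)) for (j in seq_along(k_grid)) {
    rn_ij <- -Inf
    for (a in anchor_grid) {
      s <- score_rn(r, vbgf_params(linf_grid[i], k_grid[j], t_anchor = a))
      if (s$rn > rn_ij) rn_ij <- s$rn
    }
    surf[i, j] <- rn_ij
    if (rn_ij > best) { best <- rn_ij; best_linf <- linf_grid[i]; best_k <- k_grid[j] }
  }
  expect_equal(unname(f$surface), surf)
  expect_equal(f$rn, best)
  expect_equal(unname(coef(f)[c("linf", "k")]), c(best_linf, best_k))
  # 1x1 grid returns that cell
  f11 <- elefan(lf, method = "rsa", linf_grid = 434, k_grid = 0.43)
  expect_equal(unname(coef(f11)[c("linf", "k")]), c(434, 0.43))
})

test_that("stochastic workflows are reproducible and beat/match enumeration", {
  lf <- .elefan_fixture()
  b <- list(linf = c(420, 450), k = c(0.38, 0.48))
  ctrl_sa <- list(n_temp = 25, n_prop = 10)
  f1 <- elefan(lf, method = "sa", bounds = b, seed = 3, control = ctrl_sa)
  f2 <- elefan(lf, method = "sa", bounds = b, seed = 3, control = ctrl_sa)
  expect_identical(coef(f1), coef(f2))
  ctrl_ga <- list(pop_size = 16, generations = 12)
  g1 <- elefan(lf, method = "ga", bounds = b, seed = 3, control = ctrl_ga)
  g2 <- elefan(lf, method = "ga", bounds = b, seed = 3, control = ctrl_ga)
  expect_identical(coef(g1), coef(g2))
  # collapsed bounds pin the search to a single point
  b0 <- list(linf = c(434, 434), k = c(0.43, 0.43))
  f0 <- elefan(lf, method = "sa", bounds = b0, seed = 1,
               control = list(n_temp = 2, n_prop = 2))
  expect_equal(unname(coef(f0)[c("linf", "k")]), c(434, 0.43))
  # on a small bounded space the SA/GA optimum is at least the best of a
  # discretized enumeration of the same space
  enum <- elefan(lf, method = "rsa", linf_grid = seq(420, 450, 10),
                 k_grid = seq(0.38, 0.48, 0.05))
  expect_gte(f1$rn + 1e-12, enum$rn)
  expect_gte(g1$rn + 1e-12, enum$rn)
  expect_error(elefan(lf, method = "sa", bounds = b, seed = NULL), "seed")
  expect_error(elefan(lf, method = "sa",
                      bounds = list(linf = c(450, 420), k = c(0.3, 0.5)),
                      seed = 1), "inverted")
})

test_that("the scenario sweep enumerates, ranks, and keeps metadata", {
  sc <- recovery_scenario()
  lens <- simulate_length_frequencies(sc)
  sw <- elefan_sweep(lens, bins = c(10, 20), mas = c(5, 7),
                     workflows = c("kscan", "rsa"), seed = 1,
                     bounds = recovery_bounds,
                     linf = 434, k_grid = seq(0.3, 0.6, 0.05),
                     linf_grid = seq(400, 480, 20))
  expect_equal(nrow(sw$table), 2 * 2 * 2)
  expect_true(all(diff(sw$table$rn) <= 0))       # ranked by Rn
  expect_equal(sw$best$rn, sw$table$rn[1])
  expect_setequal(unique(sw$table$bin), c(10, 20))
})
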