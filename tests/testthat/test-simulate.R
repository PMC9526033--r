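test_that("length simulation conserves counts and is seed-deterministic", {
  sc <- population_scenario(n_per_sample = 500,
                            sample_dates = c("2019-01-10", "2019-04-10",
                                             "2019-07-10", "2019-10-10"),
                            seed = 5)
  lens <- simulate_length_frequencies(sc)
  expect_length(lens, 4)
  expect_equal(unname(vapply(lens, length, integer(1))), rep(500L, 4))
  expect_equal(sum(lengths(lens)), 2000L)
  lens2 <- simulate_length_frequencies(sc)
  expect_identical(lens, lens2)
  # binning a simulated sample conserves the number of retained fish
  lf <- bin_lengths(lens, 10)
  expect_equal(unname(colSums(lf$counts)), rep(500L, 4))
})

test_that("with no variation and full selection every length sits on the growth curve", {
  sc <- population_scenario(linf = 434, k = 0.43, c_amp = 0.4, ts = 0.3,
                            z = 1.2, cv_length = 0, sel_l50 = 0,
                            recruit_pulses = 1, t_anchor = 0,
                            n_per_sample = 200,
                            sample_dates = c("2019-03-10", "2019-09-10"),
                            seed = 9)
  lens <- simulate_length_frequencies(sc)
  g <- vbgf_params(linf = 434, k = 0.43, c_amp = 0.4, ts = 0.3)
  for (d in names(lens)) {
    dt <- decimal_year(d)
    # cohort ages at this date: birthdays at integer years
    births <- seq(floor(dt) - 25, floor(dt))
    ages <- dt - births
    ok <- ages > 0
    expected <- sort(unique(round(
      vbgf_length(g, ages[ok], birth = births[ok]), 9)))
    observed <- sort(unique(round(lens[[d]], 9)))
    expect_true(all(observed %in% expected), info = d)
  }
})

test_that("invalid population scenarios are rejected", {
  expect_error(population_scenario(linf = Inf), "non-finite")
  expect_error(population_scenario(z = -1), "positive")
  expect_error(population_scenario(sel_l50 = 60, sel_l95 = 50), "sel_l95")
  expect_error(population_scenario(recruit_pulses = 3), "recruit_pulses")
})

test_that("environment grid has the right geometry and stored truth", {
  hs <- zero_noise_habitat()
  g <- simulate_environment_and_catch(hs)
  expect_equal(nrow(g$cells), 12 * 8)     # 6 x 4 degrees at 0.5
  expect_equal(nrow(g$catch), 96 * length(hs$years))
  # zero catch noise: catch exactly proportional to stored true HSI
  expect_equal(g$catch$catch_t, hs$q_catch * g$catch$true_hsi)
  # determinism
  g2 <- simulate_environment_and_catch(hs)
  expect_identical(g$catch, g2$catch)
  expect_error(
    simulate_environment_and_catch(habitat_scenario(years = integer(0))),
    "years")
})

test_that("winter-mean SST trend equals the generating slope exactly", {
  hs <- habitat_scenario(years = 1971:2019, sst_trend_per_yr = -0.028,
                         seed = 11)
  g <- simulate_environment_and_catch(hs)
  s <- winter_sst_series(g)
  tr <- winter_sst_trend(s$year, s$sst)
  # per-cell offsets are fixed across years, so OLS recovers the drift
  expect_equal(tr$slope, -0.028, tolerance = 1e-6)
})
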