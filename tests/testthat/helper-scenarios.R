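# Shared fixtures and independent oracles for the test suite.

# Quarterly two-year survey of a moderately exploited population: the
# parameter-recovery conditions (all age classes present, sub-bin
# individual length variation).
recovery_scenario <- function(seed = 42) {
  population_scenario(
    linf = 434, k = 0.43, z = 0.5, cv_length = 0.02, sel_l50 = 0,
    t_anchor = 0, n_per_sample = 500,
    sample_dates = c("2018-01-15", "2018-04-15", "2018-07-15", "2018-10-15",
                     "2019-01-15", "2019-04-15", "2019-07-15", "2019-10-15"),
    seed = seed)
}

recovery_bounds <- list(linf = c(350, 520), k = c(0.25, 0.7))

# Noise-free habitat world whose true HSI is the arithmetic mean of the
# depth and SST Gaussian suitability curves.
zero_noise_habitat <- function(seed = 3) {
  habitat_scenario(catch_noise_cv = 0, depth_noise_sd = 0,
                   sst_noise_sd = 0, sss_noise_sd = 0,
                   sst_trend_per_yr = 0, seed = seed)
}

# Independent step-by-step transcription of the ELEFAN-I restructuring
# sequence (plain loops; no shared code with stockhab::restructure).
oracle_restructure <- function(counts, ma) {
  out <- counts * 0
  for (j in seq_len(ncol(counts))) {
    n <- counts[, j]
    nb <- length(n)
    if (all(n == 0)) next
    h <- (ma - 1) / 2
    score <- numeric(nb)
    for (i in seq_len(nb)) {
      wlo <- max(1, i - h); whi <- min(nb, i + h)
      mav <- sum(n[wlo:whi]) / (whi - wlo + 1)
      score[i] <- if (mav > 0) n[i] / mav - 1 else 0
    }
    possum <- 0; poscnt <- 0
    for (i in seq_len(nb)) if (score[i] > 0) {
      possum <- possum + score[i]; poscnt <- poscnt + 1
    }
    if (poscnt > 0) {
      posmean <- possum / poscnt
      for (i in seq_len(nb)) if (score[i] > 0) score[i] <- score[i] / posmean
    }
    run <- 0
    for (i in seq_len(nb)) {
      if (n[i] == 0) {
        run <- run + 1
        score[i] <- score[i] - 0.01 * run
      } else run <- 0
    }
    for (i in seq_len(nb)) {
      if (score[i] > 0) {
        nz <- 0
        if (i > 1 && n[i - 1] == 0) nz <- nz + 1
        if (i < nb && n[i + 1] == 0) nz <- nz + 1
        score[i] <- score[i] / 2^nz
      }
    }
    out[, j] <- score
  }
  out
}

# random small length-frequency objects for property tests
random_lfq <- function(nbin, nsamp, max_count = 30) {
  counts <- matrix(rpois(nbin * nsamp, 3) *
                     rbinom(nbin * nsamp, 1, 0.7), nbin, nsamp)
  lfq(seq(100, by = 10, length.out = nbin),
      2018 + seq(0.1, 0.9, length.out = nsamp), counts)
}
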