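test_that("binning uses half-open bins spanning the data", {
  lf <- bin_lengths(list(`2019-01-20` = c(131, 139, 145)), bin_mm = 10)
  expect_equal(lf$bin_lower, c(130, 140))
  expect_equal(as.vector(lf$counts), c(2, 1))
  # a length exactly on an edge belongs to the upper bin
  lf2 <- bin_lengths(list(`2019-01-20` = c(131, 140)), bin_mm = 10)
  expect_equal(as.vector(lf2$counts), c(1, 1))
  expect_error(bin_lengths(list(), 10), "non-empty")
})

test_that("uniform and all-zero columns restructure to zero", {
  lf <- lfq(seq(100, 140, 10), c(2019.1, 2019.5),
            cbind(rep(5, 5), rep(0, 5)))
  r <- restructure(lf, ma_window = 5)
  expect_equal(unname(r$values), matrix(0, 5, 2))
})

test_that("restructuring matches the independent ELEFAN-I transcription", {
  # the worked single-spike column
  lf <- lfq(seq(100, 140, 10), 2019.1, matrix(c(0, 0, 10, 0, 0), ncol = 1))
  r <- restructure(lf, 5)
  expect_equal(unname(r$values), oracle_restructure(lf$counts, 5))
  # random small matrices, all MA windows
  set.seed(71)
  for (i in 1:25) {
    nbin <- sample(5:10, 1)
    nsamp <- sample(1:4, 1)
    lf <- random_lfq(nbin, nsamp)
    for (ma in c(3, 5)[c(3, 5) <= nbin]) {
      expect_equal(unname(restructure(lf, ma)$values),
                   unname(oracle_restructure(lf$counts, ma)),
                   info = sprintf("case %d ma %d", i, ma))
    }
  }
})

test_that("restructured scores are invariant to rescaling a column's counts", {
  set.seed(12)
  lf <- random_lfq(8, 3)
  r1 <- restructure(lf, 5)
  lf2 <- lfq(lf$bin_lower, lf$dates, lf$counts * 7L)
  r2 <- restructure(lf2, 5)
  expect_equal(r1$values, r2$values)
})

test_that("window validation is enforced", {
  lf <- random_lfq(6, 2)
  expect_error(restructure(lf, 4), "odd")
  expect_error(restructure(lf, 7), "larger")
})
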