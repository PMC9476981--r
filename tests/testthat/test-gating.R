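test_that("histogram binning conserves events and respects the log scale", {
  # all-equal events end up in a single nonzero bin
  h <- build_histogram(rep(150, 42), n_bins = 64)
  expect_equal(sum(h$counts), 42)
  expect_equal(sum(h$counts > 0), 1)

  # log bins are uniform in log(intensity)
  h <- build_histogram(c(10, 1000, runif(100, 10, 1000)), n_bins = 32)
  expect_equal(diff(log(h$bin_edges)),
               rep(diff(log(h$bin_edges))[1], 32), tolerance = 1e-6)

  # a Gaussian's modal bin sits at the mean (to within bin noise)
  set.seed(11)
  x <- rnorm(10000, 200, 6)
  h <- build_histogram(x, n_bins = 256)
  expect_lt(abs(h$mids[which.max(h$counts)] - 200) / 200, 0.01)

  # 50/50 mixture at a doubling shows two local maxima near both means
  set.seed(12)
  x <- c(rnorm(5000, 200, 6), rnorm(5000, 400, 12))
  pk <- detect_peaks(build_histogram(x, n_bins = 256))
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$position[1] - 200) / 200, 0.02)
  expect_lt(abs(pk$position[2] - 400) / 400, 0.02)

  # floor truncation excludes and reports
  h <- build_histogram(c(1, 2, 100, 200), floor = 50, n_bins = 16)
  expect_equal(h$n_excluded, 2)
  expect_equal(sum(h$counts), 2)

  expect_error(build_histogram(c(-1, 10), n_bins = 16), "positive")
  expect_error(build_histogram(1:100, n_bins = 8), "n_bins")
})

test_that("peak detection finds single and double Gaussians, rejects flat", {
  set.seed(21)
  x <- rnorm(10000, 200, 0.03 * 200)
  pk <- detect_peaks(build_histogram(x, n_bins = 256))
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$position - 200) / 200, 0.02)
  expect_lt(abs(pk$cv_percent - 3), 1)

  set.seed(22)
  x <- c(rnorm(5000, 300, 9), rnorm(5000, 600, 18))
  pk <- detect_peaks(build_histogram(x, n_bins = 256))
  expect_equal(nrow(pk), 2)
  expect_gt(pk$position[2] / pk$position[1], 1.9)
  expect_lt(pk$position[2] / pk$position[1], 2.1)

  # flat histogram: no local maximum with prominence
  h <- build_histogram(runif(50, 10, 20), n_bins = 16)
  h$counts <- rep(5L, length(h$counts))
  expect_error(detect_peaks(h), "no peak")
})

test_that("doubling-series assignment anchors 2C and flags outliers", {
  mk <- function(pos, height = rev(seq_along(pos))) {
    structure(data.frame(position = pos, height = height,
                         cv_percent = 3, c_level = NA_real_),
              class = c("peak_set", "data.frame"))
  }
  expect_equal(assign_doubling_series(mk(c(100, 200, 400)))$c_level,
               c(2, 4, 8))
  expect_equal(assign_doubling_series(mk(c(100, 205, 395)))$c_level,
               c(2, 4, 8))
  out <- assign_doubling_series(mk(c(100, 150)))$c_level
  expect_equal(out, c(2, NA))
  # single peak is anchored as 2C
  expect_equal(assign_doubling_series(mk(100))$c_level, 2)
  # sub-2C debris peak: chain consistency beats position
  out <- assign_doubling_series(mk(c(50, 120, 240, 480),
                                   height = c(40, 100, 60, 20)))$c_level
  expect_equal(out, c(NA, 2, 4, 8))
})

test_that("gating assigns gated events exactly and conserves totals", {
  pk <- structure(data.frame(position = c(100, 200, 400), height = 10,
                             cv_percent = 3, c_level = c(2, 4, 8)),
                  class = c("peak_set", "data.frame"))
  # events exactly at the peak positions go to their own class
  v <- c(rep(100, 5), rep(200, 3), rep(400, 2))
  pc <- gate_events(v, pk)
  expect_equal(unname(pc$counts), c(5, 3, 2))
  # outside events are counted as debris, never silently lost
  v2 <- c(v, 10, 10, 5000)
  pc2 <- gate_events(v2, pk)
  expect_equal(pc2$debris_low, 2L)
  expect_equal(pc2$debris_high, 1L)
  expect_equal(pc2$total + pc2$debris_low + pc2$debris_high, length(v2))
})

test_that("gating equals the nearest-log-peak oracle inside the boundaries", {
  set.seed(31)
  for (i in 1:100) {
    n_cls <- sample(2:4, 1)
    anchor <- runif(1, 50, 400)
    pos <- anchor * 2^(0:(n_cls - 1))
    pk <- structure(data.frame(position = pos, height = 10, cv_percent = 3,
                               c_level = 2 * 2^(0:(n_cls - 1))),
                    class = c("peak_set", "data.frame"))
    # events strictly inside the outer boundaries
    v <- exp(runif(80, log(anchor * 2^(-0.49)),
                   log(pos[n_cls] * 2^(0.49))))
    pc <- gate_events(v, pk)
    oracle <- nearest_peak_oracle(v, pos, pk$c_level)
    expect_equal(pc$counts[names(oracle)], oracle)
  }
})

test_that("ploidy counts are invariant under intensity rescaling", {
  set.seed(41)
  s <- simulate_events(c(0.5, 0.35, 0.15), n = 4000, debris_fraction = 0.02)
  f1 <- fit_ploidy(s)
  for (c_mult in c(0.25, 3.7, 40)) {
    f2 <- fit_ploidy(s$intensities * c_mult)
    expect_equal(f2$counts$counts, f1$counts$counts)
    expect_equal(f2$counts$debris_low, f1$counts$debris_low)
  }
})

test_that("fit_ploidy recovers simulated class proportions", {
  # conservation + recovery over seeded simulations from published rows
  tab <- pulmonaria_class_proportions()
  set.seed(51)
  rows <- tab[sample(nrow(tab), 10), ]
  errs <- c()
  for (i in seq_len(nrow(rows))) {
    p <- as.numeric(rows[i, CLASS_COLS]) / 100
    for (rep_i in 1:5) {
      s <- simulate_events(p, n = 5000, cv_percent = 3.5)
      f <- fit_ploidy(s)
      expect_equal(f$counts$total + f$counts$debris_low +
                     f$counts$debris_high, length(s$intensities))
      got <- rep(0, 6)
      got[seq_along(f$counts$counts)] <- f$counts$counts / f$counts$total
      errs <- c(errs, abs(got - p / sum(p)))
    }
  }
  expect_lt(mean(errs), 0.01)   # mean absolute error under 1 percentage point
  expect_lt(max(errs), 0.05)
})

test_that("QC thresholds match measurement-protocol rules", {
  pk <- structure(data.frame(position = c(100, 200), height = 10,
                             cv_percent = c(4.9, 4.2), c_level = c(2, 4)),
                  class = c("peak_set", "data.frame"))
  expect_true(qc_check(5000, mode = "genome_size", peaks = pk)$pass)
  expect_false(qc_check(2999, mode = "endopolyploidy")$pass)
  expect_true(qc_check(3000, mode = "endopolyploidy")$pass)
  expect_false(qc_check(4999, mode = "genome_size")$pass)
  pk$cv_percent <- c(5.1, 3.0)
  bad <- qc_check(6000, mode = "genome_size", peaks = pk)
  expect_false(bad$pass)
  expect_match(bad$violations, "CV", all = FALSE)
})

test_that("ploidy_fit methods are coherent", {
  set.seed(61)
  s <- simulate_events(c(0.6, 0.3, 0.1), n = 5000)
  f <- fit_ploidy(s)
  co <- coef(f)
  expect_named(co, c("2C", "4C", "8C"))
  expect_equal(unname(co[2] / co[1]), 2, tolerance = 0.05)
  # predict classifies the peak positions themselves correctly
  pr <- predict(f, newdata = co)
  expect_equal(as.character(pr), c("2C", "4C", "8C"))
  expect_equal(as.character(predict(f, newdata = 1e6)), "debris")
  # fitted mixture accounts for most gated events
  expect_gt(sum(fitted(f)), 0.9 * f$counts$total)
  expect_equal(length(residuals(f)), length(f$histogram$counts))
  # simulate() round-trips the fitted proportions
  s2 <- simulate(f, seed = 1)
  f2 <- fit_ploidy(s2)
  expect_equal(f2$counts$counts / f2$counts$total,
               f$counts$counts / f$counts$total, tolerance = 0.05)
  sm <- summary(f)
  expect_s3_class(sm$profile, "endopoly_profile")
})
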