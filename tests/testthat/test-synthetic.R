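test_that("degenerate and deterministic ISI models behave as defined", {
  expect_equal(simulate_isi("white", 4, mean_s = 1.0, sd_s = 0, seed = 7)$values,
               rep(1.0, 4))
  expect_equal(simulate_isi("periodic", 6, pattern = c(1.1, 1.2))$values,
               c(1.1, 1.2, 1.1, 1.2, 1.1, 1.2))
  expect_equal(simulate_isi("periodic", 3, pattern = c(1.1, 1.2))$values,
               c(1.1, 1.2, 1.1))
})

test_that("fGn stride times reproduce the theoretical lag-1 autocorrelation", {
  # theoretical lag-1 autocorrelation of unit fGn: 2^(2H-1) - 1
  h <- 0.9
  rho1 <- 2^(2 * h - 1) - 1
  r1 <- vapply(1:20, function(s) {
    isi <- simulate_isi("fgn", 1000, mean_s = 1.12, sd_s = 0.04,
                        hurst = h, seed = s)
    lag1_autocorr(isi$values, 1.12)
  }, numeric(1))
  expect_lt(abs(mean(r1) - rho1), 0.05)
  # H = 0.5 is white noise: near-zero lag-1 correlation at n = 10000
  isi5 <- simulate_isi("fgn", 10000, hurst = 0.5, seed = 1)
  expect_gt(lag1_autocorr(isi5$values, 1.12), -0.05)
  expect_lt(lag1_autocorr(isi5$values, 1.12), 0.05)
  isi9 <- simulate_isi("fgn", 10000, hurst = 0.9, seed = 1)
  expect_gt(lag1_autocorr(isi9$values, 1.12), 0.65)
})

test_that("ISI generator validates parameters and reports clipping", {
  expect_error(simulate_isi("white", 0), "positive")
  expect_error(simulate_isi("fgn", 10, hurst = 1.3), "hurst")
  expect_error(simulate_isi("fgn", 10, hurst = 0), "hurst")
  expect_error(simulate_isi("white", 100, mean_s = 1.12, sd_s = 0.4), "clip")
})

test_that("ISI sample mean stays near the requested mean", {
  for (s in 1:10) {
    # the sample mean of persistent fGn has SD sd_s * n^(H - 1), wider
    # than the i.i.d. sd_s / sqrt(n)
    isi <- simulate_isi("fgn", 400, mean_s = 1.12, sd_s = 0.04,
                        hurst = 0.85, seed = s)
    expect_lt(abs(mean(isi$values) - 1.12), 5 * 0.04 * 400^(0.85 - 1))
    w <- simulate_isi("white", 400, mean_s = 1.0, sd_s = 0.05, seed = s)
    expect_lt(abs(mean(w$values) - 1.0), 5 * 0.05 / sqrt(400))
  }
})

test_that("same seed gives identical series, different seeds differ", {
  a <- simulate_isi("fgn", 200, hurst = 0.8, seed = 3)$values
  b <- simulate_isi("fgn", 200, hurst = 0.8, seed = 3)$values
  d <- simulate_isi("fgn", 200, hurst = 0.8, seed = 4)$values
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("synthetic recordings carry exact ground truth", {
  rec <- simulate_recording(list(rep(1.1, 30), rep(1.0, 26)), gap_s = 5,
                            seed = 2)
  expect_equal(nrow(rec$true_bout_spans), 2)
  # contacts within a bout differ by the stride times exactly
  first <- rec$true_rhc_times[1:31]
  expect_equal(diff(first), rep(1.1, 30))
  # duration equals strides plus gaps plus the quiet padding
  dur <- diff(range(rec$accel$t))
  expected <- 2 * 2 + 30 * 1.1 + 5 + 26 * 1.0
  expect_lt(abs(dur - expected), 1 / 100 + 4 * 0.001)
  expect_error(simulate_recording(list(rep(1.1, 5), rep(1, 5)), gap_s = 1.5),
               "1.8")
})

test_that("the waveform has a local minimum at every true contact", {
  rec <- simulate_recording(list(rep(1.15, 20)), timestamp_jitter_sd = 0,
                            gravity = 0, invert = FALSE, noise_sd = 0,
                            seed = 1)
  a <- rec$accel$az
  t <- rec$accel$t
  for (ct in rec$true_rhc_times) {
    i <- which.min(abs(t - ct))
    expect_lte(a[i], a[i - 1])
    expect_lte(a[i], a[i + 1])
  }
})

test_that("recording generation is reproducible and seed-sensitive", {
  r1 <- simulate_recording(list(rep(1.1, 25)), noise_sd = 0.2, seed = 9)
  r2 <- simulate_recording(list(rep(1.1, 25)), noise_sd = 0.2, seed = 9)
  r3 <- simulate_recording(list(rep(1.1, 25)), noise_sd = 0.2, seed = 10)
  expect_identical(r1$accel$az, r2$accel$az)
  expect_false(identical(r1$accel$az, r3$accel$az))
})

test_that("recordings round-trip through CSV with ground-truth sidecars", {
  rec <- simulate_recording(list(rep(1.05, 26)), seed = 4)
  path <- file.path(tempdir(), "rec_roundtrip.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$t, rec$accel$t)
  expect_equal(back$az, rec$accel$az)
  expect_true(file.exists(file.path(tempdir(), "rec_roundtrip_events.csv")))
  truth <- jsonlite::read_json(file.path(tempdir(), "rec_roundtrip_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$bout_spans), 1)
  unlink(file.path(tempdir(), c("rec_roundtrip.csv", "rec_roundtrip_events.csv",
                                "rec_roundtrip_truth.json")))
})
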