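test_that("the drift high-pass removes offsets and keeps gait frequencies", {
  fs <- 100
  t <- seq(0, 120, by = 1 / fs)
  const <- signal_from_values(rep(5, length(t)))
  out <- drift_highpass(const)
  expect_lt(max(abs(tail(out$a, 1000))), 1e-3)
  s2 <- signal_from_values(sin(2 * pi * 2 * t))
  expect_gt(max(abs(tail(drift_highpass(s2)$a, 2000))), 0.99)
  slow <- signal_from_values(sin(2 * pi * 0.01 * t))
  expect_lt(max(abs(tail(drift_highpass(slow)$a, 2000))), 0.1)
})

test_that("velocity integration follows the trapezoid rule", {
  sig <- signal_from_values(c(0, 2, 4), fs = 100)
  expect_equal(integrate_velocity(sig)$a, c(0, 0.01, 0.04))
  # constant acceleration integrates to a ramp with matching slope
  const <- signal_from_values(rep(3, 200), fs = 100)
  v <- integrate_velocity(const)$a
  expect_equal(diff(v), rep(0.03, 199))
  # sinusoid integrates to its antiderivative within O(h^2)
  f <- 1
  t <- seq(0, 5, by = 0.01)
  v2 <- integrate_velocity(signal_from_values(sin(2 * pi * f * t)))$a
  expected <- (-cos(2 * pi * f * t) + 1) / (2 * pi * f)
  expect_lt(max(abs(v2 - expected)), 1e-3)
})

test_that("the wavelet trace is a smoothed differentiator", {
  # derivative of a ramp is constant (away from the padded edges)
  t <- seq(0, 10, by = 0.01)
  ramp <- signal_from_values(0.7 * t)
  tr <- cwt_differentiate(ramp)
  mid <- tr$c[200:800]
  expect_lt(max(abs(mid - 0.7)), 2e-3)  # truncated-kernel normalization
  const <- signal_from_values(rep(2, length(t)))
  expect_lt(max(abs(cwt_differentiate(const)$c)), 1e-9)
  expect_error(cwt_differentiate(signal_from_values(rnorm(50))), "support")
})

test_that("candidate thresholding follows the 40%-of-median rule", {
  # helper: a flat trace with unit-width dips of given depths
  dip_trace <- function(depths, spacing_s = 1.2, fs = 100) {
    n <- round((length(depths) + 1) * spacing_s * fs)
    x <- numeric(n)
    pos <- round(seq_len(length(depths)) * spacing_s * fs)
    x[pos] <- depths
    list(trace = trace_from_values(x, fs), pos = pos)
  }
  # 10 equal minima of -1: threshold 0.4 * median = -0.4; all retained
  d <- dip_trace(rep(-1, 10))
  expect_equal(find_candidate_minima(d$trace), d$pos)
  # weak minima of -0.3 rejected against threshold -0.4
  d2 <- dip_trace(c(rep(-1, 10), rep(-0.3, 5)))
  expect_equal(find_candidate_minima(d2$trace), d2$pos[1:10])
  expect_error(find_candidate_minima(trace_from_values(numeric(100))),
               "fewer than 10")
})

test_that("conflicting close minima keep the deeper one", {
  fs <- 100
  x <- numeric(20 * fs)
  deep <- round(seq(1, 10) * 1.2 * fs)
  x[deep] <- -1
  x[round(14 * fs)] <- -1.0
  x[round(14.5 * fs)] <- -0.8   # 0.5 s from the -1.0 dip: conflict
  got <- find_candidate_minima(trace_from_values(x, fs))
  expect_true(round(14 * fs) %in% got)
  expect_false(round(14.5 * fs) %in% got)
})

test_that("chaining walks minimum -> maximum -> acceleration minimum", {
  # two candidates that chain to the same acceleration minimum emit one event
  fs <- 100
  n <- 600
  tr <- numeric(n); acc <- numeric(n)
  tr[100] <- -1; tr[150] <- -0.9; tr[200] <- 1   # both candidates before max
  acc[300] <- -1                                 # single acceleration minimum
  ev <- chain_to_heel_contacts(signal_from_values(acc), trace_from_values(tr),
                               c(100L, 150L))
  expect_equal(ev$indices, 300L)
  # a candidate with no chainable structure before the end is dropped
  tr2 <- numeric(n); tr2[590] <- -1
  expect_warning(
    ev2 <- chain_to_heel_contacts(signal_from_values(numeric(n)),
                                  trace_from_values(tr2), 590L),
    "dropped")
  expect_length(ev2$indices, 0)
})

test_that("raw relocation finds the shifted minimum", {
  fs <- 100
  filt <- numeric(400); raw <- numeric(400)
  filt[200] <- -1
  raw[202] <- -1    # raw minimum sits 2 frames after the filtered one
  ev_f <- gaitcx:::new_heel_contacts(200L, fs = fs, t0 = 0, stream = "filtered")
  ev_r <- relocate_in_raw(ev_f, signal_from_values(raw, stream = "raw"))
  expect_equal(ev_r$indices, 202L)
  # identical streams give identical indices
  ev_same <- relocate_in_raw(ev_f, signal_from_values(filt, stream = "raw"))
  expect_equal(ev_same$indices, 200L)
})

test_that("clean synthetic recordings are detected perfectly", {
  rec <- simulate_recording(list(rep(1.0, 30)), seed = 1)
  ev <- detect_heel_contacts(preprocess_recording(rec$accel))
  truth <- rec$true_rhc_times
  sc <- score_events(ev$raw$times, truth)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  # event count preserved through relocation
  expect_equal(length(ev$raw$indices), length(ev$filtered$indices))
  # emitted series satisfies the physiological spacing rule
  expect_true(all(diff(ev$raw$times) > 0.8))
  expect_true(all(diff(ev$filtered$times) > 0.8))
})

test_that("detection is invariant to positive rescaling of the signal", {
  rec <- simulate_recording(list(rep(1.1, 28)), seed = 6)
  streams <- preprocess_recording(rec$accel)
  ev1 <- detect_heel_contacts(streams)
  scaled <- streams
  scaled$raw$a <- scaled$raw$a * 3.7
  scaled$filtered$a <- scaled$filtered$a * 3.7
  ev2 <- detect_heel_contacts(scaled)
  expect_equal(ev1$raw$indices, ev2$raw$indices)
})
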