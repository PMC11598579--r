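test_that("reshaping deals the series into s piles", {
  expect_equal(reshape_series(c(1.13, 1.15, 1.17, 1.20, 1.22), 2),
               c(1.13, 1.17, 1.22, 1.15, 1.20))
  x <- rnorm(17)
  expect_identical(reshape_series(x, 1), x)
  expect_equal(reshape_series(1:7, 3), c(1, 4, 7, 2, 5, 3, 6))
  expect_error(reshape_series(x, 0), "s must")
  expect_error(reshape_series(x, 18), "s must")
})

test_that("every reshaping is a permutation of the original values", {
  x <- simulate_isi("fgn", 800, hurst = 0.9, seed = 1)$values
  for (s in c(2, 3, 7, 50, 99, 100, 800)) {
    y <- reshape_series(x, s)
    expect_equal(sort(y), sort(x))
    # a genuine reordering for 1 < s < n (s = n deals into n piles of one,
    # which is the identity again)
    if (s > 1 && s < length(x)) expect_false(identical(y, x))
  }
})

test_that("surrogate statistics satisfy the critical-limit construction", {
  x <- simulate_isi("fgn", 400, hurst = 0.9, seed = 2)$values
  surr <- random_surrogates(x, n_surrogates = 30, seed = 7,
                            compute_saen = FALSE)
  expect_equal(surr$critical_limit,
               surr$fsi_rand_mean + 2 * surr$fsi_rand_sd)
  # permutation destroys no structure in white noise: surrogate FSI ~ 0.5
  w <- simulate_isi("white", 400, seed = 3)$values
  sw <- random_surrogates(w, n_surrogates = 30, seed = 8,
                          compute_saen = FALSE)
  expect_gt(sw$fsi_rand_mean, 0.4); expect_lt(sw$fsi_rand_mean, 0.6)
  # reproducible given the seed
  surr2 <- random_surrogates(x, n_surrogates = 30, seed = 7,
                             compute_saen = FALSE)
  expect_identical(surr$fsi_rand_mean, surr2$fsi_rand_mean)
  expect_error(random_surrogates(x[1:100]), "256")
})

test_that("the normalized sample entropy follows its definition", {
  expect_equal(normalized_saen(1.8, 1.5, 2.0), 0.6)
  expect_equal(normalized_saen(1.5, 1.5, 2.0), 0)
  expect_equal(normalized_saen(2.0, 1.5, 2.0), 1)
  expect_error(normalized_saen(1.8, 1.5, 1.5), "undefined")
})

test_that("persistence decay starts at the original FSI and censors cleanly", {
  x <- simulate_isi("fgn", 800, hurst = 0.9, seed = 4)$values
  surr <- random_surrogates(x, n_surrogates = 30, seed = 5,
                            compute_saen = FALSE)
  v <- spd(x, surr, max_s = 20)
  curve <- attr(v, "alpha_by_s")
  expect_equal(curve[1], dfa(x)$alpha)
  # an unreachable critical limit censors at max_s with the flag set
  low <- structure(list(fsi_rand_mean = 0, fsi_rand_sd = 0,
                        critical_limit = -Inf, saen_rand_mean = NA_real_,
                        n_surrogates = 0, seed = NULL),
                   class = "surrogate_stats")
  vc <- spd(x, low, max_s = 15)
  expect_equal(as.integer(vc), 15L)
  expect_true(attr(vc, "censored"))
  # the crossing is strict: a limit equal to the curve value never crosses
  at_alpha1 <- structure(list(fsi_rand_mean = curve[1], fsi_rand_sd = 0,
                              critical_limit = curve[1],
                              saen_rand_mean = NA_real_,
                              n_surrogates = 0, seed = NULL),
                         class = "surrogate_stats")
  v1 <- spd(x, at_alpha1, max_s = 5)
  expect_gt(as.integer(v1), 1)
})

test_that("white noise decays immediately: SPD of 1 in most replicates", {
  hits <- 0
  for (s in 1:10) {
    x <- simulate_isi("white", 800, seed = 400 + s)$values
    surr <- random_surrogates(x, n_surrogates = 40, seed = 500 + s,
                              compute_saen = FALSE)
    if (as.integer(spd(x, surr, max_s = 10)) == 1L) hits <- hits + 1
  }
  expect_gte(hits, 6)
})

test_that("entropic half-life normalization is zero at separation one", {
  x <- simulate_isi("fgn", 800, hurst = 0.95, seed = 6)$values
  surr <- random_surrogates(x, n_surrogates = 30, seed = 9)
  v <- enhl(x, surr, max_s = 12)
  curve <- attr(v, "norm_saen_by_s")
  expect_equal(curve[1], 0)
  expect_true(as.integer(v) >= 1 && as.integer(v) <= 12)
  # deterministic given the surrogate seed
  v2 <- enhl(x, surr, max_s = 12)
  expect_identical(as.integer(v), as.integer(v2))
})

test_that("the literal crossing convention censors monotone curves", {
  x <- simulate_isi("fgn", 800, hurst = 0.95, seed = 6)$values
  surr <- random_surrogates(x, n_surrogates = 30, seed = 9)
  v_loss <- enhl(x, surr, max_s = 15, direction = "loss")
  v_lit <- enhl(x, surr, max_s = 15, direction = "literal")
  curve <- attr(v_lit, "norm_saen_by_s")
  above <- which(curve > 0.5)
  if (length(above) == 0 || all(curve[seq(min(above), 15)] >= 0.5)) {
    expect_true(attr(v_lit, "censored"))
  } else {
    expect_gt(as.integer(v_lit), as.integer(v_loss))
  }
})
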