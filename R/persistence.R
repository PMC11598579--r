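# Statistical persistence decay (SPD) and entropic half-life (EnHL):
# progressive reshaping of the stride-time series against permutation
# surrogates.

#' Reshape a series by stride-order separation
#'
#' Deal-into-piles reordering: for separation `s`, the output concatenates
#' the elements at positions `o, o + s, o + 2s, ...` for each offset
#' `o = 1..s`. Separation 1 is the identity; larger separations place
#' originally distant strides next to each other, progressively
#' randomizing the short-range ordering while leaving the value multiset
#' unchanged. For example, `c(1.13, 1.15, 1.17, 1.20, 1.22)` at `s = 2`
#' becomes `c(1.13, 1.17, 1.22, 1.15, 1.20)`.
#'
#' @param isi Numeric series.
#' @param s Stride-order separation, `1 <= s <= length(isi)`.
#' @return The reshaped series (a permutation of the input).
#' @export
reshape_series <- function(isi, s) {
  x <- as.numeric(isi)
  n <- length(x)
  if (s < 1 || s > n) stop("s must lie in [1, length(isi)]")
  s <- as.integer(s)
  if (s == 1L) return(x)
  idx <- unlist(lapply(seq_len(s), function(o) seq.int(o, n, by = s)))
  x[idx]
}

#' Permutation surrogates and the critical limit
#'
#' Generates `n_surrogates` independent uniform random permutations of the
#' series, computes the DFA scaling index of each, and forms the critical
#' limit `mean + 2 * SD` of the surrogate indices -- the level below which
#' a scaling index is statistically indistinguishable from temporally
#' uncorrelated stride times. The sample entropy of each surrogate is also
#' averaged (used by the entropic half-life normalization).
#'
#' @param isi Numeric stride-time series (at least 256 strides, the DFA
#'   eligibility rule).
#' @param n_surrogates Number of random permutations (default 100).
#' @param seed Integer seed for the permutation stream.
#' @param box_min,box_max DFA box-size range.
#' @param m,r_fraction Entropy parameters; the radius is
#'   `r_fraction * sd(isi)` (permutation leaves the SD unchanged).
#' @param compute_saen Set `FALSE` to skip the surrogate entropies when
#'   only the critical limit is needed.
#'
#' @return An object of class `surrogate_stats`: list with
#'   `fsi_rand_mean`, `fsi_rand_sd`, `critical_limit`, `saen_rand_mean`
#'   (or `NA`), `n_surrogates`, `seed`.
#' @export
random_surrogates <- function(isi, n_surrogates = 100, seed = NULL,
                              box_min = 10, box_max = 40, m = 2,
                              r_fraction = 0.15, compute_saen = TRUE) {
  x <- as.numeric(isi)
  if (length(x) < 256)
    stop("series shorter than 256 strides; DFA eligibility unmet")
  if (sd(x) == 0) stop("series has zero variance")
  r <- r_fraction * sd(x)
  res <- with_seed(seed, {
    alphas <- numeric(n_surrogates)
    saens <- rep(NA_real_, n_surrogates)
    for (i in seq_len(n_surrogates)) {
      xs <- x[sample.int(length(x))]
      alphas[i] <- dfa(xs, box_min, box_max)$alpha
      if (compute_saen) saens[i] <- saen(xs, m = m, r = r)
    }
    list(alphas = alphas, saens = saens)
  })
  mu <- mean(res$alphas)
  sdev <- sd(res$alphas)
  structure(list(fsi_rand_mean = mu, fsi_rand_sd = sdev,
                 critical_limit = mu + 2 * sdev,
                 saen_rand_mean = if (compute_saen) mean(res$saens, na.rm = TRUE) else NA_real_,
                 n_surrogates = n_surrogates, seed = seed),
            class = "surrogate_stats")
}

#' @export
print.surrogate_stats <- function(x, ...) {
  cat(sprintf(
    "<surrogate_stats> %d permutations: FSI %.3f +/- %.3f, critical limit %.3f\n",
    x$n_surrogates, x$fsi_rand_mean, x$fsi_rand_sd, x$critical_limit))
  invisible(x)
}

#' Statistical persistence decay
#'
#' Computes the DFA scaling index of the series reshaped at every
#' stride-order separation `s = 1..max_s` ([reshape_series()]) and returns
#' the smallest separation at which the index drops below the surrogate
#' critical limit (strictly below; a value exactly at the limit does not
#' cross). If the curve never crosses, the result is censored at `max_s`
#' (attribute `censored = TRUE`). Separation 1 is the identity, so
#' `alpha_by_s[1]` equals the original series' FSI.
#'
#' @param isi Numeric stride-time series (800 strides in the standard
#'   protocol).
#' @param surrogates A `surrogate_stats` for the same series.
#' @param max_s Largest separation examined (default 100).
#' @param box_min,box_max DFA box-size range.
#'
#' @return An integer separation (strides) with attributes `censored` and
#'   `alpha_by_s` (the decay curve).
#' @export
spd <- function(isi, surrogates, max_s = 100, box_min = 10, box_max = 40) {
  stopifnot(inherits(surrogates, "surrogate_stats"))
  x <- as.numeric(isi)
  alphas <- rep(NA_real_, max_s)
  for (s in seq_len(max_s)) {
    a <- tryCatch(dfa(reshape_series(x, s), box_min, box_max)$alpha,
                  error = function(e) {
                    warning("DFA undefined at separation ", s, ": ",
                            conditionMessage(e))
                    NA_real_
                  })
    alphas[s] <- a
  }
  cross <- which(alphas < surrogates$critical_limit)
  censored <- length(cross) == 0
  out <- if (censored) max_s else min(cross)
  structure(as.integer(out), censored = censored, alpha_by_s = alphas)
}

#' Normalized sample entropy
#'
#' Rescales a reshaped series' sample entropy between the original series'
#' entropy (0) and the mean random-permutation entropy (1).
#'
#' @param saen_reshape Sample entropy of the reshaped series.
#' @param saen_original Sample entropy of the original series.
#' @param saen_rand Mean sample entropy of the random surrogates.
#' @return `(saen_reshape - saen_original) / (saen_rand - saen_original)`.
#' @export
normalized_saen <- function(saen_reshape, saen_original, saen_rand) {
  denom <- saen_rand - saen_original
  if (!is.finite(denom) || denom == 0)
    stop("normalization undefined: surrogate and original entropies equal")
  (saen_reshape - saen_original) / denom
}

#' Entropic half-life
#'
#' Sample entropy is computed for the series reshaped at each separation
#' `s = 1..max_s` and normalized between the original entropy (0) and the
#' random-surrogate entropy (1) via [normalized_saen()]. The normalized
#' curve rises from 0 towards 1 as reshaping destroys the series'
#' short-range structure; the entropic half-life is the separation at
#' which half the series' predictability is lost.
#'
#' Two crossing conventions are provided. The default, `"loss"`, reports
#' the smallest `s` at which the normalized entropy reaches or exceeds
#' 0.5 -- equivalently, the retained predictability `1 - normalized`
#' first falls below one half. The `"literal"` convention instead reports
#' the first `s` at which the normalized value drops below 0.5 after the
#' curve has exceeded it. Both are censored at `max_s` when no crossing
#' occurs (attribute `censored`).
#'
#' @param isi Numeric stride-time series.
#' @param surrogates A `surrogate_stats` computed with
#'   `compute_saen = TRUE`.
#' @param m,r_fraction Entropy parameters; the radius is fixed from the
#'   original series SD for every reshaping.
#' @param max_s Largest separation examined.
#' @param direction Crossing convention, `"loss"` (default) or
#'   `"literal"`.
#'
#' @return An integer separation (strides) with attributes `censored` and
#'   `norm_saen_by_s` (the normalized curve).
#' @export
enhl <- function(isi, surrogates, m = 2, r_fraction = 0.15, max_s = 100,
                 direction = c("loss", "literal")) {
  stopifnot(inherits(surrogates, "surrogate_stats"))
  direction <- match.arg(direction)
  x <- as.numeric(isi)
  if (!is.finite(surrogates$saen_rand_mean))
    stop("surrogates were computed without sample entropies")
  r <- r_fraction * sd(x)
  s0 <- saen(x, m = m, r = r)
  if (is.na(s0)) stop("sample entropy of the original series is undefined")
  curve <- rep(NA_real_, max_s)
  for (s in seq_len(max_s)) {
    ss <- saen(reshape_series(x, s), m = m, r = r)
    curve[s] <- normalized_saen(ss, s0, surrogates$saen_rand_mean)
  }
  if (direction == "loss") {
    cross <- which(curve >= 0.5)
  } else {
    above <- which(curve > 0.5)
    cross <- if (length(above)) {
      after <- which(curve < 0.5 & seq_along(curve) > min(above))
      after
    } else integer(0)
  }
  censored <- length(cross) == 0
  out <- if (censored) max_s else min(cross)
  structure(as.integer(out), censored = censored, norm_saen_by_s = curve,
            saen_original = s0)
}
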