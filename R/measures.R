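# Linear and single-series nonlinear stride-time variability measures.

#' Linear stride-time measures
#'
#' Mean stride time, sample standard deviation (denominator n - 1) and
#' coefficient of variation (percent) of a walking bout's inter-stride
#' intervals.
#'
#' @param bout A `walking_bout`, or a bare numeric ISI vector.
#' @param min_strides Minimum strides required (default 20).
#'
#' @return A list with `xisi` (s), `sd` (s) and `cov` (percent,
#'   `100 * sd / xisi`).
#' @export
linear_measures <- function(bout, min_strides = 20) {
  isi <- if (inherits(bout, "walking_bout")) bout$isi else as.numeric(bout)
  if (length(isi) < min_strides)
    stop("bout has fewer than ", min_strides, " strides")
  xisi <- mean(isi)
  s <- sd(isi)
  list(xisi = xisi, sd = s, cov = 100 * s / xisi)
}

#' Detrended fluctuation analysis
#'
#' Estimates the fractal scaling index (FSI) of a stride-time series. The
#' mean-centred series is integrated to a profile, the profile is split
#' into non-overlapping boxes of `n` strides taken from the start of the
#' series (the tail remainder is discarded), a least-squares line is
#' removed within each box, the root-mean-square residual is averaged
#' across boxes, and the slope of `log10(fluctuation)` against `log10(n)`
#' over `box_min:box_max` is the scaling index. An index near 0.5
#' indicates uncorrelated stride times; values near 1 indicate persistent
#' long-range correlation.
#'
#' @param isi Numeric stride-time series.
#' @param box_min,box_max Inclusive box-size range in strides (defaults
#'   10 and 40; every integer in between is used).
#'
#' @return An object of class `gait_dfa`: list with `alpha` (the FSI),
#'   `fit_intercept`, `box_sizes` and `fluctuation` (RMS per box size).
#' @examples
#' isi <- simulate_isi("white", 512, seed = 1)
#' dfa(isi$values)$alpha # near 0.5
#' @export
dfa <- function(isi, box_min = 10, box_max = 40) {
  x <- as.numeric(isi)
  N <- length(x)
  if (box_max < box_min) stop("box_max must be >= box_min")
  if (N < 2 * box_max)
    stop("series too short for box size ", box_max)
  if (sd(x) == 0) stop("series has zero variance")
  y <- cumsum(x - mean(x))
  ns <- box_min:box_max
  fluct <- vapply(ns, function(n) {
    m <- N %/% n
    mat <- matrix(y[seq_len(n * m)], nrow = n)
    xc <- seq_len(n) - (n + 1) / 2
    slope <- colSums(mat * xc) / sum(xc^2)
    resid <- mat - outer(xc, slope) - rep(colMeans(mat), each = n)
    mean(sqrt(colMeans(resid^2)))
  }, numeric(1))
  fit <- lm(log10(fluct) ~ log10(ns))
  structure(list(alpha = unname(coef(fit)[2]),
                 fit_intercept = unname(coef(fit)[1]),
                 box_sizes = ns, fluctuation = fluct),
            class = "gait_dfa")
}

#' @export
print.gait_dfa <- function(x, ...) {
  cat(sprintf("<gait_dfa> alpha = %.3f (boxes %d-%d)\n", x$alpha,
              min(x$box_sizes), max(x$box_sizes)))
  invisible(x)
}

# Template match-count matrix machinery shared by apen/saen. Returns the
# logical N-m+1 square matrix of Chebyshev template matches at length m.
template_matches <- function(x, m, r) {
  N <- length(x)
  D <- abs(outer(x, x, "-")) <= r
  M <- D[1:(N - m + 1), 1:(N - m + 1), drop = FALSE]
  if (m > 1) {
    for (k in 1:(m - 1)) {
      idx <- (1 + k):(N - m + 1 + k)
      M <- M & D[idx, idx, drop = FALSE]
    }
  }
  M
}

#' Approximate entropy
#'
#' Regularity statistic in the Pincus formulation with self-matches
#' included: `ApEn = Phi_m - Phi_(m+1)` where `Phi_m` is the mean log
#' relative frequency of Chebyshev template matches of length `m` within
#' radius `r`. Lower values indicate a more regular series.
#'
#' @param isi Numeric stride-time series.
#' @param m Template length (default 2).
#' @param r Similarity radius in seconds; defaults to
#'   `r_fraction * sd(isi)`.
#' @param r_fraction Radius fraction used when `r` is not given.
#'
#' @return Approximate entropy (unitless scalar).
#' @export
apen <- function(isi, m = 2, r = NULL, r_fraction = 0.15) {
  x <- as.numeric(isi)
  r <- r %||% (r_fraction * sd(x))
  if (!is.finite(r) || r <= 0) stop("r must be positive (constant series?)")
  phi <- function(mm) {
    M <- template_matches(x, mm, r)
    mean(log(rowSums(M) / nrow(M)))
  }
  phi(m) - phi(m + 1)
}

#' Sample entropy
#'
#' Like approximate entropy but with the self-matching bias removed:
#' `SaEn = -log(A / B)` where `B` counts ordered pairs of distinct
#' templates of length `m` matching within Chebyshev radius `r` and `A`
#' counts the same pairs still matching at length `m + 1`. Zero for a
#' strictly periodic series; undefined (returned as `NA` with a warning)
#' when no template pair matches.
#'
#' @inheritParams apen
#' @return Sample entropy (unitless scalar), or `NA` if undefined.
#' @export
saen <- function(isi, m = 2, r = NULL, r_fraction = 0.15) {
  x <- as.numeric(isi)
  r <- r %||% (r_fraction * sd(x))
  if (!is.finite(r) || r <= 0) stop("r must be positive (constant series?)")
  # count over the N-m-1+1 templates that admit an (m+1)-extension, the
  # standard convention pairing B and A over the same template set
  N <- length(x)
  Mb <- template_matches(x, m, r)
  nb <- N - m  # templates considered: 1..N-m
  B <- sum(Mb[1:nb, 1:nb]) - nb
  Ma <- template_matches(x, m + 1, r)
  A <- sum(Ma) - nrow(Ma)
  if (A == 0 || B == 0) {
    warning("sample entropy undefined: no template matches at length m",
            if (A == 0) "+1" else "")
    return(NA_real_)
  }
  -log(A / B) + 0  # + 0 normalizes the signed zero of a perfect match
}

#' Coarse-grain a series
#'
#' Replaces each non-overlapping window of `tau` consecutive values by its
#' mean; the tail remainder is dropped. Scale 1 is the identity.
#'
#' @param isi Numeric series.
#' @param tau Scale (window length), a positive integer.
#' @return Numeric series of length `floor(length(isi) / tau)`.
#' @export
coarse_grain <- function(isi, tau) {
  x <- as.numeric(isi)
  if (tau < 1) stop("tau must be >= 1")
  tau <- as.integer(tau)
  if (length(x) < tau) stop("series shorter than tau")
  m <- length(x) %/% tau
  if (tau == 1L) return(x)
  colMeans(matrix(x[seq_len(m * tau)], nrow = tau))
}

#' Multiscale entropy
#'
#' Sample entropy of coarse-grained versions of the series at the given
#' scales. The similarity radius is fixed from the original (scale-1)
#' series SD for all scales, so entropy changes across scales reflect the
#' coarse-graining, not a drifting radius.
#'
#' @param isi Numeric stride-time series.
#' @param scales Integer scales (default 1:4).
#' @param m Template length.
#' @param r_fraction Radius fraction of the scale-1 SD.
#'
#' @return A data frame with columns `scale`, `n` (coarse-grained length)
#'   and `saen`.
#' @export
mse <- function(isi, scales = 1:4, m = 2, r_fraction = 0.15) {
  x <- as.numeric(isi)
  r <- r_fraction * sd(x)
  out <- lapply(scales, function(tau) {
    xg <- coarse_grain(x, tau)
    data.frame(scale = tau, n = length(xg), saen = saen(xg, m = m, r = r))
  })
  do.call(rbind, out)
}

#' Complexity index
#'
#' Trapezoidal area under the sample-entropy-versus-scale curve.
#'
#' @param mse_result A data frame from [mse()], or a numeric vector of
#'   per-scale sample entropies (scales then taken as `1:length`).
#' @return The complexity index (unitless scalar).
#' @export
complexity_index <- function(mse_result) {
  if (is.data.frame(mse_result)) {
    scales <- mse_result$scale
    values <- mse_result$saen
  } else {
    values <- as.numeric(mse_result)
    scales <- seq_along(values)
  }
  if (anyNA(values)) stop("complexity index undefined: NA entropy at some scale")
  trapz_area(scales, values)
}
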