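# Synthetic stride-time series and gait-like acceleration recordings with
# known ground truth.

fgn_autocov <- function(k, hurst) {
  0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
           abs(k - 1)^(2 * hurst))
}

# Exact fractional Gaussian noise by circulant embedding (Davies-Harte).
# Returns n values with unit variance and the exact fGn autocovariance for
# the given Hurst exponent; the induced covariance of the construction
# equals the target Toeplitz covariance to machine precision.
fgn_sim <- function(n, hurst) {
  if (n == 1) return(rnorm(1))
  m <- 2L * n
  g <- fgn_autocov(0:n, hurst)
  c_row <- c(g, rev(g[2:n]))
  lam <- Re(fft(c_row))
  if (min(lam) < -1e-8)
    stop("circulant embedding failed: negative eigenvalue ", min(lam))
  lam[lam < 0] <- 0
  half <- m %/% 2L
  v <- rnorm(m)
  z <- complex(length.out = m)
  z[1] <- sqrt(lam[1] / m) * v[1]
  z[half + 1] <- sqrt(lam[half + 1] / m) * v[2]
  j <- 2:half
  z[j] <- sqrt(lam[j] / (2 * m)) *
    complex(real = v[seq(3, by = 2, length.out = half - 1)],
            imaginary = v[seq(4, by = 2, length.out = half - 1)])
  z[m + 2 - j] <- Conj(z[j])
  Re(fft(z))[1:n]
}

#' Simulate an inter-stride-interval series with known structure
#'
#' Generates stride-time (inter-stride-interval, ISI) series under one of
#' four generating models:
#'
#' * `"fgn"`: fractional Gaussian noise with Hurst exponent `hurst`,
#'   generated by exact circulant embedding (Davies-Harte) and scaled to
#'   `mean_s` / `sd_s`. Free-living stride times of healthy adults show
#'   persistent long-range correlation with a fractal scaling index around
#'   0.9-0.95, which `hurst` reproduces directly.
#' * `"white"`: i.i.d. Gaussian stride times.
#' * `"periodic"`: a deterministic repetition of `pattern`.
#' * `"mix"`: each stride is drawn from the Gaussian model with probability
#'   `mix_prob` and taken from the periodic pattern otherwise.
#'
#' Values are clipped below at 0.4 s, half the 0.8 s lower limit of a
#' healthy adult's stride time, so that synthetic series can never trip
#' the detector's physiological spacing rule; any clipping is reported via
#' the `n_clipped` field. Parameter combinations for which more than 1% of
#' draws would clip are rejected.
#'
#' @param model One of `"fgn"`, `"white"`, `"periodic"`, `"mix"`.
#' @param n Number of strides (>= 1).
#' @param mean_s Mean stride time in seconds.
#' @param sd_s Stride-time standard deviation in seconds (>= 0).
#' @param hurst Hurst exponent in (0, 1], used by `model = "fgn"`.
#' @param pattern Numeric vector of stride times recycled by the periodic
#'   and mix models.
#' @param mix_prob Probability that a stride is random rather than
#'   periodic under `model = "mix"`.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#'
#' @return An object of class `isi_series`: a list with `values` (seconds),
#'   `model`, `hurst`, `mean_s`, `sd_s`, `seed` and `n_clipped`.
#' @examples
#' isi <- simulate_isi("fgn", n = 256, mean_s = 1.12, sd_s = 0.04,
#'                     hurst = 0.9, seed = 1)
#' mean(isi$values)
#' @export
simulate_isi <- function(model = c("fgn", "white", "periodic", "mix"),
                         n, mean_s = 1.12, sd_s = 0.04, hurst = 0.9,
                         pattern = c(1.1, 1.2), mix_prob = 0.5,
                         seed = NULL) {
  model <- match.arg(model)
  if (length(n) != 1 || n < 1) stop("n must be a positive count")
  n <- as.integer(n)
  if (sd_s < 0) stop("sd_s must be >= 0")
  clip_floor <- 0.4
  if (model %in% c("fgn", "white", "mix") && sd_s > 0 &&
      pnorm(clip_floor, mean = mean_s, sd = sd_s) > 0.01)
    stop("sd_s so large that more than 1% of stride times would clip at ",
         clip_floor, " s; parameters unusable")
  if (model == "fgn" && (hurst <= 0 || hurst > 1))
    stop("hurst must lie in (0, 1] for the fgn model")

  values <- with_seed(seed, switch(
    model,
    fgn = mean_s + sd_s * fgn_sim(n, hurst),
    white = rnorm(n, mean_s, sd_s),
    periodic = rep_len(pattern, n),
    mix = {
      base <- rep_len(pattern, n)
      pick <- runif(n) < mix_prob
      base[pick] <- rnorm(sum(pick), mean_s, sd_s)
      base
    }))

  n_clipped <- sum(values < clip_floor)
  if (n_clipped > 0) {
    warning(n_clipped, " stride time(s) clipped at ", clip_floor, " s")
    values[values < clip_floor] <- clip_floor
  }
  structure(
    list(values = values, model = model,
         hurst = if (model == "fgn") hurst else NA_real_,
         mean_s = mean_s, sd_s = sd_s, seed = seed, n_clipped = n_clipped),
    class = "isi_series")
}

#' @export
print.isi_series <- function(x, ...) {
  cat(sprintf("<isi_series:%s> %d strides, mean %.3f s, sd %.4f s",
              x$model, length(x$values), mean(x$values), sd(x$values)))
  if (!is.na(x$hurst)) cat(sprintf(", H = %.2f", x$hurst))
  cat("\n")
  invisible(x)
}

# Gait-cycle waveform constants (m/s^2 and fractions of the stride time).
# Each stride contributes a wide negative mid-swing trough (the wavelet
# detector's candidate minimum), a sharp positive pre-contact impact peak,
# and a narrow negative transient whose minimum falls exactly at the heel
# contact. The trough scales with stride duration; the impact complex has a
# fixed duration, as ground-impact transients do not lengthen with slower
# strides.
wave_constants <- function() {
  list(trough_amp = 3.5, trough_lead = 0.55, trough_width = 0.10,
       peak_amp = 5.0, peak_lead_s = 0.12, peak_width_s = 0.044,
       contact_amp = 4.0, contact_width_s = 0.033)
}

gauss_bump <- function(t, center, width) exp(-(t - center)^2 / (2 * width^2))

# Continuous-time vertical acceleration for one bout. `contacts` has one
# more element than `isi`; a lead-in pseudo-stride before the first contact
# (same duration as the first stride) makes the first contact detectable by
# the same minimum-maximum-minimum chain as every other contact.
bout_waveform <- function(t, contacts, isi) {
  w <- wave_constants()
  dur <- c(isi[1], isi)
  a <- numeric(length(t))
  for (k in seq_along(contacts)) {
    ck <- contacts[k]
    Tk <- dur[k]
    a <- a - w$trough_amp *
      gauss_bump(t, ck - w$trough_lead * Tk, w$trough_width * Tk)
    a <- a + w$peak_amp * gauss_bump(t, ck - w$peak_lead_s, w$peak_width_s)
    a <- a - w$contact_amp * gauss_bump(t, ck, w$contact_width_s)
  }
  a
}

#' Simulate a gait-like acceleration recording with known ground truth
#'
#' Builds a vertical-acceleration recording containing one walking bout per
#' element of `bout_isis`, separated by quiet gaps, sampled on an
#' irregular (jittered) timestamp grid with a gravity offset and optional
#' upside-down orientation -- the conditions of a phone resting in a front
#' pant pocket. Within each bout, every stride contributes a smooth wide
#' mid-swing trough plus a localized impact complex (sharp positive peak
#' followed by a narrow negative transient) whose first post-maximum local
#' minimum falls exactly at the true heel-contact time, so detector output
#' can be scored against exact ground truth.
#'
#' A bout built from `n` inter-stride intervals contains `n + 1` heel
#' contacts (contacts bound strides); the bout span runs from its first to
#' its last contact.
#'
#' @param bout_isis List of `isi_series` objects (or bare numeric vectors
#'   of stride times in seconds), one per walking bout.
#' @param gap_s Numeric vector of quiet gaps between consecutive bouts, in
#'   seconds; length `length(bout_isis) - 1`. All gaps must exceed 1.8 s,
#'   otherwise adjacent bouts would merge and the ground truth would be
#'   invalid.
#' @param fs_nominal Nominal sampling rate in Hz.
#' @param timestamp_jitter_sd SD of Gaussian jitter added to the nominal
#'   timestamps, in seconds (emulates the phone's irregular sampling).
#' @param gravity Gravity offset added to the signal, in m/s^2.
#' @param invert If `TRUE` the measured signal is multiplied by -1
#'   (upside-down phone).
#' @param noise_sd SD of additive white measurement noise in m/s^2.
#' @param pad_s Quiet padding before the first and after the last bout.
#' @param seed Integer seed driving jitter and noise.
#'
#' @return An object of class `synthetic_recording`: a list with `accel`
#'   (an [accel_recording]), `true_rhc_times` (all heel-contact times,
#'   strictly increasing), `true_bout_spans` (data frame of `start_s`,
#'   `end_s`), `isi_truth` (the input list), `waveform_amplitude` (peak
#'   absolute value of the noiseless waveform) and the generator
#'   parameters.
#' @examples
#' rec <- simulate_recording(list(rep(1.1, 30)), seed = 1)
#' rec$true_bout_spans
#' @export
simulate_recording <- function(bout_isis, gap_s = numeric(0),
                               fs_nominal = 100, timestamp_jitter_sd = 0.001,
                               gravity = 9.81, invert = TRUE, noise_sd = 0,
                               pad_s = 2, seed = NULL) {
  if (fs_nominal <= 0) stop("fs_nominal must be positive")
  isis <- lapply(bout_isis, function(b) if (inherits(b, "isi_series")) b$values else as.numeric(b))
  nb <- length(isis)
  if (nb == 0) stop("at least one bout is required")
  if (length(gap_s) != nb - 1)
    stop("gap_s must have one entry per gap between bouts")
  if (any(gap_s <= 1.8))
    stop("all gaps must exceed 1.8 s; shorter gaps would merge bouts")

  contacts <- vector("list", nb)
  t0 <- pad_s
  for (b in seq_len(nb)) {
    contacts[[b]] <- t0 + c(0, cumsum(isis[[b]]))
    t0 <- max(contacts[[b]]) + if (b < nb) gap_s[b] else 0
  }
  duration <- t0 + pad_s
  n <- floor(duration * fs_nominal) + 1L

  out <- with_seed(seed, {
    tt <- (0:(n - 1)) / fs_nominal
    if (timestamp_jitter_sd > 0)
      tt <- sort(tt + rnorm(n, 0, timestamp_jitter_sd))
    a <- numeric(n)
    for (b in seq_len(nb)) a <- a + bout_waveform(tt, contacts[[b]], isis[[b]])
    amp <- max(abs(a))
    if (noise_sd > 0) a <- a + rnorm(n, 0, noise_sd)
    list(t = tt, a = a, amp = amp)
  })

  meas <- out$a + gravity
  if (invert) meas <- -meas
  rec <- accel_recording(t = out$t, az = meas, vertical_axis = "az",
                         fs_nominal = fs_nominal)
  spans <- data.frame(
    start_s = vapply(contacts, min, numeric(1)),
    end_s = vapply(contacts, max, numeric(1)))
  structure(
    list(accel = rec, true_rhc_times = unlist(contacts),
         true_bout_spans = spans,
         isi_truth = bout_isis,
         waveform_amplitude = out$amp,
         params = list(fs_nominal = fs_nominal,
                       timestamp_jitter_sd = timestamp_jitter_sd,
                       gravity = gravity, invert = invert,
                       noise_sd = noise_sd, pad_s = pad_s, gap_s = gap_s,
                       seed = seed)),
    class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording> %d bout(s), %d true contacts, %.1f s\n",
    nrow(x$true_bout_spans), length(x$true_rhc_times),
    diff(range(x$accel$t))))
  invisible(x)
}

#' Write and read recordings as CSV
#'
#' `write_recording()` stores the tri-axial stream as a CSV with columns
#' `t_s`, `ax`, `ay`, `az`. For a `synthetic_recording` it additionally
#' writes a `<path>_events.csv` sidecar of true heel-contact times and a
#' `<path>_truth.json` file of bout spans and generator parameters.
#' `read_recording()` loads such a CSV back as an [accel_recording].
#'
#' @param rec An [accel_recording] or `synthetic_recording`.
#' @param path Output CSV path.
#' @return `write_recording()` returns `path` invisibly;
#'   `read_recording()` returns an [accel_recording].
#' @export
write_recording <- function(rec, path) {
  sr <- NULL
  if (inherits(rec, "synthetic_recording")) {
    sr <- rec
    rec <- rec$accel
  }
  df <- data.frame(t_s = rec$t, ax = rec$ax, ay = rec$ay, az = rec$az)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(sr)) {
    stem <- sub("\\.csv$", "", path)
    write.csv(data.frame(t_s = sr$true_rhc_times),
              paste0(stem, "_events.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(bout_spans = sr$true_bout_spans, params = sr$params),
      paste0(stem, "_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_recording
#' @param vertical_axis Axis label to treat as vertical when reading.
#' @param fs_nominal Nominal sampling rate of the stored recording.
#' @param participant_id Optional participant label.
#' @export
read_recording <- function(path, vertical_axis = "az", fs_nominal = 100,
                           participant_id = NA_character_) {
  df <- read.csv(path)
  need <- c("t_s", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop("recording CSV must have columns t_s, ax, ay, az")
  accel_recording(t = df$t_s, ax = df$ax, ay = df$ay, az = df$az,
                  vertical_axis = vertical_axis, fs_nominal = fs_nominal,
                  participant_id = participant_id)
}
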