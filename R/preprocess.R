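# Preprocessing: irregular tri-axial recording -> two uniform vertical
# streams (raw and low-pass filtered).

#' Resample the vertical axis onto a uniform grid
#'
#' Linearly interpolates the vertical-axis acceleration onto a uniform grid
#' running from the first to the last timestamp. Duplicated timestamps are
#' collapsed to the mean of their values before interpolation. Phone
#' accelerometers do not sample at a constant rate, so this step puts the
#' signal on the fixed grid every later stage assumes.
#'
#' @param rec An [accel_recording].
#' @param fs Target sampling rate in Hz (default 100).
#'
#' @return A `uniform_signal` with `stream = "raw"` (orientation and
#'   gravity still uncorrected).
#' @export
resample_uniform <- function(rec, fs = 100) {
  stopifnot(inherits(rec, "accel_recording"))
  x <- rec[[rec$vertical_axis]]
  t <- rec$t
  if (anyDuplicated(t)) {
    x <- as.numeric(tapply(x, t, mean))
    t <- sort(unique(t))
  }
  if (length(t) < 2) stop("need at least 2 distinct timestamps")
  if (diff(range(t)) < 1) stop("recording shorter than 1 s")
  grid <- seq(t[1], t[length(t)], by = 1 / fs)
  a <- approx(t, x, xout = grid)$y
  new_uniform_signal(a, fs = fs, t0 = t[1], stream = "raw")
}

#' Remove gravity bias and correct device orientation
#'
#' Subtracts the whole-recording mean of the vertical signal (the gravity
#' bias estimate -- robust to calibration offset, unlike subtracting a
#' fixed 9.81 m/s^2) and multiplies by -1 when the device was worn upside
#' down.
#'
#' @param sig A `uniform_signal`.
#' @param invert If `TRUE`, flip the sign after mean removal.
#'
#' @return The corrected `uniform_signal`.
#' @export
correct_signal <- function(sig, invert = FALSE) {
  stopifnot(inherits(sig, "uniform_signal"))
  if (length(sig$a) == 0) stop("signal is empty")
  a <- sig$a - mean(sig$a)
  if (invert) a <- -a
  new_uniform_signal(a, fs = sig$fs, t0 = sig$t0, stream = sig$stream)
}

#' Low-pass filter the vertical acceleration
#'
#' Single-pass (causal) Butterworth low-pass filter. The causal pass
#' shifts the signal by its group delay (about 3 samples at the default
#' 16 Hz cutoff and 100 Hz rate), which is why heel-contact events found
#' in the filtered stream are later relocated in the raw stream with a
#' three-frame offset search ([relocate_in_raw()]).
#'
#' @param sig A `uniform_signal` (the corrected raw stream).
#' @param cutoff Cutoff frequency in Hz (default 16; must be below the
#'   Nyquist frequency).
#' @param order Filter order (default 4).
#'
#' @return A `uniform_signal` with `stream = "filtered"`. The input raw
#'   stream is left untouched and should be retained alongside.
#' @export
lowpass_filter <- function(sig, cutoff = 16, order = 4) {
  stopifnot(inherits(sig, "uniform_signal"))
  if (cutoff >= sig$fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (sig$fs / 2), type = "low")
  a <- as.numeric(signal::filter(bf, sig$a))
  new_uniform_signal(a, fs = sig$fs, t0 = sig$t0, stream = "filtered")
}

#' Preprocess a recording into raw and filtered streams
#'
#' Convenience wrapper: resample to a uniform grid, correct gravity and
#' orientation, and derive the filtered stream. The raw stream feeds the
#' nonlinear measures; the filtered stream feeds event detection and the
#' linear measures.
#'
#' @param rec An [accel_recording].
#' @param fs Target sampling rate in Hz.
#' @param invert Whether the device was worn upside down.
#' @param cutoff,order Low-pass filter settings.
#'
#' @return A list with elements `raw` and `filtered`, both `uniform_signal`s
#'   sharing grid, length and `t0`.
#' @export
preprocess_recording <- function(rec, fs = 100, invert = TRUE, cutoff = 16,
                                 order = 4) {
  raw <- correct_signal(resample_uniform(rec, fs = fs), invert = invert)
  list(raw = raw, filtered = lowpass_filter(raw, cutoff = cutoff, order = order))
}
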