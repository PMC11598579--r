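#' Tri-axial accelerometer recording
#'
#' Container for a raw, timestamped tri-axial acceleration stream. The
#' timestamps need not be uniformly spaced; they must be non-decreasing and
#' become strictly increasing once duplicated stamps are collapsed (see
#' [resample_uniform()]).
#'
#' @param t Numeric vector of timestamps in seconds, non-decreasing.
#' @param ax,ay,az Numeric vectors of acceleration in m/s^2, same length
#'   as `t`.
#' @param vertical_axis Which axis carries the vertical acceleration
#'   (`"ax"`, `"ay"` or `"az"`).
#' @param fs_nominal Nominal sampling rate in Hz.
#' @param participant_id Optional participant label.
#'
#' @return An object of class `accel_recording`.
#' @export
accel_recording <- function(t, ax = NULL, ay = NULL, az, vertical_axis = "az",
                            fs_nominal = 100, participant_id = NA_character_) {
  n <- length(t)
  ax <- ax %||% numeric(n)
  ay <- ay %||% numeric(n)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("t, ax, ay, az must have equal lengths")
  if (is.unsorted(t)) stop("timestamps must be non-decreasing")
  if (!vertical_axis %in% c("ax", "ay", "az"))
    stop("vertical_axis must be one of 'ax', 'ay', 'az'")
  structure(
    list(t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
         az = as.numeric(az), vertical_axis = vertical_axis,
         fs_nominal = fs_nominal, participant_id = participant_id),
    class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  dur <- diff(range(x$t))
  cat(sprintf(
    "<accel_recording> %d samples, %.1f s, nominal %g Hz, vertical axis '%s'\n",
    length(x$t), dur, x$fs_nominal, x$vertical_axis))
  invisible(x)
}

# Uniformly resampled single-axis signal. `stream` tags whether the signal
# is the raw (unfiltered) or the low-pass filtered variant.
new_uniform_signal <- function(a, fs, t0, stream = "raw") {
  stopifnot(stream %in% c("raw", "filtered"))
  structure(list(a = as.numeric(a), fs = fs, t0 = t0, stream = stream),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal:%s> %d samples at %g Hz, t0 = %.3f s\n",
              x$stream, length(x$a), x$fs, x$t0))
  invisible(x)
}

# Ordered right-heel-contact events for one stream of one recording.
new_heel_contacts <- function(indices, fs, t0, stream) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    stop("heel-contact indices must be strictly increasing")
  structure(list(indices = indices, times = t0 + (indices - 1L) / fs,
                 fs = fs, t0 = t0, stream = stream),
            class = "heel_contacts")
}

#' @export
print.heel_contacts <- function(x, ...) {
  cat(sprintf("<heel_contacts:%s> %d events", x$stream, length(x$indices)))
  if (length(x$times) > 1)
    cat(sprintf(", median ISI %.3f s", median(diff(x$times))))
  cat("\n")
  invisible(x)
}

# One trimmed walking bout: ordered inter-stride intervals with provenance.
new_walking_bout <- function(isi, start_s, end_s, stream,
                             participant_id = NA_character_) {
  structure(list(isi = as.numeric(isi), n_strides = length(isi),
                 start_s = start_s, end_s = end_s, stream = stream,
                 participant_id = participant_id),
            class = "walking_bout")
}

#' @export
print.walking_bout <- function(x, ...) {
  cat(sprintf(
    "<walking_bout:%s> %d strides, %.1f-%.1f s, mean ISI %.3f s\n",
    x$stream, x$n_strides, x$start_s, x$end_s, mean(x$isi)))
  invisible(x)
}

#' Entropy parameters
#'
#' Template length `m` and similarity radius `r` for approximate and sample
#' entropy. The radius is `r_fraction` times the sample standard deviation
#' of the series it is derived from.
#'
#' @param series Numeric series from which to derive `r`.
#' @param m Template length (default 2).
#' @param r_fraction Fraction of the series SD used as radius (default 0.15).
#'
#' @return A list with elements `m`, `r_fraction` and `r`.
#' @export
entropy_params <- function(series, m = 2, r_fraction = 0.15) {
  if (m < 1) stop("m must be >= 1")
  r <- r_fraction * sd(series)
  if (!is.finite(r) || r <= 0)
    stop("similarity radius r is not positive (constant series?)")
  structure(list(m = as.integer(m), r_fraction = r_fraction, r = r),
            class = "entropy_params")
}
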