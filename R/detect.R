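# Right-heel-contact detection: six-step CWT procedure on the filtered
# stream, then relocation of each event in the raw stream.

#' Remove low-frequency drift
#'
#' Causal 4th-order Butterworth high-pass filter (default cutoff 0.1 Hz)
#' applied to the filtered stream before integration, so that slow drift
#' does not accumulate in the velocity signal.
#'
#' @param sig A `uniform_signal` (the filtered stream).
#' @param cutoff High-pass cutoff in Hz.
#' @param order Filter order.
#' @return A drift-corrected `uniform_signal`.
#' @export
drift_highpass <- function(sig, cutoff = 0.1, order = 4) {
  stopifnot(inherits(sig, "uniform_signal"))
  bf <- signal::butter(order, cutoff / (sig$fs / 2), type = "high")
  a <- as.numeric(signal::filter(bf, sig$a))
  new_uniform_signal(a, fs = sig$fs, t0 = sig$t0, stream = sig$stream)
}

#' Integrate acceleration to a velocity signal
#'
#' Cumulative trapezoidal integration on the uniform grid, initial value 0.
#' Integration smooths the signal; the subsequent wavelet differentiation
#' then acts as a band-limited differentiator.
#'
#' @param sig A `uniform_signal`.
#' @return A `uniform_signal` holding the vertical velocity (m/s).
#' @export
integrate_velocity <- function(sig) {
  stopifnot(inherits(sig, "uniform_signal"))
  v <- cumtrapz_uniform(sig$a, 1 / sig$fs)
  new_uniform_signal(v, fs = sig$fs, t0 = sig$t0, stream = sig$stream)
}

#' Differentiate the velocity signal with a Gaussian wavelet
#'
#' Convolves the velocity signal with a first-derivative-of-Gaussian
#' wavelet, i.e. a smoothed differentiator: the trace equals the
#' acceleration smoothed by a Gaussian of width `scale` samples. The sign
#' convention makes trace minima align with acceleration minima near heel
#' contact. The scale is defined in samples at 100 Hz and rescaled
#' proportionally for other sampling rates. Edges are padded with the
#' first/last velocity value.
#'
#' @param vel A `uniform_signal` holding the velocity.
#' @param scale Wavelet scale in samples at 100 Hz (default 12).
#'
#' @return A `cwt_trace` object: list with `c` (trace values, same grid as
#'   the input), `scale`, `fs`, `t0`.
#' @export
cwt_differentiate <- function(vel, scale = 12) {
  stopifnot(inherits(vel, "uniform_signal"))
  s <- scale * vel$fs / 100
  half <- ceiling(4 * s)
  if (length(vel$a) <= 2 * half + 1)
    stop("signal shorter than the wavelet support at scale ", scale)
  tau <- (-half):half
  kern <- tau / s^2 * exp(-tau^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  v <- vel$a
  vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
  y <- as.numeric(stats::filter(vp, rev(kern), sides = 2))
  y <- y[(half + 1):(half + length(v))] * vel$fs
  structure(list(c = y, scale = scale, fs = vel$fs, t0 = vel$t0),
            class = "cwt_trace")
}

#' @export
print.cwt_trace <- function(x, ...) {
  cat(sprintf("<cwt_trace> %d samples, scale %g\n", length(x$c), x$scale))
  invisible(x)
}

#' Find candidate heel-contact minima in the wavelet trace
#'
#' Locates all strict local minima of the trace, sets the detection
#' threshold to `threshold_fraction` times the median of the 10
#' most-negative local-minimum values, retains minima more negative than
#' the threshold, and greedily enforces the physiological separation rule
#' (minima closer than `min_separation` keep only the more negative one).
#' 0.8 s is the lower limit of a healthy adult's stride time, so two
#' retained candidates can never belong to the same stride.
#'
#' @param trace A `cwt_trace`.
#' @param min_separation Minimum separation between candidates in seconds.
#' @param threshold_fraction Fraction of the median of the 10 deepest
#'   minima used as threshold.
#'
#' @return Integer vector of candidate sample indices (1-based, sorted).
#' @export
find_candidate_minima <- function(trace, min_separation = 0.8,
                                  threshold_fraction = 0.4) {
  stopifnot(inherits(trace, "cwt_trace"))
  mins <- local_minima_idx(trace$c)
  if (length(mins) < 10)
    stop("fewer than 10 local minima in the trace; ",
         "recording too short to calibrate the threshold")
  vals <- trace$c[mins]
  threshold <- threshold_fraction * median(sort(vals)[1:10])
  keep <- mins[vals < threshold]
  if (length(keep) == 0) return(integer(0))
  sep <- min_separation * trace$fs
  accepted <- integer(0)
  for (idx in keep[order(trace$c[keep])]) {
    if (!length(accepted) || all(abs(accepted - idx) > sep))
      accepted <- c(accepted, idx)
  }
  sort(accepted)
}

#' Chain candidate minima to heel-contact events
#'
#' For each candidate wavelet minimum, searches forward to the next strict
#' local maximum of the trace, then forward from that maximum in the
#' filtered acceleration to the first strict local minimum -- the
#' right-heel contact. Candidates that run off the end of the signal are
#' dropped with a warning; duplicate resolutions collapse to one event,
#' and the physiological spacing rule (events closer than `min_separation`)
#' is enforced on the output by keeping the earlier event.
#'
#' @param sig_filtered The filtered `uniform_signal`.
#' @param trace The matching `cwt_trace`.
#' @param candidates Candidate indices from [find_candidate_minima()].
#' @param min_separation Minimum inter-event spacing in seconds.
#'
#' @return A `heel_contacts` object with `stream = "filtered"`.
#' @export
chain_to_heel_contacts <- function(sig_filtered, trace, candidates,
                                   min_separation = 0.8) {
  stopifnot(inherits(sig_filtered, "uniform_signal"),
            inherits(trace, "cwt_trace"))
  acc <- sig_filtered$a
  events <- integer(0)
  dropped <- 0L
  for (ci in candidates) {
    mx <- first_max_from(trace$c, ci + 1L)
    if (is.na(mx)) { dropped <- dropped + 1L; next }
    mn <- first_min_from(acc, mx + 1L)
    if (is.na(mn)) { dropped <- dropped + 1L; next }
    events <- c(events, mn)
  }
  if (dropped > 0)
    warning(dropped, " candidate(s) dropped: no maximum/minimum before ",
            "end of signal")
  events <- sort(unique(events))
  if (length(events) > 1) {
    sep <- min_separation * sig_filtered$fs
    keep <- c(TRUE, diff(events) > sep)
    while (!all(keep)) {
      events <- events[keep]
      keep <- c(TRUE, diff(events) > sep)
    }
  }
  new_heel_contacts(events, fs = sig_filtered$fs, t0 = sig_filtered$t0,
                    stream = "filtered")
}

#' Relocate heel contacts in the raw stream
#'
#' The causal low-pass filter delays the filtered stream by roughly three
#' samples, so each filtered-stream event index is offset backwards by
#' `offset_frames` and the raw signal is searched forward from there for
#' the first strict local minimum. Events whose search exhausts the signal
#' are dropped with a warning.
#'
#' @param events A `heel_contacts` object (filtered stream).
#' @param sig_raw The raw `uniform_signal` sharing the filtered stream's
#'   grid.
#' @param offset_frames Backward offset in samples (default 3).
#'
#' @return A `heel_contacts` object with `stream = "raw"`.
#' @export
relocate_in_raw <- function(events, sig_raw, offset_frames = 3) {
  stopifnot(inherits(events, "heel_contacts"),
            inherits(sig_raw, "uniform_signal"))
  out <- integer(0)
  dropped <- 0L
  for (e in events$indices) {
    mn <- first_min_from(sig_raw$a, e - offset_frames)
    if (is.na(mn)) { dropped <- dropped + 1L; next }
    out <- c(out, mn)
  }
  if (dropped > 0)
    warning(dropped, " event(s) dropped in raw relocation: search window ",
            "exceeded signal end")
  new_heel_contacts(sort(unique(out)), fs = sig_raw$fs, t0 = sig_raw$t0,
                    stream = "raw")
}

#' Detect right-heel contacts in a preprocessed recording
#'
#' Runs the full detection chain -- drift high-pass, trapezoidal
#' integration to velocity, Gaussian-wavelet differentiation, candidate
#' thresholding, minimum-maximum-minimum chaining, and raw-stream
#' relocation -- and returns the event series for both streams.
#'
#' @param streams A list with `raw` and `filtered` `uniform_signal`s, as
#'   returned by [preprocess_recording()].
#' @param highpass_cutoff Drift high-pass cutoff in Hz.
#' @param cwt_scale Wavelet scale in samples at 100 Hz.
#' @param min_separation Candidate/event separation in seconds.
#' @param threshold_fraction Candidate threshold fraction.
#' @param offset_frames Raw-relocation backward offset in samples.
#'
#' @return A list with `filtered` and `raw` `heel_contacts`.
#' @examples
#' rec <- simulate_recording(list(rep(1.1, 30)), seed = 1)
#' ev <- detect_heel_contacts(preprocess_recording(rec$accel))
#' ev$raw
#' @export
detect_heel_contacts <- function(streams, highpass_cutoff = 0.1,
                                 cwt_scale = 12, min_separation = 0.8,
                                 threshold_fraction = 0.4,
                                 offset_frames = 3) {
  hp <- drift_highpass(streams$filtered, cutoff = highpass_cutoff)
  vel <- integrate_velocity(hp)
  trace <- cwt_differentiate(vel, scale = cwt_scale)
  cand <- find_candidate_minima(trace, min_separation = min_separation,
                                threshold_fraction = threshold_fraction)
  ev_f <- chain_to_heel_contacts(streams$filtered, trace, cand,
                                 min_separation = min_separation)
  ev_r <- relocate_in_raw(ev_f, streams$raw, offset_frames = offset_frames)
  list(filtered = ev_f, raw = ev_r)
}
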