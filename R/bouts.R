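# Walking-bout segmentation and the per-participant frequency table.

#' Segment heel contacts into walking bouts
#'
#' Splits a heel-contact series at inter-event gaps greater than `gap_s`
#' into candidate bouts, computes each bout's inter-stride-interval (ISI)
#' series as successive contact-time differences, discards bouts with
#' `min_raw_strides` or fewer strides, removes the first and last `trim`
#' strides of each surviving bout (gait initiation and termination are not
#' steady state), and retains bouts with at least `min_strides` strides
#' after trimming.
#'
#' A bout "stride count" is its number of ISI values, i.e. events minus
#' one. With the defaults, a bout must have at least 25 strides before
#' trimming and therefore at least 21 afterwards.
#'
#' @param events A `heel_contacts` object.
#' @param gap_s Gap threshold separating bouts, in seconds (default 1.8).
#' @param min_raw_strides Bouts with this many strides or fewer (pre-trim)
#'   are discarded (default 24, i.e. a bout needs more than 24).
#' @param trim Strides removed from each end of a surviving bout.
#' @param min_strides Minimum strides retained after trimming.
#' @param participant_id Optional participant label carried into the bouts.
#'
#' @return A list of `walking_bout` objects (possibly empty).
#' @export
segment_bouts <- function(events, gap_s = 1.8, min_raw_strides = 24,
                          trim = 2, min_strides = 20,
                          participant_id = NA_character_) {
  stopifnot(inherits(events, "heel_contacts"))
  times <- events$times
  if (length(times) == 0) return(list())
  brk <- which(diff(times) > gap_s)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(times))
  bouts <- list()
  for (k in seq_along(starts)) {
    tk <- times[starts[k]:ends[k]]
    n_str <- length(tk) - 1L
    if (n_str <= min_raw_strides) next
    isi <- diff(tk)
    keep <- (trim + 1L):(n_str - trim)
    isi <- isi[keep]
    if (length(isi) < min_strides) next
    bouts[[length(bouts) + 1L]] <- new_walking_bout(
      isi, start_s = tk[trim + 1L], end_s = tk[n_str + 1L - trim],
      stream = events$stream, participant_id = participant_id)
  }
  bouts
}

#' Per-participant walking-bout frequency table
#'
#' Summarizes, for each participant, the number of retained walking bouts,
#' the total stride count, and the stride counts of the longest and
#' shortest bouts. Participants without any retained bout are listed with
#' zeros.
#'
#' @param bouts_by_participant Named list: one list of `walking_bout`s per
#'   participant.
#'
#' @return A data frame with columns `participant`, `walking_bouts`,
#'   `total_strides`, `longest_bout`, `shortest_bout`.
#' @export
bout_frequency_table <- function(bouts_by_participant) {
  if (length(bouts_by_participant) == 0)
    stop("at least one participant is required")
  ids <- names(bouts_by_participant) %||%
    as.character(seq_along(bouts_by_participant))
  rows <- lapply(seq_along(bouts_by_participant), function(i) {
    bouts <- bouts_by_participant[[i]]
    ns <- vapply(bouts, function(b) b$n_strides, integer(1))
    data.frame(participant = ids[i],
               walking_bouts = length(bouts),
               total_strides = if (length(ns)) sum(ns) else 0L,
               longest_bout = if (length(ns)) max(ns) else 0L,
               shortest_bout = if (length(ns)) min(ns) else 0L)
  })
  do.call(rbind, rows)
}
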