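# End-to-end orchestration: preprocessing -> detection -> segmentation ->
# measures, over one or many recordings.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its standard default:
#' 100 Hz resampling; 16 Hz / order-4 causal low-pass; orientation
#' inversion on; 0.1 Hz drift high-pass; wavelet scale 12; 0.8 s candidate
#' separation with a 40% threshold fraction; 3-frame raw relocation
#' offset; 1.8 s bout gap; bouts of more than 24 strides trimmed by 2 at
#' each end and retained at 20+; DFA boxes 10-40; entropy m = 2,
#' r = 0.15 SD; multiscale entropy scales 1-4 on 800-stride series; 100
#' reshapings and 100 permutation surrogates up to separation 100.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fs = 100, lowpass_cutoff_hz = 16, filter_order = 4, invert = TRUE,
    vertical_axis = "az",
    highpass_cutoff_hz = 0.1, cwt_scale = 12, min_separation_s = 0.8,
    threshold_fraction = 0.4, offset_frames = 3,
    gap_s = 1.8, min_raw_strides = 24, trim_strides = 2, min_strides = 20,
    dfa_box_min = 10, dfa_box_max = 40,
    entropy_m = 2, entropy_r_fraction = 0.15,
    mse_scales = 1:4, mse_required_strides = 800,
    linear_min_strides = 20, nonlinear_min_strides = 256,
    n_surrogates = 100, max_separation = 100,
    enhl_direction = "loss", compute_decay = TRUE,
    seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys present in the file override the defaults of [pipeline_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

measure_names <- c("xisi", "sd", "cov", "fsi", "apen", "saen",
                   "mse_scale_1", "mse_scale_2", "mse_scale_3",
                   "mse_scale_4", "ci", "spd", "enhl")

empty_measures <- function() {
  out <- as.list(rep(NA_real_, length(measure_names)))
  names(out) <- measure_names
  out
}

#' Compute the full measure set for one participant
#'
#' Applies the bout-length eligibility rules: linear measures (mean stride
#' time, SD, COV) are computed on every filtered-stream bout with at least
#' 20 strides and averaged within the participant; the fractal scaling
#' index and approximate/sample entropy are computed on every raw-stream
#' bout with more than 255 strides and averaged; multiscale entropy (with
#' its complexity index), statistical persistence decay and entropic
#' half-life use exactly the first `mse_required_strides` strides of the
#' longest raw-stream bout, and are unavailable when no bout is long
#' enough. Ineligible measures are `NA` with the reason recorded.
#'
#' @param bouts_filtered,bouts_raw Lists of `walking_bout`s from the
#'   filtered and raw streams.
#' @param config A [pipeline_config()].
#' @param seed Seed for the surrogate permutations (defaults to
#'   `config$seed`).
#'
#' @return An object of class `gait_measures`: list with `measures` (named
#'   numeric list), `eligibility` (named reasons for unavailable
#'   measures), and bout provenance counts.
#' @export
participant_measures <- function(bouts_filtered, bouts_raw,
                                 config = pipeline_config(), seed = NULL) {
  seed <- seed %||% config$seed
  meas <- empty_measures()
  elig <- list()

  lin_bouts <- Filter(function(b) b$n_strides >= config$linear_min_strides,
                      bouts_filtered)
  if (length(lin_bouts)) {
    lm_list <- lapply(lin_bouts, linear_measures,
                      min_strides = config$linear_min_strides)
    meas$xisi <- mean(vapply(lm_list, `[[`, numeric(1), "xisi"))
    meas$sd <- mean(vapply(lm_list, `[[`, numeric(1), "sd"))
    meas$cov <- mean(vapply(lm_list, `[[`, numeric(1), "cov"))
  } else {
    elig[c("xisi", "sd", "cov")] <-
      sprintf("no bout with >= %d strides", config$linear_min_strides)
  }

  long_bouts <- Filter(function(b) b$n_strides >= config$nonlinear_min_strides,
                       bouts_raw)
  if (length(long_bouts)) {
    fsi_v <- vapply(long_bouts, function(b)
      dfa(b$isi, config$dfa_box_min, config$dfa_box_max)$alpha, numeric(1))
    ap_v <- vapply(long_bouts, function(b)
      apen(b$isi, m = config$entropy_m,
           r_fraction = config$entropy_r_fraction), numeric(1))
    sa_v <- vapply(long_bouts, function(b)
      saen(b$isi, m = config$entropy_m,
           r_fraction = config$entropy_r_fraction), numeric(1))
    meas$fsi <- mean(fsi_v)
    meas$apen <- mean(ap_v)
    meas$saen <- mean(sa_v, na.rm = TRUE)
  } else {
    elig[c("fsi", "apen", "saen")] <-
      sprintf("no bout with > %d strides", config$nonlinear_min_strides - 1L)
  }

  need <- config$mse_required_strides
  raw_lens <- vapply(bouts_raw, function(b) b$n_strides, integer(1))
  decay_names <- c(paste0("mse_scale_", config$mse_scales), "ci", "spd", "enhl")
  if (length(raw_lens) && max(raw_lens) >= need) {
    longest <- bouts_raw[[which.max(raw_lens)]]
    series <- longest$isi[seq_len(need)]
    mse_df <- mse(series, scales = config$mse_scales, m = config$entropy_m,
                  r_fraction = config$entropy_r_fraction)
    for (i in seq_len(nrow(mse_df)))
      meas[[paste0("mse_scale_", mse_df$scale[i])]] <- mse_df$saen[i]
    meas$ci <- tryCatch(complexity_index(mse_df), error = function(e) {
      elig$ci <<- conditionMessage(e); NA_real_ })
    if (isTRUE(config$compute_decay)) {
      surr <- random_surrogates(
        series, n_surrogates = config$n_surrogates, seed = seed,
        box_min = config$dfa_box_min, box_max = config$dfa_box_max,
        m = config$entropy_m, r_fraction = config$entropy_r_fraction)
      meas$spd <- as.integer(spd(series, surr, max_s = config$max_separation,
                                 box_min = config$dfa_box_min,
                                 box_max = config$dfa_box_max))
      meas$enhl <- as.integer(enhl(series, surr, m = config$entropy_m,
                                   r_fraction = config$entropy_r_fraction,
                                   max_s = config$max_separation,
                                   direction = config$enhl_direction))
    } else {
      elig[c("spd", "enhl")] <- "decay measures disabled in configuration"
    }
  } else {
    elig[decay_names] <- sprintf("longest bout shorter than %d strides", need)
  }

  structure(list(measures = meas, eligibility = elig,
                 n_bouts_filtered = length(bouts_filtered),
                 n_bouts_raw = length(bouts_raw)),
            class = "gait_measures")
}

#' @export
print.gait_measures <- function(x, ...) {
  cat("<gait_measures>\n")
  for (nm in names(x$measures)) {
    v <- x$measures[[nm]]
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(v)) paste0("NA (", x$eligibility[[nm]] %||% "NA", ")")
                else format(signif(v, 5))))
  }
  invisible(x)
}

#' Run the full pipeline over one or many recordings
#'
#' For each recording: preprocess into raw and filtered streams, detect
#' heel contacts, segment both event streams into walking bouts (linear
#' measures consume the filtered-stream bouts, nonlinear measures the
#' raw-stream bouts), and compute the participant's measure set. A stage
#' failure marks the participant as failed and is reported in the warnings
#' log rather than aborting the batch. Given the same configuration and
#' seed, the report is identical across runs; per-participant surrogate
#' seeds are derived as `config$seed + participant index`.
#'
#' @param recordings Named list of [accel_recording] objects,
#'   `synthetic_recording` objects, or file paths readable by
#'   [read_recording()].
#' @param config A [pipeline_config()].
#'
#' @return An object of class `run_report`: list with `measures` (data
#'   frame, one row per participant), `frequency` (bout frequency table),
#'   `details` (per-participant `gait_measures`), `bouts` (per-participant
#'   bout lists by stream), `warnings` (character log) and `config`.
#' @export
run_pipeline <- function(recordings, config = pipeline_config()) {
  if (length(recordings) == 0) stop("at least one recording is required")
  ids <- names(recordings) %||% paste0("P", seq_along(recordings))
  ids[ids == ""] <- paste0("P", which(ids == ""))
  details <- list()
  bouts_all <- list()
  warn_log <- character(0)
  for (i in seq_along(recordings)) {
    id <- ids[i]
    res <- tryCatch({
      rec <- recordings[[i]]
      if (is.character(rec))
        rec <- read_recording(rec, vertical_axis = config$vertical_axis,
                              fs_nominal = config$fs, participant_id = id)
      if (inherits(rec, "synthetic_recording")) rec <- rec$accel
      withCallingHandlers({
        streams <- preprocess_recording(
          rec, fs = config$fs, invert = config$invert,
          cutoff = config$lowpass_cutoff_hz, order = config$filter_order)
        ev <- detect_heel_contacts(
          streams, highpass_cutoff = config$highpass_cutoff_hz,
          cwt_scale = config$cwt_scale,
          min_separation = config$min_separation_s,
          threshold_fraction = config$threshold_fraction,
          offset_frames = config$offset_frames)
        seg <- function(e) segment_bouts(
          e, gap_s = config$gap_s, min_raw_strides = config$min_raw_strides,
          trim = config$trim_strides, min_strides = config$min_strides,
          participant_id = id)
        bouts <- list(filtered = seg(ev$filtered), raw = seg(ev$raw))
        pm <- participant_measures(bouts$filtered, bouts$raw, config,
                                   seed = config$seed + i)
        list(pm = pm, bouts = bouts)
      }, warning = function(w) {
        warn_log <<- c(warn_log, paste0(id, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    }, error = function(e) {
      warn_log <<- c(warn_log, paste0(id, " FAILED: ", conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      details[[id]] <- structure(
        list(measures = empty_measures(),
             eligibility = as.list(stats::setNames(
               rep("stage failure", length(measure_names)), measure_names)),
             n_bouts_filtered = 0L, n_bouts_raw = 0L),
        class = "gait_measures")
      bouts_all[[id]] <- list(filtered = list(), raw = list())
    } else {
      details[[id]] <- res$pm
      bouts_all[[id]] <- res$bouts
    }
  }
  measures_df <- do.call(rbind, lapply(ids, function(id) {
    cbind(data.frame(participant = id),
          as.data.frame(details[[id]]$measures))
  }))
  freq <- bout_frequency_table(lapply(bouts_all, `[[`, "raw"))
  structure(list(measures = measures_df, frequency = freq,
                 details = details, bouts = bouts_all,
                 warnings = warn_log, config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d participant(s), %d warning(s)\n",
              nrow(x$measures), length(x$warnings)))
  print(x$measures)
  invisible(x)
}

#' Descriptive group summary
#'
#' Mean and SD of each measure per group, plus the between-group
#' difference of means. The difference is reported as the first group
#' level minus the second (for an older-versus-young comparison with
#' groups ordered `c("OA", "YA")`, the difference column is OA - YA).
#'
#' @param report A `run_report`, or its `measures` data frame.
#' @param groups Named character vector or factor mapping participant ids
#'   to exactly two group labels.
#'
#' @return A data frame with one row per measure: group means and SDs and
#'   the difference of means.
#' @export
group_summary <- function(report, groups) {
  df <- if (inherits(report, "run_report")) report$measures else report
  g <- groups[df$participant]
  if (anyNA(g)) stop("unknown group label for participant(s): ",
                     paste(df$participant[is.na(g)], collapse = ", "))
  lev <- if (is.factor(groups)) levels(groups) else unique(unname(groups))
  if (length(lev) != 2) stop("exactly two groups are required")
  rows <- lapply(measure_names, function(nm) {
    v1 <- df[[nm]][g == lev[1]]
    v2 <- df[[nm]][g == lev[2]]
    data.frame(measure = nm,
               mean_1 = mean(v1, na.rm = TRUE), sd_1 = sd(v1[!is.na(v1)]),
               mean_2 = mean(v2, na.rm = TRUE), sd_2 = sd(v2[!is.na(v2)]),
               difference = mean(v1, na.rm = TRUE) - mean(v2, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  names(out) <- c("measure",
                  paste0(c("mean_", "sd_"), lev[1]),
                  paste0(c("mean_", "sd_"), lev[2]), "difference")
  out
}
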