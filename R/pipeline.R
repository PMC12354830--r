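# End-to-end orchestration: mains cancellation -> segmentation ->
# spectrogram -> CNN detection -> pYIN + WBF filter -> event aggregation ->
# biomass lookup -> per-period sums.

#' Default pipeline configuration
#'
#' All stage parameters in one nested list; [read_pipeline_config()] merges
#' a YAML file over these defaults.
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    powerline = list(freqs = c(50, 60), margin = 2, q = 30, nchunks = 4),
    detector = list(threshold = 0.5, checkpoint = NULL),
    wbf = list(fmin = 20, fmax = 2000, frame_length = 512, hop = 256,
               min_mu = 20, min_sigma = 1, max_ratio = 0.8,
               ratio_as_printed = FALSE, combine_and = FALSE),
    events = list(iou_threshold = 0.1, bc_threshold = 0.7,
                  bc_as_printed = FALSE, sigma_as_printed = FALSE),
    biomass = list(table = NULL, fallback_dense_median = FALSE),
    daytime = list(enabled = FALSE, start_hour = 3, end_hour = 22),
    seed = 1L
  )
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file; keys override [default_pipeline_config()].
#' @return merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, override) {
    for (nm in names(override)) {
      if (is.list(base[[nm]]) && is.list(override[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
      } else {
        base[[nm]] <- override[[nm]]
      }
    }
    base
  }
  merge_lists(default_pipeline_config(), user)
}

#' Process one recording into insect events
#'
#' Stage order: power-line detect/cancel, 1-s segmentation, spectrogram,
#' CNN classification, pYIN WBF estimation with the discard filter, and
#' IoU/Bhattacharyya aggregation. Stage counts are attached so a run can
#' be audited (segments >= detector-positive >= WBF-kept >= covered by
#' events).
#'
#' @param rec a [recording] (must be 4 kHz).
#' @param model a trained `insect_detector`.
#' @param config pipeline configuration (see
#'   [default_pipeline_config()]).
#' @return list with `events` (data frame), `stage_counts` (named list)
#'   and `powerline` (the detection report).
#' @export
process_recording <- function(rec, model, config = default_pipeline_config()) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs != 4000) {
    stop("pipeline requires 4 kHz recordings, got ", rec$fs, " Hz",
         call. = FALSE)
  }
  pl <- NULL
  if (length(rec$samples) >= config$powerline$nchunks * rec$fs) {
    pl <- detect_powerline(rec, candidate_freqs = config$powerline$freqs,
                           nchunks = config$powerline$nchunks,
                           margin = config$powerline$margin)
    if (pl$detected) {
      rec <- comb_cancel(rec, pl$mains_hz, q = config$powerline$q)
    }
  }
  segs <- segment_signal(rec)
  n_segments <- length(segs)
  events <- data.frame(event_id = integer(), start_s = numeric(),
                       end_s = numeric(), n_segments = integer(),
                       mu_f0 = numeric(), sigma_f0 = numeric(),
                       n_voiced = integer())
  n_pos <- 0L; n_kept <- 0L
  if (n_segments > 0) {
    specs <- lapply(segs, function(s) unclass(spectrogram(s)))
    probs <- predict_prob(model, specs)
    pos <- which(probs >= config$detector$threshold)
    n_pos <- length(pos)
    kept <- list()
    for (i in pos) {
      w <- estimate_f0(segs[[i]], fmin = config$wbf$fmin,
                       fmax = config$wbf$fmax,
                       frame_length = config$wbf$frame_length,
                       hop = config$wbf$hop)
      ok <- passes_wbf_filter(w, min_mu = config$wbf$min_mu,
                              min_sigma = config$wbf$min_sigma,
                              max_ratio = config$wbf$max_ratio,
                              ratio_as_printed = config$wbf$ratio_as_printed,
                              combine_and = config$wbf$combine_and)
      if (ok) kept[[length(kept) + 1L]] <- w
    }
    n_kept <- length(kept)
    events <- aggregate_segments(
      kept, iou_threshold = config$events$iou_threshold,
      bc_threshold = config$events$bc_threshold,
      bc_as_printed = config$events$bc_as_printed,
      sigma_as_printed = config$events$sigma_as_printed)
  }
  if (nrow(events) > 0) {
    events$recording_id <- paste0(rec$sensor_id, "_",
                                  format(rec$start_time, "%Y%m%dT%H%M%S",
                                         tz = "UTC"))
  } else {
    events$recording_id <- character(0)
  }
  list(events = events,
       stage_counts = list(segments = n_segments,
                           detector_positive = n_pos,
                           wbf_kept = n_kept,
                           events = nrow(events)),
       powerline = pl)
}

#' Run the full pipeline over recordings
#'
#' @param recordings list of [recording]s, or character paths to WAV
#'   files.
#' @param model trained `insect_detector` (or a checkpoint path).
#' @param table a [load_reference_table()] result (or a CSV path); NULL
#'   skips biomass.
#' @param periods optional data frame `period_id`, `start`, `end`
#'   (POSIXct or ISO strings) for trapping-period aggregation.
#' @param config pipeline configuration.
#' @return list with `events` (all recordings, with `mass_mg` when a
#'   table is given), `periods` (aggregates or NULL), `stage_counts`
#'   (per recording).
#' @export
run_pipeline <- function(recordings, model, table = NULL, periods = NULL,
                         config = default_pipeline_config()) {
  if (is.character(model)) model <- load_detector(model)
  if (!is.null(table) && !inherits(table, "reference_table")) {
    table <- load_reference_table(table)
  }
  if (is.character(recordings)) {
    recordings <- lapply(recordings, read_recording)
  }
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  if (!is.null(periods)) {
    if (is.character(periods$start)) periods$start <- parse_iso8601(periods$start)
    if (is.character(periods$end)) periods$end <- parse_iso8601(periods$end)
  }
  all_events <- list()
  counts <- list()
  starts <- list()
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    if (isTRUE(config$daytime$enabled)) {
      hr <- as.numeric(format(rec$start_time, "%H", tz = "UTC")) +
        as.numeric(format(rec$start_time, "%M", tz = "UTC")) / 60
      if (hr < config$daytime$start_hour || hr >= config$daytime$end_hour) {
        next
      }
    }
    out <- tryCatch(process_recording(rec, model, config),
                    error = function(e) {
                      warning("recording ", ri, " skipped: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(out)) next
    ev <- out$events
    if (!is.null(table) && nrow(ev) > 0) {
      est <- lapply(seq_len(nrow(ev)), function(i) {
        estimate_mass(ev$mu_f0[i], ev$sigma_f0[i], table,
                      fallback_dense_median =
                        config$biomass$fallback_dense_median)
      })
      ev$mass_mg <- vapply(est, `[[`, numeric(1), "mass_mg")
      ev$region <- vapply(est, `[[`, character(1), "region")
      ev$method <- vapply(est, `[[`, character(1), "method")
    }
    if (nrow(ev) > 0) {
      ev$recording_start <- rec$start_time
      all_events[[length(all_events) + 1L]] <- ev
    }
    counts[[length(counts) + 1L]] <- c(list(recording = ri),
                                       out$stage_counts)
    starts[[length(starts) + 1L]] <- rec$start_time
  }
  events <- if (length(all_events) > 0) do.call(rbind, all_events) else
    data.frame(event_id = integer(), start_s = numeric(), end_s = numeric(),
               n_segments = integer(), mu_f0 = numeric(),
               sigma_f0 = numeric(), n_voiced = integer(),
               recording_id = character())
  period_out <- NULL
  if (!is.null(periods) && nrow(events) > 0) {
    # absolute event times: recording start + offset
    abs_events <- events
    abs_events$start_s <- as.numeric(difftime(events$recording_start,
                                              min(events$recording_start),
                                              units = "secs")) +
      events$start_s
    period_out <- aggregate_period(abs_events, periods,
                                   min(events$recording_start))
  } else if (!is.null(periods)) {
    period_out <- aggregate_period(events, periods, Sys.time())
  }
  list(events = events, periods = period_out,
       stage_counts = do.call(rbind, lapply(counts, as.data.frame)))
}
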