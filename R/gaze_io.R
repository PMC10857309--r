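# Data model and CSV I/O for gaze recordings, event logs and analysis config.
#
# Gaze CSV dialect: comma separated, UTF-8, "." decimal separator, mandatory
# header  t,left_x,left_y,right_x,right_y,valid_left,valid_right.
# Event CSV header:
#   trial_index,condition,mask_onset,stimulus_onset,mask_duration,
#   stimulus_duration,stimulus_string.
# Times are milliseconds everywhere; validity code 0 = valid, any non-zero
# integer = invalid (the tracker's convention).

GAZE_COLUMNS  <- c("t", "left_x", "left_y", "right_x", "right_y",
                   "valid_left", "valid_right")
EVENT_COLUMNS <- c("trial_index", "condition", "mask_onset", "stimulus_onset",
                   "mask_duration", "stimulus_duration", "stimulus_string")
CONDITIONS <- c("target", "distractor")

#' Construct a binocular gaze recording
#'
#' A gaze recording is an ordered sequence of timestamped binocular samples:
#' per-eye on-screen coordinates in pixels plus per-eye integer validity
#' codes (0 = valid pupil/iris detection; any non-zero code marks the sample
#' invalid). Coordinates may lie outside the screen bounds (trackers report
#' overshoot) but must be finite wherever the corresponding validity code
#' is 0.
#'
#' @param subject_id,tracker_id Identifiers (e.g. tracker `"WC"` for a
#'   webcam-like device, `"ET"` for an infrared-like one).
#' @param nominal_rate Nominal sampling rate in Hz.
#' @param samples A data.frame with columns
#'   `t, left_x, left_y, right_x, right_y, valid_left, valid_right`;
#'   `t` in ms since recording start, strictly increasing.
#' @return An object of class `"gaze_recording"`.
#' @export
gaze_recording <- function(subject_id, tracker_id, nominal_rate, samples) {
  stopifnot_scalar_number(nominal_rate, "nominal_rate")
  if (nominal_rate <= 0) param_error("'nominal_rate' must be > 0")
  missing <- setdiff(GAZE_COLUMNS, names(samples))
  if (length(missing))
    format_error("gaze samples missing column(s): %s",
                 paste(missing, collapse = ", "))
  samples <- as.data.frame(samples)[GAZE_COLUMNS]
  if (nrow(samples)) {
    if (any(!is.finite(samples$t)) || any(samples$t < 0))
      data_error("sample times must be finite and non-negative")
    d <- diff(samples$t)
    if (length(d) && any(d <= 0))
      data_error("sample timestamps not strictly increasing at row %d",
                 which(d <= 0)[1] + 1L)
    for (v in c("valid_left", "valid_right")) {
      if (any(!is.finite(samples[[v]])) || any(samples[[v]] < 0) ||
          any(samples[[v]] != round(samples[[v]])))
        data_error("'%s' must contain non-negative integer codes", v)
    }
    ok <- samples$valid_left == 0 & samples$valid_right == 0
    coord <- as.matrix(samples[c("left_x", "left_y", "right_x", "right_y")])
    if (any(!is.finite(coord[ok, , drop = FALSE])))
      data_error("non-finite coordinates in samples marked valid")
  }
  structure(list(subject_id = as.character(subject_id),
                 tracker_id = as.character(tracker_id),
                 nominal_rate = nominal_rate,
                 samples = samples),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("Gaze recording: subject %s, tracker %s, %g Hz, %d samples",
              x$subject_id, x$tracker_id, x$nominal_rate, n))
  if (n) cat(sprintf(" (%.0f-%.0f ms)", min(x$samples$t), max(x$samples$t)))
  cat("\n")
  invisible(x)
}

#' Read a binocular gaze CSV
#'
#' Reads the documented gaze CSV dialect (see [write_gaze_csv()]). Samples
#' are returned in time order; strictly decreasing or duplicated timestamps
#' raise a data error naming the first offending row. Rows whose coordinates
#' are non-numeric despite a validity code of 0 are contradictory
#' tracker output and are dropped with a warning.
#'
#' @param path Path to the CSV file.
#' @param tracker_id Identifier to attach to the recording.
#' @param subject_id Subject identifier (default: file name stem).
#' @param nominal_rate Nominal sampling rate in Hz.
#' @return A [gaze_recording()].
#' @export
read_gaze_csv <- function(path, tracker_id, subject_id = NULL,
                          nominal_rate = 30) {
  if (!file.exists(path)) input_error("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(GAZE_COLUMNS, names(df))
  if (length(missing))
    format_error("gaze CSV %s missing column(s): %s", path,
                 paste(missing, collapse = ", "))
  for (nm in GAZE_COLUMNS) df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  coord_bad <- !stats::complete.cases(
    df[c("left_x", "left_y", "right_x", "right_y")])
  valid <- df$valid_left == 0 & df$valid_right == 0
  reject <- coord_bad & valid & !is.na(valid)
  if (any(reject)) {
    warning(sprintf("%s: dropping %d row(s) with non-numeric coordinates but validity 0",
                    path, sum(reject)))
    df <- df[!reject, , drop = FALSE]
  }
  gaze_recording(subject_id %||% sub("\\.[^.]*$", "", basename(path)),
                 tracker_id, nominal_rate, df)
}

#' Write a binocular gaze CSV
#'
#' Writes a recording in the dialect read by [read_gaze_csv()]; numeric
#' values keep full double precision, so a write/read round trip is exact
#' for validity codes and accurate to well below 1e-6 for coordinates.
#'
#' @param recording A [gaze_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(recording, path) {
  if (!inherits(recording, "gaze_recording"))
    input_error("'recording' must be a gaze_recording")
  utils::write.csv(recording$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an oddball event log
#'
#' One row per trial of the session: a 1-based contiguous `trial_index`, the
#' `condition` (`"target"` or `"distractor"`), the mask and stimulus onsets
#' and durations in ms (with `stimulus_onset = mask_onset + mask_duration`),
#' and the presented character string. All stimulus strings in a session
#' share one length.
#'
#' @param trials A data.frame with the event-log columns.
#' @return An object of classes `"event_log"` and `"data.frame"`.
#' @export
event_log <- function(trials) {
  trials <- as.data.frame(trials)
  missing <- setdiff(EVENT_COLUMNS, names(trials))
  if (length(missing))
    format_error("event log missing column(s): %s",
                 paste(missing, collapse = ", "))
  trials <- trials[EVENT_COLUMNS]
  trials$condition <- tolower(as.character(trials$condition))
  bad <- !(trials$condition %in% CONDITIONS)
  if (any(bad))
    format_error("unknown condition label '%s' at trial %d",
                 trials$condition[bad][1], which(bad)[1])
  n <- nrow(trials)
  if (!identical(as.integer(trials$trial_index), seq_len(n)))
    data_error("trial_index must be contiguous 1..%d", n)
  trials$trial_index <- as.integer(trials$trial_index)
  if (n && any(abs(trials$stimulus_onset -
                   (trials$mask_onset + trials$mask_duration)) > 1e-6))
    data_error("stimulus_onset must equal mask_onset + mask_duration")
  if (n && length(unique(nchar(as.character(trials$stimulus_string)))) > 1L)
    data_error("stimulus_string length must be fixed within a session")
  trials$stimulus_string <- as.character(trials$stimulus_string)
  class(trials) <- c("event_log", "data.frame")
  trials
}

#' Read an oddball event log CSV
#'
#' Condition labels are normalized to lower case; unknown labels raise a
#' format error and gaps in `trial_index` a data error. Trials are never
#' reordered.
#'
#' @param path Path to the CSV file.
#' @return An [event_log()].
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) input_error("file not found: %s", path)
  event_log(utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = list(stimulus_string = "character")))
}

#' Write an oddball event log CSV
#' @param events An [event_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  if (!inherits(events, "event_log")) input_error("'events' must be an event_log")
  utils::write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Collects every tunable of the analysis: viewing geometry, response
#' windows, the epoch extracted around each stimulus onset, the
#' normalization window of the relative modulation V(t), the invalid-sample
#' exclusion threshold, and the t-test variant for unpaired comparisons.
#'
#' @param geometry A [geometry_config()].
#' @param windows A [window_definition()].
#' @param epoch_window Length-2 numeric, epoch bounds in ms relative to
#'   stimulus onset (default `c(-200, 2000)`).
#' @param norm_window Length-2 numeric, window (ms post-onset) over which
#'   `max |gamma(t) - gamma0|` normalizes each trial (default `c(0, 2000)`).
#' @param exclusion_threshold Trials with at least this many invalid samples
#'   in the epoch are discarded (default 15).
#' @param t_test `"welch"` (default) or `"student"` for unpaired comparisons.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(geometry = geometry_config(),
                            windows = window_definition(),
                            epoch_window = c(-200, 2000),
                            norm_window = c(0, 2000),
                            exclusion_threshold = 15,
                            t_test = c("welch", "student")) {
  t_test <- match.arg(t_test)
  if (!inherits(geometry, "geometry_config")) geometry <- do.call(geometry_config, geometry)
  if (!inherits(windows, "window_definition")) windows <- do.call(window_definition, windows)
  if (length(epoch_window) != 2 || epoch_window[1] >= epoch_window[2])
    param_error("'epoch_window' must be (start, end) with start < end")
  if (length(norm_window) != 2 || norm_window[1] >= norm_window[2])
    param_error("'norm_window' must be (start, end) with start < end")
  for (w in windows) {
    if (w[1] < epoch_window[1] || w[2] > epoch_window[2])
      param_error("analysis windows must lie inside the epoch window")
  }
  if (norm_window[1] < epoch_window[1] || norm_window[2] > epoch_window[2])
    param_error("'norm_window' must lie inside the epoch window")
  stopifnot_scalar_number(exclusion_threshold, "exclusion_threshold")
  structure(list(geometry = geometry, windows = windows,
                 epoch_window = as.numeric(epoch_window),
                 norm_window = as.numeric(norm_window),
                 exclusion_threshold = exclusion_threshold,
                 t_test = t_test),
            class = "analysis_config")
}

#' Read/write the analysis configuration as YAML
#'
#' The file mirrors [analysis_config()]: top-level keys `geometry`,
#' `windows`, `epoch_window`, `norm_window`, `exclusion_threshold`,
#' `t_test`; missing keys take the defaults.
#'
#' @param path Path to a YAML file.
#' @return For `read_analysis_config`, an [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) input_error("file not found: %s", path)
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$geometry)) args$geometry <- do.call(geometry_config, raw$geometry)
  if (!is.null(raw$windows))
    args$windows <- do.call(window_definition, lapply(raw$windows, unlist))
  for (k in c("epoch_window", "norm_window"))
    if (!is.null(raw[[k]])) args[[k]] <- unlist(raw[[k]])
  for (k in c("exclusion_threshold", "t_test"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  do.call(analysis_config, args)
}

#' @rdname read_analysis_config
#' @param config An [analysis_config()].
#' @export
write_analysis_config <- function(config, path) {
  if (!inherits(config, "analysis_config"))
    input_error("'config' must be an analysis_config")
  out <- list(geometry = unclass(config$geometry),
              windows = lapply(unclass(config$windows), as.numeric),
              epoch_window = config$epoch_window,
              norm_window = config$norm_window,
              exclusion_threshold = config$exclusion_threshold,
              t_test = config$t_test)
  yaml::write_yaml(out, path)
  invisible(path)
}
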