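# Trial segmentation, validity-based exclusion, and interpolation onto a
# uniform per-trial grid.

#' Cut a recording into per-trial sample slices
#'
#' Each trial's slice holds the raw samples with
#' `stimulus_onset + start <= t < stimulus_onset + end` (half-open, so at
#' 30 Hz a (0, 2000) ms window yields 60 samples). A trial whose window
#' extends past the end of the recording is flagged `truncated`; a trial
#' with no samples at all is flagged `excluded` with reason `"no data"`.
#'
#' @param recording A [gaze_recording()].
#' @param events An [event_log()].
#' @param epoch_window Length-2 numeric `(start, end)` in ms relative to
#'   stimulus onset.
#' @return A list with one element per trial:
#'   `trial_index`, `condition`, `stimulus_onset`, `samples` (data.frame),
#'   `truncated`, `excluded`, `reason`.
#' @export
segment_trials <- function(recording, events, epoch_window = c(-200, 2000)) {
  if (epoch_window[1] >= epoch_window[2])
    param_error("'epoch_window' must satisfy start < end")
  t <- recording$samples$t
  t_end <- if (length(t)) max(t) else -Inf
  lapply(seq_len(nrow(events)), function(i) {
    onset <- events$stimulus_onset[i]
    lo <- onset + epoch_window[1]
    hi <- onset + epoch_window[2]
    keep <- t >= lo & t < hi
    sl <- recording$samples[keep, , drop = FALSE]
    empty <- nrow(sl) == 0L
    list(trial_index = events$trial_index[i],
         condition = events$condition[i],
         stimulus_onset = onset,
         samples = sl,
         truncated = hi > t_end,
         excluded = empty,
         reason = if (empty) "no data" else NA_character_)
  })
}

#' Count invalid samples in a trial slice
#'
#' A sample is invalid if either eye's validity code is non-zero: the
#' vergence angle needs both eyes, so the count is the union (a sample
#' invalid in both eyes counts once).
#'
#' @param slice A slice from [segment_trials()] or a samples data.frame.
#' @return Integer count of invalid samples.
#' @export
count_invalid <- function(slice) {
  s <- if (is.data.frame(slice)) slice else slice$samples
  sum(s$valid_left != 0 | s$valid_right != 0)
}

#' Exclusion rule for trials with too many invalid samples
#'
#' A trial is discarded when its number of invalid samples reaches the
#' threshold: 14 invalid points retain the trial, 15 discard it (with the
#' default threshold).
#'
#' @param n_invalid Non-negative integer count (vectorised).
#' @param threshold Minimum invalid count that discards (default 15).
#' @return Logical: `TRUE` = discard.
#' @export
exclude_trial <- function(n_invalid, threshold = 15) {
  if (any(n_invalid < 0)) param_error("'n_invalid' must be >= 0")
  n_invalid >= threshold
}

#' Interpolate a trial slice onto an evenly spaced grid
#'
#' Invalid samples are removed, then each coordinate channel is linearly
#' interpolated onto the grid `k * (1000/rate)` ms for all integers `k`
#' with the grid point inside `epoch_window` (so t = 0, stimulus onset, is
#' always a grid point). Grid points outside the span of the valid
#' timestamps take the nearest valid value — ends are clamped, never
#' extrapolated.
#'
#' @param slice A slice from [segment_trials()].
#' @param rate Grid rate in Hz.
#' @param epoch_window Length-2 numeric `(start, end)` ms relative to onset.
#' @return A data.frame with columns `t_rel, left_x, left_y, right_x,
#'   right_y`, or `NULL` if fewer than 2 valid samples remain (reason
#'   `"insufficient data"`).
#' @export
interpolate_uniform <- function(slice, rate, epoch_window = c(-200, 2000)) {
  s <- slice$samples
  ok <- s$valid_left == 0 & s$valid_right == 0
  s <- s[ok, , drop = FALSE]
  if (nrow(s) < 2L) return(NULL)
  step <- 1000 / rate
  kmin <- ceiling(epoch_window[1] / step - 1e-9)
  kmax <- floor(epoch_window[2] / step + 1e-9)
  t_rel <- (kmin:kmax) * step
  t_obs <- s$t - slice$stimulus_onset
  out <- data.frame(t_rel = t_rel)
  for (ch in c("left_x", "left_y", "right_x", "right_y"))
    out[[ch]] <- stats::approx(t_obs, s[[ch]], xout = t_rel, rule = 2,
                               ties = "ordered")$y
  out
}

#' Build per-trial vergence epochs from a recording and its event log
#'
#' Runs the full preprocessing chain: segmentation, invalid-sample
#' counting, the exclusion rule, interpolation onto the uniform grid, and
#' the pixel-to-vergence-angle transform. Webcam-style recordings whose
#' validity codes are all 0 pass the exclusion rule untouched.
#'
#' @param recording A [gaze_recording()].
#' @param events An [event_log()].
#' @param geometry A [geometry_config()].
#' @param epoch_window Length-2 numeric `(start, end)` ms relative to onset.
#' @param threshold Invalid-sample exclusion threshold (default 15).
#' @param rate Grid rate in Hz; defaults to the recording's nominal rate.
#' @return A list of `"trial_epoch"` objects with fields `subject_id`,
#'   `tracker_id`, `trial_index`, `condition`, `t_rel`, `gamma` (vergence
#'   angle, deg; `NULL` for excluded trials), `n_invalid`, `excluded`,
#'   `reason`.
#' @export
epoch_trials <- function(recording, events, geometry = geometry_config(),
                         epoch_window = c(-200, 2000), threshold = 15,
                         rate = NULL) {
  rate <- rate %||% recording$nominal_rate
  slices <- segment_trials(recording, events, epoch_window)
  lapply(slices, function(sl) {
    n_inv <- count_invalid(sl)
    ep <- list(subject_id = recording$subject_id,
               tracker_id = recording$tracker_id,
               trial_index = sl$trial_index,
               condition = sl$condition,
               t_rel = NULL, gamma = NULL,
               n_invalid = n_inv,
               excluded = sl$excluded,
               reason = sl$reason)
    if (!ep$excluded && exclude_trial(n_inv, threshold)) {
      ep$excluded <- TRUE
      ep$reason <- "too many invalid samples"
    }
    if (!ep$excluded) {
      grid <- interpolate_uniform(sl, rate, epoch_window)
      if (is.null(grid)) {
        ep$excluded <- TRUE
        ep$reason <- "insufficient data"
      } else {
        ep$t_rel <- grid$t_rel
        ep$gamma <- gamma_from_px(grid$left_x, grid$right_x, geometry)
      }
    }
    class(ep) <- "trial_epoch"
    ep
  })
}

#' Fraction of excluded trials
#'
#' @param epochs A list of trial epochs from [epoch_trials()].
#' @return Excluded count / total, in `[0, 1]`.
#' @export
exclusion_rate <- function(epochs) {
  if (!length(epochs)) input_error("'epochs' must be non-empty")
  mean(vapply(epochs, function(e) isTRUE(e$excluded), logical(1)))
}

#' Per-trial quality-control table
#'
#' @param epochs A list of trial epochs from [epoch_trials()].
#' @return A data.frame: subject, tracker, trial, condition, n_invalid,
#'   excluded, reason.
#' @export
qc_table <- function(epochs) {
  do.call(rbind, lapply(epochs, function(e) {
    data.frame(subject = e$subject_id, tracker = e$tracker_id,
               trial = e$trial_index, condition = e$condition,
               n_invalid = e$n_invalid, excluded = e$excluded,
               reason = ifelse(is.na(e$reason), "", e$reason),
               stringsAsFactors = FALSE)
  }))
}
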