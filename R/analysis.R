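# The fitting-style entry point: from recordings + event logs to curves,
# windowed measures, modulation indices and group comparisons.

#' Cognitive-vergence analysis of an oddball session set
#'
#' Runs the full analysis on one or more binocular gaze recordings: trial
#' segmentation and validity-based exclusion, interpolation, the
#' pixel-to-vergence transform, per-trial relative modulation V(t),
#' condition-averaged curves, windowed response measures (initial, peak,
#' delay), per-subject modulation indices `mi = (T - D)/(T + D)`, group
#' t-tests at trial and subject level, cross-tracker sign-agreement
#' counts, and the distractor response slope.
#'
#' @param recordings Either a list of [gaze_recording()] objects (any mix
#'   of subjects and trackers) or a `"vergence_cohort"` from
#'   [simulate_cohort()].
#' @param events An [event_log()] shared by all recordings, or a named
#'   list of event logs keyed by subject id. Ignored (taken from the
#'   cohort) when `recordings` is a cohort.
#' @param config An [analysis_config()].
#' @return An object of class `"vergence_analysis"` with components
#'   `subjects` (per subject x tracker: trial counts, T, D, mi, reason),
#'   `window_table` (condition x window means with across-trial and
#'   across-subject SDs, per tracker), `trial_windows` (per-trial window
#'   means), `mean_curves` (condition-averaged V(t) per tracker),
#'   `mean_gamma_curves` (condition-averaged unnormalized
#'   `gamma - gamma0`, deg), `slopes` (distractor OLS slope, deg/ms),
#'   `tests` (t-test report), `quadrants` (cross-tracker mi sign counts,
#'   or `NULL` with fewer than two trackers), `qc` (per-trial exclusion
#'   log), `config`, and `call`.
#' @seealso [summary.vergence_analysis()], [coef.vergence_analysis()],
#'   [plot.vergence_analysis()]
#' @examples
#' params <- simulation_params(n_subjects = 2, seed = 1)
#' fit <- vergence_analysis(simulate_cohort(params))
#' coef(fit)
#' @export
vergence_analysis <- function(recordings, events = NULL,
                              config = analysis_config()) {
  cl <- match.call()
  if (inherits(recordings, "vergence_cohort")) {
    events <- recordings$events
    recordings <- unlist(recordings$recordings, recursive = FALSE,
                         use.names = FALSE)
  }
  if (inherits(recordings, "gaze_recording")) recordings <- list(recordings)
  if (!length(recordings)) input_error("'recordings' must be non-empty")
  events_for <- function(subject_id) {
    if (inherits(events, "event_log")) return(events)
    ev <- events[[subject_id]]
    if (is.null(ev)) input_error("no event log for subject '%s'", subject_id)
    ev
  }

  windows <- config$windows
  all_qc <- list(); summaries <- list(); trial_rows <- list()
  curve_pool <- list()   # [[tracker]][[condition]] -> list of curves
  gamma_pool <- list()   # same, unnormalized gamma - gamma0 series

  for (rec in recordings) {
    ev <- events_for(rec$subject_id)
    epochs <- epoch_trials(rec, ev, config$geometry, config$epoch_window,
                           config$exclusion_threshold)
    all_qc[[length(all_qc) + 1L]] <- qc_table(epochs)
    curves <- list(target = list(), distractor = list())
    for (e in epochs) {
      if (e$excluded) next
      cu <- relative_modulation(e$gamma, e$t_rel, config$norm_window,
                                condition = e$condition)
      curves[[e$condition]][[length(curves[[e$condition]]) + 1L]] <- cu
      tr <- rec$tracker_id
      curve_pool[[tr]][[e$condition]] <-
        c(curve_pool[[tr]][[e$condition]], list(cu))
      g0 <- e$gamma[which.min(abs(e$t_rel))]
      gamma_pool[[tr]][[e$condition]] <-
        c(gamma_pool[[tr]][[e$condition]],
          list(list(t_rel = e$t_rel, v = e$gamma - g0)))
      trial_rows[[length(trial_rows) + 1L]] <- data.frame(
        subject = rec$subject_id, tracker = tr, trial = e$trial_index,
        condition = e$condition,
        initial = window_mean(cu, windows$initial),
        peak = window_mean(cu, windows$peak),
        delay = window_mean(cu, windows$delay),
        mi_window = window_mean(cu, windows$mi),
        stringsAsFactors = FALSE)
    }
    summaries[[length(summaries) + 1L]] <-
      subject_modulation_index(curves$target, curves$distractor, windows,
                               rec$subject_id, rec$tracker_id)
  }

  qc <- do.call(rbind, all_qc)
  trial_windows <- if (length(trial_rows)) do.call(rbind, trial_rows) else NULL
  subjects <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(subject = s$subject_id, tracker = s$tracker_id,
               n_target = s$n_target, n_distractor = s$n_distractor,
               T = s$T, D = s$D, mi = s$mi,
               reason = ifelse(is.na(s$reason), "", s$reason),
               stringsAsFactors = FALSE)
  }))

  trackers <- unique(subjects$tracker)
  win_names <- names(windows)

  # condition x window summary: across-trial and across-subject moments
  window_table <- do.call(rbind, lapply(trackers, function(tr) {
    do.call(rbind, lapply(c("target", "distractor"), function(cond) {
      tw <- trial_windows[trial_windows$tracker == tr &
                            trial_windows$condition == cond, , drop = FALSE]
      do.call(rbind, lapply(win_names, function(wn) {
        col <- if (wn == "mi") "mi_window" else wn
        subj_means <- if (nrow(tw))
          tapply(tw[[col]], tw$subject, mean) else numeric(0)
        data.frame(tracker = tr, condition = cond, window = wn,
                   mean = if (nrow(tw)) mean(tw[[col]]) else NA_real_,
                   sd_trials = if (nrow(tw) > 1) stats::sd(tw[[col]]) else NA_real_,
                   mean_subjects = if (length(subj_means))
                     mean(subj_means) else NA_real_,
                   sd_subjects = if (length(subj_means) > 1)
                     stats::sd(subj_means) else NA_real_,
                   n_trials = nrow(tw), n_subjects = length(subj_means),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))

  avg_pool <- function(pool_entry) {
    # pointwise mean of (t_rel, v) series sharing one grid
    grid <- pool_entry[[1]]$t_rel
    v <- rowMeans(vapply(pool_entry, function(cu) cu$v,
                         numeric(length(grid))))
    list(t_rel = grid, v = v, n = length(pool_entry))
  }
  mean_curves <- do.call(rbind, lapply(trackers, function(tr) {
    do.call(rbind, lapply(c("target", "distractor"), function(cond) {
      cus <- curve_pool[[tr]][[cond]]
      if (is.null(cus) || !length(cus)) return(NULL)
      av <- condition_average(cus, cond)
      data.frame(tracker = tr, condition = cond, t_rel = av$t_rel,
                 v = av$v, n_trials = av$n_trials, stringsAsFactors = FALSE)
    }))
  }))
  mean_gamma_curves <- do.call(rbind, lapply(trackers, function(tr) {
    do.call(rbind, lapply(c("target", "distractor"), function(cond) {
      gs <- gamma_pool[[tr]][[cond]]
      if (is.null(gs) || !length(gs)) return(NULL)
      av <- avg_pool(gs)
      data.frame(tracker = tr, condition = cond, t_rel = av$t_rel,
                 dgamma = av$v, n_trials = av$n, stringsAsFactors = FALSE)
    }))
  }))

  slope_window <- c(0, 1250)
  slopes <- do.call(rbind, lapply(trackers, function(tr) {
    do.call(rbind, lapply(c("target", "distractor"), function(cond) {
      mg <- mean_gamma_curves[mean_gamma_curves$tracker == tr &
                                mean_gamma_curves$condition == cond, ]
      if (!nrow(mg)) return(NULL)
      data.frame(tracker = tr, condition = cond,
                 window_start = slope_window[1], window_end = slope_window[2],
                 slope_deg_per_ms = response_slope(
                   list(t_rel = mg$t_rel, v = mg$dgamma), slope_window),
                 stringsAsFactors = FALSE)
    }))
  }))

  var_equal <- config$t_test == "student"
  tests <- list()
  add_test <- function(level, tracker, contrast, window, a, b,
                       paired = FALSE) {
    if (length(a) < 2 || length(b) < 2 ||
        (paired && length(a) != length(b))) return()
    res <- two_tailed_t(a, b, paired = paired, var_equal = var_equal)
    tests[[length(tests) + 1L]] <<- data.frame(
      level = level, tracker = tracker, contrast = contrast,
      window = window, n_a = length(a), n_b = length(b),
      t = res$t, df = res$df, p = res$p, stringsAsFactors = FALSE)
  }
  for (tr in trackers) {
    tw <- trial_windows[trial_windows$tracker == tr, , drop = FALSE]
    sub <- subjects[subjects$tracker == tr, , drop = FALSE]
    for (wn in win_names) {
      col <- if (wn == "mi") "mi_window" else wn
      add_test("trial", tr, "target vs distractor", wn,
               tw[[col]][tw$condition == "target"],
               tw[[col]][tw$condition == "distractor"])
      sm <- tapply(tw[[col]], list(tw$subject, tw$condition), mean)
      if (!is.null(dim(sm)) && all(c("target", "distractor") %in% colnames(sm))) {
        keep <- stats::complete.cases(sm[, c("target", "distractor"),
                                         drop = FALSE])
        add_test("subject", tr, "target vs distractor", wn,
                 sm[keep, "target"], sm[keep, "distractor"], paired = TRUE)
      }
    }
    keep <- !is.na(sub$T) & !is.na(sub$D)
    add_test("subject", tr, "T vs D", "mi", sub$T[keep], sub$D[keep],
             paired = TRUE)
  }
  quadrants <- NULL
  if (length(trackers) >= 2) {
    t1 <- trackers[1]; t2 <- trackers[2]
    ids <- unique(subjects$subject)
    mi_of <- function(tr) subjects$mi[match(
      paste(ids, tr), paste(subjects$subject, subjects$tracker))]
    m1 <- mi_of(t1); m2 <- mi_of(t2)
    quadrants <- sign_quadrant_counts(m1, m2, labels = c(t1, t2))
    keep <- !is.na(m1) & !is.na(m2)
    add_test("subject", paste(t1, "vs", t2), "mi", "mi",
             m1[keep], m2[keep], paired = TRUE)
  }

  structure(list(subjects = subjects, window_table = window_table,
                 trial_windows = trial_windows, mean_curves = mean_curves,
                 mean_gamma_curves = mean_gamma_curves, slopes = slopes,
                 tests = do.call(rbind, tests), quadrants = quadrants,
                 qc = qc, config = config, call = cl),
            class = "vergence_analysis")
}

#' @export
print.vergence_analysis <- function(x, ...) {
  cat("Cognitive-vergence analysis\n")
  trackers <- unique(x$subjects$tracker)
  cat(sprintf("  %d subject(s), tracker(s): %s\n",
              length(unique(x$subjects$subject)),
              paste(trackers, collapse = ", ")))
  cat(sprintf("  trials: %d analyzed, %d excluded (%.1f%%)\n",
              sum(!x$qc$excluded), sum(x$qc$excluded),
              100 * mean(x$qc$excluded)))
  for (tr in trackers) {
    mi <- x$subjects$mi[x$subjects$tracker == tr]
    cat(sprintf("  %s: mean mi = %.3f (SD %.3f, n = %d defined, %.1f%% positive)\n",
                tr, mean(mi, na.rm = TRUE), stats::sd(mi, na.rm = TRUE),
                sum(!is.na(mi)), 100 * mean(mi > 0, na.rm = TRUE)))
  }
  invisible(x)
}

#' Summarize a cognitive-vergence analysis
#'
#' @param object A `"vergence_analysis"`.
#' @param ... Unused.
#' @return An object of class `"summary.vergence_analysis"` bundling the
#'   window summary table, per-subject indices, slopes, t-test report and
#'   quadrant counts, with a print method.
#' @export
summary.vergence_analysis <- function(object, ...) {
  structure(list(window_table = object$window_table,
                 subjects = object$subjects, slopes = object$slopes,
                 tests = object$tests, quadrants = object$quadrants),
            class = "summary.vergence_analysis")
}

#' @export
print.summary.vergence_analysis <- function(x, ...) {
  cat("Window summary (mean across trials +/- SD):\n")
  wt <- x$window_table
  for (tr in unique(wt$tracker)) {
    cat(sprintf("  tracker %s\n", tr))
    for (cond in unique(wt$condition[wt$tracker == tr])) {
      rows <- wt[wt$tracker == tr & wt$condition == cond &
                   wt$window != "mi", ]
      cat(sprintf("    %-10s %s\n", cond,
                  paste(sprintf("%s %.3f +/- %.3f", rows$window, rows$mean,
                                rows$sd_trials), collapse = ", ")))
    }
  }
  cat("\nPer-subject modulation indices:\n")
  for (tr in unique(x$subjects$tracker)) {
    mi <- x$subjects$mi[x$subjects$tracker == tr]
    cat(sprintf("  %s: mean %.3f, SD %.3f, %.1f%% positive (n = %d)\n",
                tr, mean(mi, na.rm = TRUE), stats::sd(mi, na.rm = TRUE),
                100 * mean(mi > 0, na.rm = TRUE), sum(!is.na(mi))))
  }
  if (!is.null(x$quadrants)) {
    cat("\nCross-tracker mi sign counts:\n")
    print(x$quadrants$counts)
  }
  if (!is.null(x$tests)) {
    cat("\nComparisons (two-tailed t):\n")
    print(x$tests, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Per-subject modulation indices of a fitted analysis
#'
#' @param object A `"vergence_analysis"`.
#' @param ... Unused.
#' @return A matrix of modulation indices, subjects x trackers.
#' @export
coef.vergence_analysis <- function(object, ...) {
  s <- object$subjects
  ids <- unique(s$subject); trs <- unique(s$tracker)
  m <- matrix(NA_real_, length(ids), length(trs),
              dimnames = list(ids, trs))
  m[cbind(match(s$subject, ids), match(s$tracker, trs))] <- s$mi
  m
}

#' Plot condition-averaged modulation curves
#'
#' One panel per tracker: the mean V(t) of target and distractor trials
#' against time from stimulus onset, with the onset marked.
#'
#' @param x A `"vergence_analysis"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.vergence_analysis <- function(x, ...) {
  mc <- x$mean_curves
  trackers <- unique(mc$tracker)
  old <- graphics::par(mfrow = c(1, length(trackers)))
  on.exit(graphics::par(old))
  for (tr in trackers) {
    d <- mc[mc$tracker == tr, ]
    graphics::plot(NA, xlim = range(d$t_rel), ylim = range(d$v),
                   xlab = "time from stimulus onset (ms)",
                   ylab = "mean V(t)", main = sprintf("tracker %s", tr), ...)
    graphics::abline(v = 0, lty = 3); graphics::abline(h = 0, lty = 3)
    cols <- c(target = "red", distractor = "blue")
    for (cond in c("target", "distractor")) {
      dd <- d[d$condition == cond, ]
      graphics::lines(dd$t_rel, dd$v, col = cols[[cond]], lwd = 2)
    }
    graphics::legend("topleft", legend = names(cols), col = cols, lwd = 2,
                     bty = "n")
  }
  invisible(x)
}
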