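# File-oriented orchestration: write a simulated cohort as CSVs, analyze a
# dataset directory, and render a markdown report from the result CSVs.
# Every artifact is plain text; reports and manifests carry no timestamps,
# so a rerun with the same seed is byte-identical.

#' Simulate a cohort and write it as a dataset directory
#'
#' Writes one gaze CSV per subject x tracker
#' (`gaze_<subject>_<tracker>.csv`), one event CSV per subject
#' (`events_<subject>.csv`), `ground_truth.csv`, and `manifest.yaml`
#' recording the seed, package version and design counts.
#'
#' @param out_dir Output directory (created if absent).
#' @param params A [simulation_params()].
#' @param geometry A [geometry_config()].
#' @return The cohort (invisibly), as from [simulate_cohort()].
#' @export
run_simulate <- function(out_dir, params = simulation_params(),
                         geometry = geometry_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(params, geometry)
  for (sid in names(cohort$recordings)) {
    write_event_log(cohort$events[[sid]],
                    file.path(out_dir, sprintf("events_%s.csv", sid)))
    for (tr in names(cohort$recordings[[sid]]))
      write_gaze_csv(cohort$recordings[[sid]][[tr]],
                     file.path(out_dir, sprintf("gaze_%s_%s.csv", sid, tr)))
  }
  utils::write.csv(cohort$ground_truth,
                   file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  yaml::write_yaml(
    list(package = "cogvergence",
         version = as.character(utils::packageVersion("cogvergence")),
         seed = params$seed %||% NA,
         n_subjects = params$n_subjects, n_trials = params$n_trials,
         p_target = params$p_target,
         trackers = names(params$trackers)),
    file.path(out_dir, "manifest.yaml"))
  invisible(cohort)
}

#' Analyze a dataset directory and write result CSVs
#'
#' Reads every `gaze_<subject>_<tracker>.csv` and `events_<subject>.csv`
#' under `data_dir` (the layout written by [run_simulate()]), fits
#' [vergence_analysis()], and writes `mean_curves.csv`,
#' `mean_gamma_curves.csv`, `window_summary.csv`, `subject_mi.csv`,
#' `trial_windows.csv`, `slopes.csv`, `tests.csv`, `quadrant_counts.csv`
#' (when two trackers are present) and the exclusion log `qc.csv` to
#' `out_dir`, plus a `curves.png` figure drawn from the exported
#' `mean_curves.csv` (never from in-memory state).
#'
#' @param data_dir Dataset directory.
#' @param out_dir Results directory (created if absent).
#' @param config An [analysis_config()].
#' @param plot Draw the figure (default TRUE).
#' @return The `"vergence_analysis"` object, invisibly.
#' @export
run_analyze <- function(data_dir, out_dir, config = analysis_config(),
                        plot = TRUE) {
  if (!dir.exists(data_dir)) input_error("no such dataset directory: %s", data_dir)
  gaze_files <- list.files(data_dir, "^gaze_.*\\.csv$", full.names = TRUE)
  if (!length(gaze_files)) input_error("no gaze CSVs under %s", data_dir)
  recordings <- lapply(gaze_files, function(f) {
    parts <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]]
    read_gaze_csv(f, tracker_id = parts[3], subject_id = parts[2])
  })
  subjects <- unique(vapply(recordings, `[[`, character(1), "subject_id"))
  events <- lapply(subjects, function(sid)
    read_event_log(file.path(data_dir, sprintf("events_%s.csv", sid))))
  names(events) <- subjects

  fit <- vergence_analysis(recordings, events, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(fit$mean_curves, "mean_curves.csv")
  wr(fit$mean_gamma_curves, "mean_gamma_curves.csv")
  wr(fit$window_table, "window_summary.csv")
  wr(fit$subjects, "subject_mi.csv")
  wr(fit$trial_windows, "trial_windows.csv")
  wr(fit$slopes, "slopes.csv")
  wr(fit$tests, "tests.csv")
  wr(fit$qc, "qc.csv")
  if (!is.null(fit$quadrants)) {
    q <- fit$quadrants
    utils::write.csv(
      data.frame(cell = c(outer(rownames(q$counts), colnames(q$counts),
                                paste, sep = "/")),
                 count = as.vector(q$counts),
                 stringsAsFactors = FALSE),
      file.path(out_dir, "quadrant_counts.csv"), row.names = FALSE)
  }
  if (plot) {
    mc <- utils::read.csv(file.path(out_dir, "mean_curves.csv"))
    grDevices::png(file.path(out_dir, "curves.png"), width = 900,
                   height = 420)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_mean_curves(mc)
  }
  invisible(fit)
}

# figure drawn from the exported CSV, so it is reproducible from artifacts
plot_mean_curves <- function(mc) {
  trackers <- unique(mc$tracker)
  old <- graphics::par(mfrow = c(1, length(trackers)))
  on.exit(graphics::par(old))
  cols <- c(target = "red", distractor = "blue")
  for (tr in trackers) {
    d <- mc[mc$tracker == tr, ]
    graphics::plot(NA, xlim = range(d$t_rel), ylim = range(d$v),
                   xlab = "time from stimulus onset (ms)",
                   ylab = "mean V(t)", main = sprintf("tracker %s", tr))
    graphics::abline(v = 0, lty = 3); graphics::abline(h = 0, lty = 3)
    for (cond in names(cols)) {
      dd <- d[d$condition == cond, ]
      if (nrow(dd)) graphics::lines(dd$t_rel, dd$v, col = cols[[cond]],
                                    lwd = 2)
    }
    graphics::legend("topleft", legend = names(cols), col = cols, lwd = 2,
                     bty = "n")
  }
}

#' Render a markdown report from a results directory
#'
#' Reads the CSVs written by [run_analyze()] and writes one human-readable
#' markdown document: the window-summary table, per-tracker modulation
#' index statistics (mean, SD, positive fraction), cross-tracker quadrant
#' counts when present, slopes, and the t-test report. A missing required
#' file raises a report error naming it. Output contains no timestamps,
#' so regeneration is byte-identical.
#'
#' @param results_dir Directory written by [run_analyze()].
#' @param out_file Output path (default `report.md` inside `results_dir`).
#' @return `out_file`, invisibly.
#' @export
run_report <- function(results_dir, out_file = file.path(results_dir,
                                                         "report.md")) {
  need <- function(name) {
    p <- file.path(results_dir, name)
    if (!file.exists(p)) report_error("missing result file: %s", name)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  wt <- need("window_summary.csv")
  sub <- need("subject_mi.csv")
  tests <- need("tests.csv")
  slopes <- need("slopes.csv")
  qpath <- file.path(results_dir, "quadrant_counts.csv")
  quad <- if (file.exists(qpath)) utils::read.csv(qpath) else NULL

  L <- c("# Cognitive vergence analysis report", "")
  L <- c(L, "## Window summary (mean V across trials, +/- SD)", "",
         "| tracker | condition | initial | peak | delay |",
         "|---|---|---|---|---|")
  fmt <- function(m, s) sprintf("%.3f +/- %.3f", m, s)
  for (tr in unique(wt$tracker)) for (cond in c("target", "distractor")) {
    row <- function(wn) wt[wt$tracker == tr & wt$condition == cond &
                             wt$window == wn, ]
    i <- row("initial"); p <- row("peak"); d <- row("delay")
    if (!nrow(i)) next
    L <- c(L, sprintf("| %s | %s | %s | %s | %s |", tr, cond,
                      fmt(i$mean, i$sd_trials), fmt(p$mean, p$sd_trials),
                      fmt(d$mean, d$sd_trials)))
  }
  L <- c(L, "", "## Modulation indices", "")
  for (tr in unique(sub$tracker)) {
    mi <- sub$mi[sub$tracker == tr]
    n_undef <- sum(is.na(mi))
    L <- c(L, sprintf(
      "- %s: mean mi = %.3f (SD %.3f), %.1f%% positive, n = %d defined%s",
      tr, mean(mi, na.rm = TRUE), stats::sd(mi, na.rm = TRUE),
      100 * mean(mi > 0, na.rm = TRUE), sum(!is.na(mi)),
      if (n_undef) sprintf(" (%d undefined, excluded)", n_undef) else ""))
  }
  if (!is.null(quad)) {
    L <- c(L, "", "## Cross-tracker mi sign agreement", "")
    L <- c(L, sprintf("- %s: %d subject(s)", quad$cell, quad$count))
  }
  L <- c(L, "", "## Distractor/target response slopes (deg/ms)", "")
  L <- c(L, sprintf("- %s %s, %g-%g ms: %.3g", slopes$tracker,
                    slopes$condition, slopes$window_start,
                    slopes$window_end, slopes$slope_deg_per_ms))
  L <- c(L, "", "## Two-tailed t-tests", "",
         "| level | tracker | contrast | window | t | df | p |",
         "|---|---|---|---|---|---|---|")
  L <- c(L, sprintf("| %s | %s | %s | %s | %.3f | %.1f | %.3g |",
                    tests$level, tests$tracker, tests$contrast,
                    tests$window, tests$t, tests$df, tests$p))
  writeLines(L, out_file)
  invisible(out_file)
}
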