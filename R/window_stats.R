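# Windowed response measures, the modulation index, slope, and group
# comparisons.

#' Analysis windows of the oddball vergence response
#'
#' All windows are in ms relative to stimulus onset and are closed
#' intervals on the sample grid: `initial` (0-200 ms), `peak` (400-433 ms
#' — one 30 Hz sampling interval wide, so it may contain a single grid
#' point), `delay` (600-1250 ms), and `mi` (300-600 ms), the window over
#' which the per-condition responses entering the modulation index are
#' averaged.
#'
#' @param initial,peak,delay,mi Length-2 numeric `(start, end)` windows.
#' @return An object of class `"window_definition"`.
#' @export
window_definition <- function(initial = c(0, 200), peak = c(400, 433),
                              delay = c(600, 1250), mi = c(300, 600)) {
  w <- list(initial = as.numeric(initial), peak = as.numeric(peak),
            delay = as.numeric(delay), mi = as.numeric(mi))
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2 || w[[nm]][1] >= w[[nm]][2])
      param_error("window '%s' must be (start, end) with start < end", nm)
  }
  structure(w, class = "window_definition")
}

#' Mean response in a time window
#'
#' Arithmetic mean of the curve values at grid points `t` with
#' `start <= t <= end` (closed interval). Windows as narrow as one
#' sampling interval are legal: a single contained grid point is returned
#' as-is.
#'
#' @param curve A `"modulation_curve"`, or anything with `t_rel` and `v`
#'   fields (e.g. a list holding an unnormalized gamma-minus-baseline
#'   series in `v`).
#' @param window Length-2 numeric `(start, end)` in ms.
#' @return The windowed mean.
#' @export
window_mean <- function(curve, window) {
  idx <- curve$t_rel >= window[1] - 1e-9 & curve$t_rel <= window[2] + 1e-9
  if (!any(idx))
    window_error("window (%g, %g) contains no grid point", window[1], window[2])
  mean(curve$v[idx])
}

#' Target/distractor modulation index
#'
#' `mi = (T - D) / (T + D)`, contrasting the mean window-averaged response
#' to targets (`T`) against distractors (`D`). Positive mi means a
#' stronger target response. The index is scale invariant
#' (`mi(aT, aD) = mi(T, D)` for `a > 0`) and unbounded as `T + D`
#' approaches 0, so magnitudes above 1 occur; when `|T + D| < 1e-12` the
#' index is undefined and `NA` is returned with a warning (propagated as
#' missing and excluded from group means).
#'
#' @param T,D Window-averaged responses (vectorised).
#' @return The modulation index (`NA` where undefined).
#' @export
modulation_index <- function(T, D) {
  den <- T + D
  undef <- abs(den) < 1e-12
  if (any(undef, na.rm = TRUE))
    warning("modulation index undefined for |T + D| < 1e-12; returning NA")
  out <- (T - D) / den
  out[undef] <- NA_real_
  out
}

#' Per-subject window summary and modulation index
#'
#' For one subject and tracker: averages each retained trial's V(t) over
#' the mi window, means those per condition to obtain `T` (targets) and
#' `D` (distractors), and forms `mi = (T - D)/(T + D)`. The initial, peak
#' and delay window means (with across-trial SDs) are computed per
#' condition the same way.
#'
#' @param target_curves,distractor_curves Lists of single-trial
#'   `"modulation_curve"` objects.
#' @param windows A [window_definition()].
#' @param subject_id,tracker_id Identifiers carried into the summary.
#' @return An object of class `"subject_summary"`: `subject_id`,
#'   `tracker_id`, `n_target`, `n_distractor`, `window_table` (data.frame:
#'   condition, window, mean, sd, n), `T`, `D`, `mi`, `reason` (NA unless
#'   mi is missing).
#' @export
subject_modulation_index <- function(target_curves, distractor_curves,
                                     windows = window_definition(),
                                     subject_id = NA_character_,
                                     tracker_id = NA_character_) {
  per_window <- function(curves, cond) {
    do.call(rbind, lapply(names(windows), function(wn) {
      m <- vapply(curves, window_mean, numeric(1), window = windows[[wn]])
      data.frame(condition = cond, window = wn,
                 mean = if (length(m)) mean(m) else NA_real_,
                 sd = if (length(m) > 1) stats::sd(m) else NA_real_,
                 n = length(m), stringsAsFactors = FALSE)
    }))
  }
  tab <- rbind(per_window(target_curves, "target"),
               per_window(distractor_curves, "distractor"))
  mi_of <- function(curves) {
    if (!length(curves)) return(NA_real_)
    mean(vapply(curves, window_mean, numeric(1), window = windows$mi))
  }
  T <- mi_of(target_curves)
  D <- mi_of(distractor_curves)
  reason <- NA_character_
  if (is.na(T) || is.na(D)) {
    mi <- NA_real_
    reason <- sprintf("no retained %s trials",
                      if (is.na(T)) "target" else "distractor")
  } else {
    mi <- suppressWarnings(modulation_index(T, D))
    if (is.na(mi)) reason <- "undefined: |T + D| < 1e-12"
  }
  structure(list(subject_id = subject_id, tracker_id = tracker_id,
                 n_target = length(target_curves),
                 n_distractor = length(distractor_curves),
                 window_table = tab, T = T, D = D, mi = mi, reason = reason),
            class = "subject_summary")
}

#' @export
print.subject_summary <- function(x, ...) {
  cat(sprintf("Subject %s / tracker %s: %d target, %d distractor trials\n",
              x$subject_id, x$tracker_id, x$n_target, x$n_distractor))
  cat(sprintf("  T = %.4g, D = %.4g, mi = %.4g%s\n", x$T, x$D, x$mi,
              ifelse(is.na(x$reason), "", paste0(" (", x$reason, ")"))))
  invisible(x)
}

#' Ordinary least-squares slope of a response curve
#'
#' Slope of curve values against time over a window, in units of the
#' curve per ms (deg/ms when applied to an unnormalized
#' `gamma(t) - gamma0` series).
#'
#' @param curve As in [window_mean()].
#' @param window Length-2 numeric `(start, end)` in ms.
#' @return The OLS slope.
#' @export
response_slope <- function(curve, window) {
  idx <- curve$t_rel >= window[1] - 1e-9 & curve$t_rel <= window[2] + 1e-9
  if (sum(idx) < 2L)
    window_error("window (%g, %g) contains fewer than 2 grid points",
                 window[1], window[2])
  t <- curve$t_rel[idx]
  v <- curve$v[idx]
  unname(stats::coef(stats::lm(v ~ t))[2])
}

#' Two-tailed t-test with degenerate-sample contract
#'
#' Unpaired comparisons use the Welch two-sample t by default (pooled
#' Student t via `var_equal = TRUE`); paired comparisons are the
#' one-sample t on the differences. When both samples (or all paired
#' differences) have zero variance, `t.test` would fail; here equal means
#' give `t = 0, p = 1` and unequal means `t = +/-Inf, p = 0`.
#'
#' @param a,b Numeric samples, each of length >= 2; equal lengths if
#'   `paired`.
#' @param paired Logical.
#' @param var_equal Pooled-variance Student t instead of Welch (unpaired
#'   only).
#' @return A list: `t`, `df`, `p`.
#' @export
two_tailed_t <- function(a, b, paired = FALSE, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    input_error("each sample must contain at least 2 values")
  if (paired && length(a) != length(b))
    input_error("paired samples must have equal length")
  degenerate <- if (paired) stats::sd(a - b) == 0
                else stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate) {
    dm <- mean(a) - mean(b)
    if (dm == 0) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(dm) * Inf, df = NA_real_, p = 0))
  }
  ht <- if (paired) stats::t.test(a - b)
        else stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Cross-tracker sign agreement of modulation indices
#'
#' Tabulates, over subjects measured with two trackers, the 2x2 counts of
#' modulation-index sign combinations (mi > 0 is "positive"; zero counts
#' as non-positive) together with the per-tracker positive fractions.
#' Subjects missing either index are reported separately, not dropped
#' silently.
#'
#' @param mi_a,mi_b Numeric vectors of per-subject modulation indices,
#'   paired by position (one subject per element); `NA` = missing.
#' @param labels Length-2 character, tracker names for the output.
#' @return A list: `counts` (2x2 matrix, rows = first tracker pos/nonpos,
#'   cols = second), `frac_positive` (named length-2), `n_complete`,
#'   `n_missing`.
#' @export
sign_quadrant_counts <- function(mi_a, mi_b, labels = c("A", "B")) {
  if (length(mi_a) != length(mi_b))
    input_error("'mi_a' and 'mi_b' must be paired by subject (equal length)")
  complete <- !is.na(mi_a) & !is.na(mi_b)
  a <- mi_a[complete] > 0
  b <- mi_b[complete] > 0
  counts <- matrix(c(sum(a & b), sum(a & !b),
                     sum(!a & b), sum(!a & !b)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(paste0(labels[1], c("+", "-")),
                                   paste0(labels[2], c("+", "-"))))
  frac <- c(mean(mi_a > 0, na.rm = TRUE), mean(mi_b > 0, na.rm = TRUE))
  names(frac) <- labels
  list(counts = counts, frac_positive = frac,
       n_complete = sum(complete), n_missing = sum(!complete))
}
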