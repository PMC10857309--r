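# The relative vergence modulation V(t) and condition averaging.

#' Relative vergence modulation of one trial
#'
#' The central statistic: with `gamma0` the vergence angle at stimulus
#' onset (the single grid sample at t = 0), the trial's response is
#' `d(t) = gamma(t) - gamma0`, normalized by its maximum absolute
#' excursion within `norm_window`:
#' \deqn{V(t) = \frac{\gamma(t) - \gamma_0}{\max |\gamma(t) - \gamma_0|}.}
#' V is dimensionless, equals 0 at onset, and attains absolute value 1
#' somewhere inside the normalization window — unless the trial is
#' perfectly flat there, in which case V is identically 0 and `norm_max`
#' is recorded as 0 (keeping such trials in averages without dividing by
#' zero).
#'
#' @param gamma Numeric vergence-angle series (deg) on a uniform grid.
#' @param t_rel The grid, ms relative to stimulus onset; must contain 0.
#' @param norm_window Length-2 numeric; window over which the normalizing
#'   maximum is taken (default `c(0, 2000)` ms, the stimulus epoch).
#' @param condition Optional condition label carried on the curve.
#' @return An object of class `"modulation_curve"`: fields `t_rel`, `v`,
#'   `gamma0`, `norm_max`, `condition`, `n_trials` (= 1).
#' @export
relative_modulation <- function(gamma, t_rel, norm_window = c(0, 2000),
                                condition = NA_character_) {
  if (length(gamma) != length(t_rel))
    input_error("'gamma' and 't_rel' must have equal length")
  if (norm_window[1] >= norm_window[2])
    param_error("'norm_window' must satisfy start < end")
  i0 <- which.min(abs(t_rel))
  if (abs(t_rel[i0]) > 1e-6)
    input_error("grid does not contain the stimulus onset t = 0")
  in_win <- t_rel >= norm_window[1] - 1e-9 & t_rel <= norm_window[2] + 1e-9
  if (!any(in_win))
    window_error("normalization window (%g, %g) contains no grid point",
                 norm_window[1], norm_window[2])
  if (any(!is.finite(gamma[in_win])))
    data_error("non-finite vergence values inside the normalization window")
  gamma0 <- gamma[i0]
  d <- gamma - gamma0
  norm_max <- max(abs(d[in_win]))
  v <- if (norm_max == 0) rep(0, length(d)) else d / norm_max
  structure(list(t_rel = t_rel, v = v, gamma0 = gamma0,
                 norm_max = norm_max, condition = condition, n_trials = 1L),
            class = "modulation_curve")
}

#' @export
print.modulation_curve <- function(x, ...) {
  cat(sprintf(
    "Modulation curve (%s, %d trial%s): %d points, %g..%g ms, norm_max = %g deg\n",
    ifelse(is.na(x$condition), "unlabelled", x$condition), x$n_trials,
    if (x$n_trials == 1) "" else "s", length(x$t_rel),
    min(x$t_rel), max(x$t_rel), x$norm_max))
  invisible(x)
}

#' Average modulation curves within a condition
#'
#' Pointwise arithmetic mean of single-trial (or previously averaged)
#' V(t) curves sharing one grid; this is the "mean V(t)" curve of a
#' condition. Averaging happens after the per-trial normalization, so the
#' mean curve may have `max |V| < 1`. The stored `gamma0` and `norm_max`
#' are the means of the members' values (metadata, not a normalizer).
#'
#' @param curves A non-empty list of `"modulation_curve"` objects on a
#'   common grid.
#' @param condition Optional label; if given, every member must match it.
#' @return A `"modulation_curve"` with `n_trials` the total member count.
#' @export
condition_average <- function(curves, condition = NULL) {
  if (!length(curves)) input_error("'curves' must be non-empty")
  grid <- curves[[1]]$t_rel
  for (cu in curves) {
    if (length(cu$t_rel) != length(grid) || any(abs(cu$t_rel - grid) > 1e-9))
      cv_error("cogvergence_alignment_error", "curves are not on a common grid")
    if (!is.null(condition) && !identical(cu$condition, condition))
      input_error("curve condition '%s' does not match '%s'",
                  cu$condition, condition)
  }
  w <- vapply(curves, function(cu) as.numeric(cu$n_trials), numeric(1))
  vs <- vapply(curves, function(cu) cu$v, numeric(length(grid)))
  vs <- matrix(vs, nrow = length(grid))
  structure(list(t_rel = grid,
                 v = as.numeric(vs %*% w / sum(w)),
                 gamma0 = stats::weighted.mean(
                   vapply(curves, function(cu) cu$gamma0, numeric(1)), w),
                 norm_max = stats::weighted.mean(
                   vapply(curves, function(cu) cu$norm_max, numeric(1)), w),
                 condition = condition %||% curves[[1]]$condition,
                 n_trials = as.integer(sum(w))),
            class = "modulation_curve")
}
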