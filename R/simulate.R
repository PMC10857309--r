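# Seedable simulator of oddball sessions and binocular gaze recordings.
#
# The generator encodes the study design it emulates: 100-trial sessions
# with 20% targets, 2000 ms mask + 2000 ms stimulus epochs, 30 Hz binocular
# sampling, an event-locked convergence transient (onset ~300 ms, peak
# ~450 ms) plus a sustained delay component through 1250 ms, larger for
# targets than distractors, with tracker-specific additive noise and
# validity dropouts and log-normal between-subject amplitude spread.

# small blacklist so a random 11-letter string never spells a word
WORD_BLACKLIST <- c("information", "performance", "development", "environment",
                    "education", "government", "independent", "experience",
                    "management", "important", "technology", "interesting")

#' Parametric shape of the event-locked convergence response
#'
#' The response kernel is zero before `latency`, rises along a
#' raised-cosine ramp to `peak_amp` at `peak_time`, relaxes exponentially
#' (time constant `decay`) toward the sustained plateau `delay_amp`, and
#' after `sustain_until` relaxes exponentially back to 0. It is continuous
#' everywhere. The parameters — not the specific ramp shape — carry the
#' structure the analysis must detect: transient onset near 300 ms, peak
#' near 450 ms, and a delay component through 1250 ms.
#'
#' @param latency Transient onset, ms after stimulus onset (default 300).
#' @param peak_time Time of the transient peak, ms (default 450); must
#'   exceed `latency`.
#' @param peak_amp Transient amplitude, deg of vergence over baseline.
#' @param delay_amp Sustained (delay-component) amplitude, deg.
#' @param decay Exponential relaxation time constant, ms (default 150).
#' @param sustain_until End of the sustained component, ms (default 1250).
#' @return An object of class `"response_kernel"`.
#' @export
response_kernel <- function(latency = 300, peak_time = 450, peak_amp = 0.3,
                            delay_amp = 0.4 * peak_amp, decay = 150,
                            sustain_until = 1250) {
  if (latency >= peak_time) param_error("'latency' must be < 'peak_time'")
  if (peak_amp < 0 || delay_amp < 0) param_error("amplitudes must be >= 0")
  if (decay <= 0) param_error("'decay' must be > 0")
  structure(list(latency = latency, peak_time = peak_time,
                 peak_amp = peak_amp, delay_amp = delay_amp,
                 decay = decay, sustain_until = sustain_until),
            class = "response_kernel")
}

#' Evaluate a response kernel on a time grid
#'
#' @param kernel A [response_kernel()].
#' @param t_rel Numeric times, ms relative to stimulus onset.
#' @return Vergence increment over baseline, deg, same length as `t_rel`.
#' @export
kernel_curve <- function(kernel, t_rel) {
  k <- kernel
  y <- numeric(length(t_rel))
  rise <- t_rel >= k$latency & t_rel <= k$peak_time
  y[rise] <- k$peak_amp * 0.5 *
    (1 - cos(pi * (t_rel[rise] - k$latency) / (k$peak_time - k$latency)))
  fall <- t_rel > k$peak_time & t_rel <= k$sustain_until
  y[fall] <- k$delay_amp +
    (k$peak_amp - k$delay_amp) * exp(-(t_rel[fall] - k$peak_time) / k$decay)
  v_end <- k$delay_amp +
    (k$peak_amp - k$delay_amp) * exp(-(k$sustain_until - k$peak_time) / k$decay)
  late <- t_rel > k$sustain_until
  y[late] <- v_end * exp(-(t_rel[late] - k$sustain_until) / k$decay)
  y
}

#' Tracker noise/dropout specification
#'
#' @param rate Sampling rate, Hz.
#' @param noise_sd Additive per-eye, per-sample gaze noise, deg.
#' @param dropout_prob Per-sample probability of an invalid validity code
#'   (0 for webcam-like trackers, which report no validity dropouts).
#' @return An object of class `"tracker_spec"`.
#' @export
tracker_spec <- function(rate = 30, noise_sd = 0.1, dropout_prob = 0) {
  if (rate <= 0) param_error("'rate' must be > 0")
  if (noise_sd < 0) param_error("'noise_sd' must be >= 0")
  if (dropout_prob < 0 || dropout_prob >= 1)
    param_error("'dropout_prob' must be in [0, 1)")
  structure(list(rate = rate, noise_sd = noise_sd,
                 dropout_prob = dropout_prob), class = "tracker_spec")
}

#' Simulation parameters for a full oddball cohort
#'
#' Defaults reproduce the study design the package analyzes: 28 subjects,
#' 100 trials per session with 20% targets, 2000 + 2000 ms mask/stimulus
#' epochs, and two simultaneous 30 Hz trackers — an infrared-like tracker
#' (`ET`: low noise, per-sample validity dropouts at a rate giving an
#' expected ~33% trial exclusion under the 15-invalid-sample rule) and a
#' webcam-like tracker (`WC`: higher noise, no dropouts). Target responses
#' are larger than distractor responses; each subject carries a log-normal
#' multiplicative amplitude factor with spread `subject_sd`.
#'
#' @param n_subjects Number of subjects (default 28).
#' @param n_trials Trials per session (default 100).
#' @param p_target Proportion of target trials (default 0.20).
#' @param mask_ms,stim_ms Mask and stimulus durations, ms (defaults 2000).
#' @param target_kernel,distractor_kernel [response_kernel()]s per
#'   condition.
#' @param subject_sd SD of the log amplitude factor across subjects.
#' @param trackers Named list of [tracker_spec()]s.
#' @param seed Integer seed for [simulate_cohort()]; `NULL` uses the
#'   current RNG stream.
#' @return An object of class `"simulation_params"`.
#' @export
simulation_params <- function(n_subjects = 28, n_trials = 100,
                              p_target = 0.20,
                              mask_ms = 2000, stim_ms = 2000,
                              target_kernel = response_kernel(
                                peak_amp = 0.3, delay_amp = 0.12),
                              distractor_kernel = response_kernel(
                                peak_amp = 0.05, delay_amp = 0.01),
                              subject_sd = 0.5,
                              trackers = list(
                                ET = tracker_spec(rate = 30, noise_sd = 0.08,
                                                  dropout_prob = 0.2),
                                WC = tracker_spec(rate = 30, noise_sd = 0.2,
                                                  dropout_prob = 0)),
                              seed = NULL) {
  if (p_target <= 0 || p_target >= 1)
    param_error("'p_target' must be strictly between 0 and 1")
  if (n_subjects < 1 || n_trials < 1)
    param_error("'n_subjects' and 'n_trials' must be >= 1")
  if (!length(trackers) || is.null(names(trackers)) ||
      any(!nzchar(names(trackers))))
    param_error("'trackers' must be a named list of tracker_spec objects")
  structure(list(n_subjects = n_subjects, n_trials = n_trials,
                 p_target = p_target, mask_ms = mask_ms, stim_ms = stim_ms,
                 target_kernel = target_kernel,
                 distractor_kernel = distractor_kernel,
                 subject_sd = subject_sd, trackers = trackers, seed = seed),
            class = "simulation_params")
}

random_stimulus_string <- function(len) {
  repeat {
    s <- paste(sample(c(letters, LETTERS), len, replace = TRUE),
               collapse = "")
    if (!(tolower(s) %in% WORD_BLACKLIST)) return(s)
  }
}

#' Generate one oddball trial schedule
#'
#' Exactly `round(n_trials * p_target)` target trials are placed by a
#' seeded shuffle (the design fixes the target percentage, so counts are
#' exact, not Bernoulli draws). Trials follow a fixed cadence of
#' `mask_ms + stim_ms`; stimulus strings are random mixed-case letter
#' strings, regenerated if they spell a blacklisted English word.
#'
#' @param n_trials Number of trials (default 100).
#' @param p_target Proportion of targets (default 0.20).
#' @param mask_ms,stim_ms Mask and stimulus durations, ms.
#' @param string_len Stimulus string length (default 11 characters).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An [event_log()] of `n_trials` trials.
#' @export
generate_paradigm <- function(n_trials = 100, p_target = 0.20,
                              mask_ms = 2000, stim_ms = 2000,
                              string_len = 11, seed = NULL) {
  if (p_target <= 0 || p_target >= 1)
    param_error("'p_target' must be strictly between 0 and 1")
  with_seed(seed, {
    n_target <- round(n_trials * p_target)
    cond <- sample(c(rep("target", n_target),
                     rep("distractor", n_trials - n_target)))
    mask_onset <- (seq_len(n_trials) - 1) * (mask_ms + stim_ms)
    event_log(data.frame(
      trial_index = seq_len(n_trials),
      condition = cond,
      mask_onset = mask_onset,
      stimulus_onset = mask_onset + mask_ms,
      mask_duration = mask_ms,
      stimulus_duration = stim_ms,
      stimulus_string = vapply(seq_len(n_trials), function(i)
        random_stimulus_string(string_len), character(1)),
      stringsAsFactors = FALSE))
  })
}

#' Simulate one subject's recording with one tracker
#'
#' Builds the subject's vergence trajectory `gamma(t)` as the baseline
#' vergence for fixation of the screen centre plus, in each trial, the
#' condition's response kernel scaled by the subject's amplitude factor.
#' The binocular geometry is then inverted: the eyes fixate a point on the
#' central normal whose depth yields `gamma(t)`, and each eye's line of
#' sight is intersected with the screen plane to obtain per-eye gaze
#' coordinates — so running the analysis geometry forward recovers
#' `gamma(t)` exactly in the noise-free case. Per-eye Gaussian gaze noise
#' (`noise_sd`, deg, converted to px through the geometry) is added, and
#' samples are marked invalid (validity code 4, both eyes) with
#' probability `dropout_prob`.
#'
#' @param params A [simulation_params()].
#' @param subject_id,tracker_id Identifiers; `tracker_id` must name an
#'   entry of `params$trackers`.
#' @param geometry A [geometry_config()].
#' @param events Optional [event_log()]; generated from `params` if
#'   `NULL`.
#' @param amp_factor Optional fixed subject amplitude factor; drawn from
#'   `exp(rnorm(1, 0, params$subject_sd))` if `NULL`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A list: `recording` ([gaze_recording()]), `events`
#'   ([event_log()]), `amp_factor`.
#' @export
simulate_subject <- function(params, subject_id, tracker_id,
                             geometry = geometry_config(), events = NULL,
                             amp_factor = NULL, seed = NULL) {
  spec <- params$trackers[[tracker_id]]
  if (is.null(spec))
    param_error("unknown tracker '%s' (have: %s)", tracker_id,
                paste(names(params$trackers), collapse = ", "))
  with_seed(seed, {
    if (is.null(events))
      events <- generate_paradigm(params$n_trials, params$p_target,
                                  params$mask_ms, params$stim_ms)
    if (is.null(amp_factor))
      amp_factor <- exp(stats::rnorm(1, 0, params$subject_sd))
    step <- 1000 / spec$rate
    duration <- nrow(events) * (params$mask_ms + params$stim_ms)
    t <- (0:floor((duration - 1e-9) / step)) * step
    gamma_base <- 2 * atan(geometry$ipd / (2 * geometry$viewing_distance)) *
      180 / pi
    increment <- numeric(length(t))
    for (i in seq_len(nrow(events))) {
      onset <- events$stimulus_onset[i]
      idx <- t >= onset & t < onset + params$stim_ms + params$mask_ms
      kern <- if (events$condition[i] == "target") params$target_kernel
              else params$distractor_kernel
      increment[idx] <- kernel_curve(kern, t[idx] - onset) * amp_factor
    }
    gamma <- gamma_base + increment
    # invert binocular geometry: fixation point on central normal at the
    # depth that subtends gamma; left-eye sight line meets the screen at
    # x = d*tan(gamma/2) - ipd/2 (mm from centre), right eye mirrored
    x_mm <- geometry$viewing_distance * tan(gamma / 2 * pi / 180) -
      geometry$ipd / 2
    noise_px <- spec$noise_sd * px_per_deg(geometry)
    n <- length(t)
    left_x <- mm_to_px_x(x_mm, geometry) + stats::rnorm(n, 0, noise_px)
    right_x <- mm_to_px_x(-x_mm, geometry) + stats::rnorm(n, 0, noise_px)
    left_y <- geometry$screen_h_px / 2 + stats::rnorm(n, 0, noise_px)
    right_y <- geometry$screen_h_px / 2 + stats::rnorm(n, 0, noise_px)
    invalid <- stats::runif(n) < spec$dropout_prob
    code <- ifelse(invalid, 4L, 0L)
    rec <- gaze_recording(subject_id, tracker_id, spec$rate,
                          data.frame(t = t,
                                     left_x = left_x, left_y = left_y,
                                     right_x = right_x, right_y = right_y,
                                     valid_left = code, valid_right = code))
    list(recording = rec, events = events, amp_factor = amp_factor)
  })
}

#' Simulate a full cohort recorded with every tracker
#'
#' Each subject gets one event log and one amplitude factor, then is
#' "recorded" independently by every tracker in `params$trackers` against
#' that same event log. The returned ground-truth table holds each
#' subject's true amplitudes for parameter-recovery checks.
#'
#' @param params A [simulation_params()]; `params$seed` (if non-`NULL`)
#'   makes the cohort bit-reproducible.
#' @param geometry A [geometry_config()].
#' @return An object of class `"vergence_cohort"`: `recordings` (nested
#'   list `[[subject_id]][[tracker_id]]`), `events` (list by subject),
#'   `ground_truth` (data.frame: subject_id, amp_factor,
#'   target_peak_amp, distractor_peak_amp), `params`, `geometry`.
#' @export
simulate_cohort <- function(params = simulation_params(),
                            geometry = geometry_config()) {
  with_seed(params$seed, {
    ids <- sprintf("S%02d", seq_len(params$n_subjects))
    recordings <- list()
    events <- list()
    amp <- numeric(params$n_subjects)
    for (i in seq_along(ids)) {
      ev <- generate_paradigm(params$n_trials, params$p_target,
                              params$mask_ms, params$stim_ms)
      amp[i] <- exp(stats::rnorm(1, 0, params$subject_sd))
      recordings[[ids[i]]] <- lapply(params$trackers, function(spec) NULL)
      for (tr in names(params$trackers)) {
        recordings[[ids[i]]][[tr]] <-
          simulate_subject(params, ids[i], tr, geometry,
                           events = ev, amp_factor = amp[i])$recording
      }
      events[[ids[i]]] <- ev
    }
    gt <- data.frame(
      subject_id = ids, amp_factor = amp,
      target_peak_amp = amp * params$target_kernel$peak_amp,
      distractor_peak_amp = amp * params$distractor_kernel$peak_amp,
      stringsAsFactors = FALSE)
    structure(list(recordings = recordings, events = events,
                   ground_truth = gt, params = params, geometry = geometry),
              class = "vergence_cohort")
  })
}

#' @export
print.vergence_cohort <- function(x, ...) {
  cat(sprintf("Simulated oddball cohort: %d subjects x %d trackers (%s), %d trials each\n",
              length(x$recordings), length(x$params$trackers),
              paste(names(x$params$trackers), collapse = ", "),
              x$params$n_trials))
  invisible(x)
}
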