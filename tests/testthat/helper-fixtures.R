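# Fixtures built in code: tiny recordings, event logs and curves.

tiny_geometry <- function() geometry_config()

# recording sampled exactly on a uniform grid, all valid, fixating the
# screen centre (constant baseline vergence) unless gamma_fun is given
make_recording <- function(n = 10, rate = 30, subject = "S01",
                           tracker = "T1", valid = 0L) {
  t <- (seq_len(n) - 1) * 1000 / rate
  g <- tiny_geometry()
  cx <- g$screen_w_px / 2
  data.frame(t = t, left_x = cx, left_y = g$screen_h_px / 2,
             right_x = cx, right_y = g$screen_h_px / 2,
             valid_left = valid, valid_right = valid) |>
    (\(df) gaze_recording(subject, tracker, rate, df))()
}

make_events <- function(n_trials = 3, mask_ms = 2000, stim_ms = 2000,
                        conditions = NULL) {
  if (is.null(conditions))
    conditions <- rep(c("distractor", "target"), length.out = n_trials)
  mo <- (seq_len(n_trials) - 1) * (mask_ms + stim_ms)
  event_log(data.frame(trial_index = seq_len(n_trials),
                       condition = conditions,
                       mask_onset = mo, stimulus_onset = mo + mask_ms,
                       mask_duration = mask_ms, stimulus_duration = stim_ms,
                       stimulus_string = strrep("x", 11)))
}

# a modulation_curve-shaped object with arbitrary values (for window ops)
make_curve <- function(t_rel, v, condition = "target") {
  structure(list(t_rel = t_rel, v = v, gamma0 = 0, norm_max = 1,
                 condition = condition, n_trials = 1L),
            class = "modulation_curve")
}

# small cohort for pipeline tests: 2 subjects, both default trackers
small_params <- function(seed = 11, n_subjects = 2)
  simulation_params(n_subjects = n_subjects, seed = seed)
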