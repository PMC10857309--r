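test_that("paradigm generation fixes counts, cadence and seeding", {
  ev <- generate_paradigm(seed = 4)
  expect_equal(nrow(ev), 100)
  expect_equal(sum(ev$condition == "target"), 20)
  expect_equal(sum(ev$condition == "distractor"), 80)
  expect_equal(ev$stimulus_onset, ev$mask_onset + ev$mask_duration)
  expect_true(all(diff(ev$mask_onset) == 4000))
  expect_true(all(nchar(ev$stimulus_string) == 11))
  # exact counts at other sizes
  ev5 <- generate_paradigm(n_trials = 5, p_target = 0.2, seed = 1)
  expect_equal(sum(ev5$condition == "target"), 1)
  # same seed -> identical; different seed -> same counts, other order
  expect_identical(generate_paradigm(seed = 4), ev)
  ev2 <- generate_paradigm(seed = 5)
  expect_equal(sum(ev2$condition == "target"), 20)
  expect_false(identical(ev2$condition, ev$condition))
  expect_error(generate_paradigm(p_target = 1.2),
               class = "cogvergence_parameter_error")
})

test_that("response kernel has the designed shape", {
  k <- response_kernel(peak_amp = 0.3, delay_amp = 0.12)
  t <- seq(-200, 2000, by = 1)
  y <- kernel_curve(k, t)
  expect_true(all(y[t < 300] == 0))          # silent before latency
  expect_equal(kernel_curve(k, 450), 0.3)    # peak value by construction
  expect_equal(max(y), 0.3, tolerance = 1e-9)
  expect_equal(t[which.max(y)], 450)
  # continuous everywhere (no jump exceeds the 1 ms local slope scale)
  expect_lt(max(abs(diff(y))), 0.01)
  # sustained component persists through 1250 ms then relaxes toward 0
  expect_gt(kernel_curve(k, 1250), 0.9 * k$delay_amp)
  expect_lt(kernel_curve(k, 2000), kernel_curve(k, 1250))
  # zero-amplitude kernel is identically zero
  k0 <- response_kernel(peak_amp = 0, delay_amp = 0)
  expect_true(all(kernel_curve(k0, t) == 0))
})

test_that("noise-free simulation inverts the analysis geometry exactly", {
  quiet <- simulation_params(
    n_subjects = 1, n_trials = 4,
    target_kernel = response_kernel(peak_amp = 0, delay_amp = 0),
    distractor_kernel = response_kernel(peak_amp = 0, delay_amp = 0),
    subject_sd = 0,
    trackers = list(ET = tracker_spec(30, noise_sd = 0, dropout_prob = 0)))
  sim <- simulate_subject(quiet, "S01", "ET", seed = 2)
  g <- geometry_config()
  gamma <- with(sim$recording$samples,
                vergence_angle(gaze_to_azimuth(left_x, -g$ipd / 2, g),
                               gaze_to_azimuth(right_x, +g$ipd / 2, g)))
  gamma_base <- 2 * atan(g$ipd / (2 * g$viewing_distance)) * 180 / pi
  expect_true(all(abs(gamma - gamma_base) < 1e-9))
  expect_equal(count_invalid(sim$recording$samples), 0)
  expect_error(simulate_subject(quiet, "S01", "XX"),
               class = "cogvergence_parameter_error")
})

test_that("dropout rate yields the analytically expected trial exclusion", {
  params <- simulation_params(n_subjects = 4, seed = 91)
  epochs <- list()
  cohort <- simulate_cohort(params)
  for (sid in names(cohort$recordings))
    epochs <- c(epochs, epoch_trials(cohort$recordings[[sid]]$ET,
                                     cohort$events[[sid]]))
  n_tr <- length(epochs)
  rate <- exclusion_rate(epochs)
  # binomial oracle: a 66-sample epoch at per-sample dropout p is excluded
  # with probability P(Binom(66, p) >= 15); check the empirical rate
  # against the binomial 95% CI around that expectation
  p_excl <- 1 - pbinom(14, 66, params$trackers$ET$dropout_prob)
  ci <- qbinom(c(0.025, 0.975), n_tr, p_excl) / n_tr
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("cohort structure, totals and reproducibility", {
  params <- simulation_params(n_subjects = 3, n_trials = 10, seed = 12)
  co <- simulate_cohort(params)
  expect_length(co$recordings, 3)
  expect_named(co$recordings$S01, c("ET", "WC"))
  expect_equal(nrow(co$ground_truth), 3)
  expect_equal(co$ground_truth$target_peak_amp,
               co$ground_truth$amp_factor * 0.3)
  co2 <- simulate_cohort(params)
  expect_identical(co$recordings$S02$WC$samples, co2$recordings$S02$WC$samples)
  expect_identical(co$ground_truth, co2$ground_truth)
  # full design: 28 subjects x 100 trials -> 2240 distractor, 560 target
  set.seed(6)
  conds <- unlist(lapply(1:28, function(i)
    generate_paradigm(100, 0.2)$condition))
  expect_equal(sum(conds == "distractor"), 2240)
  expect_equal(sum(conds == "target"), 560)
})

test_that("more tracker noise spreads the window means further", {
  # measured on target trials: their 0.3 deg transient dominates at low
  # noise, so the across-trial SD of normalized window means grows with
  # noise_sd (distractor V(t) is noise-dominated at every level and its
  # SD saturates — a consequence of the per-trial normalization)
  for (seed in c(55, 56)) {
    grid_sd <- vapply(c(0.02, 0.1, 0.3), function(ns) {
      params <- simulation_params(
        n_subjects = 1, n_trials = 60, subject_sd = 0,
        trackers = list(T1 = tracker_spec(30, noise_sd = ns,
                                          dropout_prob = 0)))
      sim <- simulate_subject(params, "S01", "T1", seed = seed)
      epochs <- epoch_trials(sim$recording, sim$events)
      pk <- vapply(Filter(function(e) !e$excluded &&
                            e$condition == "target", epochs), function(e) {
        cu <- relative_modulation(e$gamma, e$t_rel)
        window_mean(cu, c(400, 433))
      }, numeric(1))
      sd(pk)
    }, numeric(1))
    expect_true(all(diff(grid_sd) > 0))
  }
})
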