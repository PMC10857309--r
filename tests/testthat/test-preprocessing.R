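test_that("segmentation slices trials and conserves their number", {
  params <- simulation_params(n_subjects = 1)
  sim <- simulate_subject(params, "S01", "WC", seed = 21)
  slices <- segment_trials(sim$recording, sim$events, c(-200, 2000))
  expect_length(slices, 100)
  # half-open (0, 2000) window at 30 Hz holds 60 samples
  s60 <- segment_trials(sim$recording, sim$events, c(0, 2000))
  expect_true(all(vapply(s60, function(s) nrow(s$samples), integer(1)) == 60))
  # retained + excluded = number of events, whatever the dropout pattern
  epochs <- epoch_trials(sim$recording, sim$events)
  expect_equal(sum(vapply(epochs, `[[`, logical(1), "excluded")) +
                 sum(!vapply(epochs, `[[`, logical(1), "excluded")),
               nrow(sim$events))
})

test_that("trials beyond the recording end are flagged", {
  rec <- make_recording(30)           # ~1 s of data
  ev <- make_events(1)                # stimulus onset at 2000 ms
  slices <- segment_trials(rec, ev, c(-200, 2000))
  expect_true(slices[[1]]$truncated)
  expect_true(slices[[1]]$excluded)   # nothing at/after onset-200 -> no data
  expect_identical(slices[[1]]$reason, "no data")
})

test_that("invalid samples are counted as the union over eyes", {
  s <- make_recording(20)$samples
  s$valid_left[1:3] <- 4L             # left-only invalid
  s$valid_right[4:5] <- 2L            # right-only invalid
  s$valid_left[6] <- 1L; s$valid_right[6] <- 1L   # both
  expect_equal(count_invalid(s), 6)   # union, not 7
  expect_equal(count_invalid(make_recording(5)$samples), 0)
  s2 <- make_recording(20)$samples
  s2$valid_left[1:14] <- 4L
  expect_equal(count_invalid(s2), 14)
})

test_that("exclusion threshold boundary is exact and monotone", {
  expect_false(exclude_trial(0))
  expect_false(exclude_trial(14))
  expect_true(exclude_trial(15))
  expect_true(exclude_trial(40))
  n <- 0:40
  expect_true(all(diff(exclude_trial(n)) >= 0))  # monotone in n_invalid
  expect_true(exclude_trial(5, threshold = 5))
})

test_that("interpolation is linear, clamped, and the identity on clean grids", {
  # hand oracle: valid points (t=0, x=0) and (t=100, x=10), step 50
  sl <- list(stimulus_onset = 0, samples = data.frame(
    t = c(0, 100), left_x = c(0, 10), left_y = 0, right_x = c(0, 10),
    right_y = 0, valid_left = 0L, valid_right = 0L))
  out <- interpolate_uniform(sl, rate = 20, epoch_window = c(0, 100))
  expect_equal(out$t_rel, c(0, 50, 100))
  expect_equal(out$left_x, c(0, 5, 10))

  # identity on already-uniform fully-valid input
  rec <- make_recording(67)
  sl2 <- list(stimulus_onset = 200,
              samples = transform(rec$samples, left_x = seq_len(67)))
  out2 <- interpolate_uniform(sl2, 30, c(-200, 2000))
  obs_rel <- rec$samples$t - 200
  keep <- obs_rel >= -200 & obs_rel <= 2000
  expect_equal(out2$left_x[seq_len(sum(keep))], seq_len(67)[keep],
               tolerance = 1e-9)

  # clamped ends: grid points before the first valid sample take its value
  sl3 <- list(stimulus_onset = 0, samples = data.frame(
    t = c(100, 200), left_x = c(7, 9), left_y = 0, right_x = c(7, 9),
    right_y = 0, valid_left = 0L, valid_right = 0L))
  out3 <- interpolate_uniform(sl3, 10, c(0, 300))
  expect_equal(out3$left_x, c(7, 7, 9, 9))
  # interpolated values never leave the envelope of the valid neighbours
  expect_true(all(out3$left_x >= 7 & out3$left_x <= 9))

  # fewer than 2 valid samples -> no grid
  sl4 <- sl3
  sl4$samples$valid_left <- c(0L, 4L)
  expect_null(interpolate_uniform(sl4, 10, c(0, 300)))
})

test_that("epoch_trials excludes on threshold and insufficient data", {
  rec <- make_recording(200, tracker = "ET")
  rec$samples$valid_left[10:40] <- 4L   # >= 15 invalid in first epoch
  ev <- make_events(1, mask_ms = 0, stim_ms = 2000)
  epochs <- epoch_trials(rec, ev, epoch_window = c(0, 2000))
  expect_true(epochs[[1]]$excluded)
  expect_identical(epochs[[1]]$reason, "too many invalid samples")
  qc <- qc_table(epochs)
  expect_identical(names(qc), c("subject", "tracker", "trial", "condition",
                                "n_invalid", "excluded", "reason"))
  expect_equal(qc$n_invalid[1], 31)
})

test_that("exclusion rate is the excluded fraction", {
  mk <- function(excl) structure(list(excluded = excl), class = "trial_epoch")
  expect_equal(exclusion_rate(list(mk(TRUE), mk(FALSE), mk(FALSE))), 1 / 3,
               tolerance = 1e-12)
  expect_equal(exclusion_rate(list(mk(FALSE), mk(FALSE))), 0)
  expect_equal(exclusion_rate(list(mk(TRUE), mk(TRUE))), 1)
  expect_error(exclusion_rate(list()), class = "cogvergence_input_error")
})
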