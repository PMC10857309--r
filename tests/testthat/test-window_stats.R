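test_that("window_mean averages closed-interval grid points", {
  grid <- seq(0, 1000, by = 100)
  cu <- make_curve(grid, grid / 1000)
  expect_equal(window_mean(cu, c(0, 200)), mean(c(0, 0.1, 0.2)))
  # constant curve -> the constant, over any window
  cc <- make_curve(grid, rep(0.7, length(grid)))
  expect_equal(window_mean(cc, c(300, 800)), 0.7)
  # 30 Hz grid: the 400-433 ms peak window holds exactly one point (400 ms)
  g30 <- seq(0, 2000, by = 1000 / 30)
  c30 <- make_curve(g30, sin(g30 / 300))
  in_peak <- g30 >= 400 - 1e-9 & g30 <= 433 + 1e-9
  expect_equal(sum(in_peak), 1)
  expect_equal(window_mean(c30, c(400, 433)), sin(400 / 300))
  # empty window errors, naming the bounds
  expect_error(window_mean(cu, c(150.1, 199.9)), "150.1",
               class = "cogvergence_window_error")
})

test_that("window_mean over adjacent windows composes by point count", {
  set.seed(7)
  grid <- seq(0, 990, by = 33)
  cu <- make_curve(grid, rnorm(length(grid)))
  w1 <- c(0, 300); w2 <- c(301, 700)
  n1 <- sum(grid >= w1[1] & grid <= w1[2])
  n2 <- sum(grid > w1[2] & grid <= w2[2])
  expect_equal(window_mean(cu, c(0, 700)),
               (n1 * window_mean(cu, w1) + n2 * window_mean(cu, w2)) /
                 (n1 + n2), tolerance = 1e-12)
})

test_that("modulation index algebra", {
  expect_equal(modulation_index(0.5, 0.5), 0)
  expect_equal(modulation_index(0.3, 0), 1)
  # arithmetic on the published webcam peak means
  expect_equal(modulation_index(0.036, -0.013), 0.049 / 0.023)
  expect_equal(modulation_index(0.036, -0.013), 2.1304, tolerance = 1e-4)
  # scale invariance and antisymmetry
  set.seed(9)
  for (i in 1:25) {
    T <- rnorm(1); D <- rnorm(1); a <- runif(1, 0.01, 100)
    if (abs(T + D) < 1e-6) next
    expect_equal(modulation_index(a * T, a * D), modulation_index(T, D),
                 tolerance = 1e-9)
    expect_equal(modulation_index(D, T), -modulation_index(T, D),
                 tolerance = 1e-12)
  }
  # undefined when T + D vanishes: NA with a warning
  expect_warning(res <- modulation_index(0.4, -0.4))
  expect_true(is.na(res))
})

test_that("subject summary matches the brute-force definition", {
  win <- window_definition()
  grid <- seq(-200, 2000, by = 1000 / 30)
  set.seed(13)
  for (rep in 1:10) {
    tc <- lapply(1:3, function(i) make_curve(grid, rnorm(length(grid)), "target"))
    dc <- lapply(1:3, function(i) make_curve(grid, rnorm(length(grid)),
                                             "distractor"))
    s <- subject_modulation_index(tc, dc, win, "S01", "ET")
    # brute force: average per-trial window means, then the index
    wm <- function(cu) mean(cu$v[grid >= 300 - 1e-9 & grid <= 600 + 1e-9])
    T_b <- mean(vapply(tc, wm, numeric(1)))
    D_b <- mean(vapply(dc, wm, numeric(1)))
    expect_equal(s$T, T_b, tolerance = 1e-12)
    expect_equal(s$D, D_b, tolerance = 1e-12)
    expect_equal(s$mi, (T_b - D_b) / (T_b + D_b), tolerance = 1e-12)
  }
  # identical trials across conditions -> mi exactly 0
  same <- lapply(1:3, function(i) make_curve(grid, sin(grid / 500)))
  expect_equal(subject_modulation_index(same, same, win)$mi, 0)
  # constant separated conditions -> mi 1
  tgt <- list(make_curve(grid, rep(0.5, length(grid))))
  dis <- list(make_curve(grid, rep(0, length(grid))))
  s2 <- subject_modulation_index(tgt, dis, win)
  expect_equal(c(s2$T, s2$D, s2$mi), c(0.5, 0, 1))
  # a condition with no retained trials yields a reasoned missing mi
  s3 <- subject_modulation_index(list(), dis, win)
  expect_true(is.na(s3$mi))
  expect_match(s3$reason, "target")
})

test_that("response slope recovers linear trends by OLS", {
  grid <- seq(0, 1250, by = 1000 / 30)
  cu <- make_curve(grid, 2 + 0.001 * grid)
  expect_equal(response_slope(cu, c(0, 1250)), 0.001, tolerance = 1e-12)
  expect_equal(response_slope(make_curve(grid, rep(1, length(grid))),
                              c(0, 1250)), 0, tolerance = 1e-12)
  # sampling-distribution oracle: estimate within 3 SE of the truth
  set.seed(31)
  t60 <- seq(0, 1966, length.out = 60)
  noise_sd <- 1e-3
  v <- 3e-5 * t60 + rnorm(60, 0, noise_sd)
  est <- response_slope(make_curve(t60, v), c(0, 2000))
  se <- noise_sd / sqrt(sum((t60 - mean(t60))^2))
  expect_lt(abs(est - 3e-5), 3 * se)
  expect_error(response_slope(cu, c(10, 20)),
               class = "cogvergence_window_error")
})

test_that("two-tailed t matches closed forms and the degenerate contract", {
  # textbook closed form on 2-point samples: t = (ma - mb)/sqrt(sa2/2 + sb2/2)
  a <- c(1, 3); b <- c(6, 10)
  ref <- (mean(a) - mean(b)) / sqrt(var(a) / 2 + var(b) / 2)
  expect_equal(two_tailed_t(a, b)$t, ref, tolerance = 1e-10)
  expect_equal(two_tailed_t(a, b, var_equal = TRUE)$t, ref, tolerance = 1e-10)
  # identical samples; paired identical samples
  expect_equal(two_tailed_t(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  expect_equal(two_tailed_t(c(1, 2, 3), c(1, 2, 3), paired = TRUE)[c("t", "p")],
               list(t = 0, p = 1))
  # near-complete separation drives |t| large and p tiny
  set.seed(17)
  a2 <- rnorm(4, 0, 1e-9); b2 <- 1 + rnorm(5, 0, 1e-9)
  res <- two_tailed_t(a2, b2)
  expect_gt(abs(res$t), 1e6)
  expect_lt(res$p, 1e-6)
  # zero variance, unequal means
  res2 <- two_tailed_t(c(1, 1), c(2, 2))
  expect_identical(res2$t, -Inf)
  expect_identical(res2$p, 0)
  # paired comparison is the one-sample t on differences
  x <- c(1.2, 0.8, 1.9, 1.4); y <- c(0.9, 0.7, 1.1, 1.0)
  expect_equal(two_tailed_t(x, y, paired = TRUE)$t,
               unname(t.test(x - y)$statistic), tolerance = 1e-12)
  expect_error(two_tailed_t(1, c(1, 2)), class = "cogvergence_input_error")
})

test_that("sign quadrant counts tally mi sign combinations", {
  q <- sign_quadrant_counts(c(1, 2, 0.5), c(0.1, 3, 2), c("ET", "WC"))
  expect_equal(q$counts["ET+", "WC+"], 3)
  expect_equal(unname(q$frac_positive), c(1, 1))
  # one pair in each quadrant; zero counts as non-positive
  q2 <- sign_quadrant_counts(c(1, 1, -1, 0), c(1, -1, 1, -2))
  expect_equal(as.vector(q2$counts), c(1, 1, 1, 1))
  # brute-force tally over hand-assigned pairs, with missing pairs reported
  set.seed(23)
  a <- c(rnorm(10), NA, 0.4); b <- c(rnorm(10), 0.2, NA)
  q3 <- sign_quadrant_counts(a, b)
  cc <- !is.na(a) & !is.na(b)
  expect_equal(q3$n_complete, sum(cc))
  expect_equal(q3$n_missing, 2)
  expect_equal(q3$counts[1, 1], sum(a[cc] > 0 & b[cc] > 0))
  expect_equal(q3$counts[2, 2], sum(a[cc] <= 0 & b[cc] <= 0))
  expect_equal(sum(q3$counts), sum(cc))
})
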