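# period estimators: continuous reference and spectral baselines

test_that("continuous finite-extent estimate is exact for sinusoids", {
  e <- continuous_reference_estimate(4.3, 50, "finite")
  expect_true(e$valid)
  expect_lt(abs(e$period_px / 4.3 - 1), 1e-6)
  for (P in seq(3.5, 9.5, by = 1.5)) {
    e <- continuous_reference_estimate(P, 50, "finite")
    expect_lt(abs(e$period_px / P - 1), 1e-6)
  }
})

test_that("continuous estimates agree with the closed-form oracle", {
  for (method in c("finite", "acf", "acf_periodic")) {
    for (P in c(3.7, 5.2)) {
      mine <- continuous_reference_estimate(P, 40, method)
      ref <- oracle_continuous_estimate(P, 40, method)
      expect_equal(mine$period_px, ref, tolerance = 1e-6)
    }
  }
})

test_that("continuous ACF variants carry modulated boundary errors", {
  Ps <- seq(4, 9, by = 0.5)
  err_a <- vapply(Ps, function(P)
    continuous_reference_estimate(P, 50, "acf")$period_px / P - 1, numeric(1))
  err_p <- vapply(Ps, function(P)
    continuous_reference_estimate(P, 50, "acf_periodic")$period_px / P - 1,
    numeric(1))
  expect_gt(max(abs(err_a)), 1e-5)         # nonzero, unlike the finite method
  expect_gt(max(abs(err_p)), 1e-4)
  # periodic wrap mismatch under- and over-estimates as P varies
  expect_gt(sum(err_p > 1e-7), 0)
  expect_gt(sum(err_p < -1e-7), 0)
  # magnitude modulation: errors are far from constant across P
  expect_gt(max(abs(err_a)) / max(min(abs(err_a)), 1e-12), 5)
})

test_that("spectrum-peak estimator: on-bin exactness and flat input", {
  line <- make_sine_line(64, 8)
  for (w in c("none", "hann")) {
    e <- estimate_period_fft(line, 2, 31, window = w)
    expect_true(e$valid)
    expect_equal(e$period_px, 8, tolerance = 1e-9)
  }
  flat <- estimate_period_fft(rep(3, 40))
  expect_false(flat$valid)
  expect_identical(flat$contrast, 0)
})

test_that("spectrum-peak estimator matches an independent DFT oracle", {
  line <- make_sine_line(50, 4.3)
  for (w in c("hann", "none")) {
    mine <- estimate_period_fft(line, 2, 10, window = w)
    ref <- oracle_fft_estimate(line, 2, 10, window = w)
    expect_equal(mine$period_px, ref, tolerance = 1e-9)
  }
  # off-bin frequency: the refined estimate is close to but not exactly 4.3
  e <- estimate_period_fft(line, 2, 10)
  expect_gt(abs(e$period_px / 4.3 - 1), 1e-4)
  expect_lt(abs(e$period_px / 4.3 - 1), 0.05)
})

test_that("quadratic-ACF estimator: exact lag, flat input, oracle match", {
  e <- estimate_period_acf_quadratic(rep(c(0, 1, 0, -1), 12), 2, 10)
  expect_true(e$valid)
  expect_equal(e$period_px, 4, tolerance = 1e-9)

  expect_false(estimate_period_acf_quadratic(rep(0, 40))$valid)

  line <- make_sine_line(50, 4.3)
  mine <- estimate_period_acf_quadratic(line, 2, 10)
  ref <- oracle_acf_estimate(line, 2, 10)
  expect_equal(mine$period_px, ref, tolerance = 1e-9)
})

test_that("sum and per-line-mean agree on identical lines", {
  m <- matrix(rep(make_sine_line(54, 4.32), 31), nrow = 31, byrow = TRUE)
  e1 <- estimate_period(m, "finite", mode = "sum")
  e2 <- estimate_period(m, "finite", mode = "per_line_mean")
  expect_equal(e1$period_px, e2$period_px, tolerance = 1e-9)
  expect_identical(e2$n_lines, 31L)
})

test_that("per-line-mean excludes signal-free lines; sum stays valid", {
  base <- make_sine_line(54, 4.32)
  m <- rbind(matrix(rep(base, 26), 26, byrow = TRUE),
             matrix(0.5, 5, 54))
  e_sum <- estimate_period(m, "finite", mode = "sum")
  e_plm <- estimate_period(m, "finite", mode = "per_line_mean")
  expect_true(e_sum$valid)
  expect_true(e_plm$valid)
  expect_identical(e_plm$n_lines, 26L)
  expect_equal(e_sum$period_px, e_plm$period_px, tolerance = 1e-6)

  all_flat <- estimate_period(matrix(1, 4, 20), "finite",
                              mode = "per_line_mean")
  expect_false(all_flat$valid)
})

test_that("line superposition and per-line averaging differ on jittered ROIs", {
  m <- fixture_roi_lines()
  e1 <- estimate_period(m, "finite", mode = "sum")
  e2 <- estimate_period(m, "finite", mode = "per_line_mean")
  expect_lt(abs(e1$period_px / 4.32 - 1), 0.01)
  expect_lt(abs(e2$period_px / 4.32 - 1), 0.01)
  expect_false(identical(e1$period_px, e2$period_px))
  expect_lt(abs(e1$period_px - e2$period_px), 0.02)
})

test_that("detrending rescues ramp-dominated lines", {
  x <- 0.1 * make_sine_line(60, 5) + 0.05 * (0:59)
  with_dt <- estimate_period(x, "finite", detrend = TRUE, period_hint = 5)
  expect_true(with_dt$valid)
  expect_lt(abs(with_dt$period_px / 5 - 1), 0.005)
  without <- estimate_period(x, "finite", detrend = FALSE)
  biased <- !without$valid || abs(without$period_px / 5 - 1) > 0.005
  expect_true(biased)
})
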