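# core piecewise-cubic similarity machinery

test_that("finite measure of a constant line is identically zero", {
  cur <- build_similarity(rep(5, 10), "finite")
  expect_lt(max(abs(cur$coef)), 1e-12)
  expect_lt(max(abs(predict(cur, seq(0, 9, 0.1)))), 1e-12)
})

test_that("integer-periodic content gives an exact zero at the period", {
  cur <- build_similarity(rep(c(0, 1), 4), "finite")
  expect_lt(abs(predict(cur, 2)), 1e-12)

  cur48 <- build_similarity(rep(c(0, 1, 0, -1), 12), "finite")
  est <- locate_fundamental(cur48, 2, 10)
  expect_true(est$valid)
  expect_equal(est$period_px, 4, tolerance = 1e-9)
  expect_gte(est$contrast, 0.99)
})

test_that("curves match piecewise quadrature of the defining integrals", {
  set.seed(11)
  for (method in c("finite", "acf", "acf_periodic")) {
    f <- rnorm(30)
    cur <- build_similarity(f, method)
    ss <- runif(500, 0, cur$K)
    mine <- predict(cur, ss)
    ref <- vapply(ss, function(s) oracle_similarity(f, s, method), numeric(1))
    expect_lt(max(abs(mine - ref)) / max(abs(ref)), 1e-8)
  }
})

test_that("curve invariants: node continuity, nonnegativity, periodicity", {
  for (seed in 1:5) {
    set.seed(seed)
    f <- rnorm(24)
    for (method in c("finite", "acf", "acf_periodic")) {
      cur <- build_similarity(f, method)
      k <- seq_len(cur$K - 1)
      left <- predict(cur, k - 1e-12)
      right <- predict(cur, k + 1e-12)
      scale <- 1 + max(abs(cur$coef))
      expect_lt(max(abs(left - right)), 1e-9 * scale)
    }
    fin <- build_similarity(f, "finite")
    ss <- seq(0, fin$K, by = 0.05)
    expect_lt(abs(predict(fin, 0)), 1e-12)
    expect_gte(min(predict(fin, ss)), -1e-12 * max(abs(predict(fin, ss))))
    per <- build_similarity(f, "acf_periodic")
    s1 <- seq(0.1, 11.9, by = 0.37)
    expect_equal(predict(per, s1),
                 predict(per, (s1 + length(f)) %% length(f)),
                 tolerance = 1e-9)
  }
})

test_that("finite measure is offset- and reversal-invariant; ACF is not", {
  set.seed(3)
  f <- rnorm(20)
  a <- build_similarity(f, "finite")
  b <- build_similarity(f + 7.5, "finite")
  expect_equal(a$coef, b$coef, tolerance = 1e-9)
  r <- build_similarity(rev(f), "finite")
  expect_equal(a$coef, r$coef, tolerance = 1e-9)

  a2 <- build_similarity(f, "acf")
  b2 <- build_similarity(f + 7.5, "acf")
  expect_gt(max(abs(a2$coef - b2$coef)), 1)
  a3 <- build_similarity(f, "acf_periodic")
  b3 <- build_similarity(f + 7.5, "acf_periodic")
  expect_gt(max(abs(a3$coef - b3$coef)), 1)
})

test_that("curve accumulation is exactly linear", {
  set.seed(7)
  f1 <- rnorm(25)
  f2 <- rnorm(25)
  c1 <- build_similarity(f1, "finite")
  c2 <- build_similarity(f2, "finite")
  m5 <- accumulate_curves(rep(list(c1), 5))
  expect_equal(m5$coef, 5 * c1$coef, tolerance = 1e-12)

  zero <- build_similarity(rep(0, 25), "finite")
  expect_equal(accumulate_curves(list(c1, zero))$coef, c1$coef)

  both <- accumulate_curves(list(c1, c2))
  ss <- seq(0.1, 23.9, length.out = 100)
  expect_equal(predict(both, ss), predict(c1, ss) + predict(c2, ss),
               tolerance = 1e-12)
})

test_that("monotone curves yield no (valid) fundamental period", {
  ramp <- seq(0, 5, length.out = 40)
  est <- locate_fundamental(build_similarity(ramp, "finite"), 2, 19)
  expect_false(est$valid)
  expect_true(is.na(est$period_px))
  expect_identical(est$contrast, 0)
})

test_that("sampled sinusoid near 4.3 px is recovered within 1%", {
  est <- locate_fundamental(build_similarity(make_sine_line(50, 4.3), "finite"),
                            2, 10)
  expect_true(est$valid)
  expect_lt(abs(est$period_px / 4.3 - 1), 0.01)
  # estimate stays inside the search bounds
  expect_gte(est$period_px, 2)
  expect_lte(est$period_px, 10)
})

test_that("normalized finite variant keeps exact periodic minima in place", {
  f <- rep(c(0, 1, 0, -1), 12)
  raw <- estimate_period(f, "finite", s_min = 2, s_max = 10)
  nrm <- estimate_period(f, "finite", s_min = 2, s_max = 10, normalize = TRUE)
  expect_equal(raw$period_px, 4, tolerance = 1e-9)
  expect_equal(nrm$period_px, 4, tolerance = 1e-6)
})

test_that("input and compatibility errors are classed", {
  expect_error(build_similarity(c(1, 2, 3), "finite"),
               class = "sarclen_input_too_short")
  expect_error(build_similarity(c(1, NA, 3, 4), "finite"),
               class = "sarclen_bad_input")
  c1 <- build_similarity(rnorm(10), "finite")
  c2 <- build_similarity(rnorm(10), "acf")
  c3 <- build_similarity(rnorm(12), "finite")
  expect_error(accumulate_curves(list(c1, c2)),
               class = "sarclen_incompatible_curves")
  expect_error(accumulate_curves(list(c1, c3)),
               class = "sarclen_incompatible_curves")
})
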