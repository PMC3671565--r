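# ROI extraction, orientation correction, sensitivity maps, tracing

test_that("axis-aligned integer ROI extraction is an exact copy", {
  set.seed(1)
  img <- matrix(rnorm(30 * 40), 30, 40)
  r <- roi(c(15, 20), 7, 11, angle_deg = 0)
  expect_identical(extract_roi(img, r), img[12:18, 15:25])
})

test_that("bilinear sampling reproduces affine intensity fields exactly", {
  img <- outer(1:40, 1:50, function(r, c) 2 * r + 3 * c - 1)
  for (ang in c(0, 12.5, -30)) {
    r <- roi(c(20.3, 25.7), 9, 15, angle_deg = ang)
    got <- extract_roi(img, r)
    g <- sarclen:::roi_sample_coords(img, r)
    expect_equal(got, 2 * g$row + 3 * g$col - 1, tolerance = 1e-12)
  }
  expect_error(extract_roi(img, roi(c(2, 3), 9, 15)),
               class = "sarclen_out_of_bounds")
})

test_that("a tilted ROI on straight striations reads P / cos(theta)", {
  spec <- striation_spec(width = 96, height = 64, period_px = 4.32)
  img <- make_striation_image(spec)
  r <- roi(c(32.5, 48.5), 21, 48, angle_deg = 10)
  e <- estimate_period(extract_roi(img, r), "finite", detrend = TRUE)
  expect_true(e$valid)
  expect_lt(abs(e$period_px / (4.32 / cos(10 * pi / 180)) - 1), 0.005)
})

test_that("orientation scan recovers the striation orientation", {
  spec <- striation_spec(width = 110, height = 80, period_px = 4.32,
                         orientation_deg = 4.72)
  img <- make_striation_image(spec)
  sc <- orientation_scan(img, roi(c(40.5, 55.5), 21, 48), seq(-10, 10, 1),
                         method = "finite", detrend = TRUE)
  # residual pixelation bias at ~4.3 px/period limits the recovery to
  # about half a degree / half a percent (see the methods vignette)
  expect_lt(abs(sc$alpha0_deg - 4.72), 0.75)
  expect_lt(abs(sc$corrected_sl_px / 4.32 - 1), 0.006)
  expect_equal(cos(sc$alpha0_deg * pi / 180), 0.997, tolerance = 2e-3)
  expect_identical(nrow(tidy(sc)), 21L)
  expect_identical(glance(sc)$n_valid, 21L)
})

test_that("orientation scan is symmetric for aligned striations", {
  spec <- striation_spec(width = 110, height = 80, period_px = 4.5,
                         orientation_deg = 0)
  img <- make_striation_image(spec)
  sc <- orientation_scan(img, roi(c(40.5, 55.5), 21, 48), seq(-8, 8, 2),
                         method = "finite", detrend = TRUE)
  s <- sc$samples
  sl <- setNames(s$sl_px, as.character(s$angle_deg))
  for (a in c(2, 4, 6, 8)) {
    expect_equal(sl[[as.character(a)]], sl[[as.character(-a)]],
                 tolerance = 0.01)
  }
  expect_lt(abs(sc$alpha0_deg), 0.75)
  expect_lte(min(s$sl_px), sl[["0"]] * 1.001)
})

test_that("orientation scan recovers alpha0 under noise", {
  spec <- striation_spec(width = 110, height = 80, period_px = 4.32,
                         orientation_deg = 4.72, amplitude = 0.3,
                         noise_sigma = 0.006, seed = 31)
  img <- make_striation_image(spec)
  sc <- orientation_scan(img, roi(c(40.5, 55.5), 41, 56), seq(-10, 10, 1),
                         method = "finite", detrend = TRUE)
  expect_lt(abs(sc$alpha0_deg - 4.72), 0.75)
})

test_that("the P/cos orientation model holds on noise-free striations", {
  spec <- striation_spec(width = 120, height = 90, period_px = 4.32,
                         orientation_deg = 3)
  img <- make_striation_image(spec)
  angles <- seq(-7, 13, by = 2)            # |alpha - alpha0| <= 10 deg
  sl <- vapply(angles, function(a) {
    estimate_period(extract_roi(img, roi(c(45.5, 60.5), 21, 48, a)),
                    "finite", detrend = TRUE)$period_px
  }, numeric(1))
  flat <- sl * cos((angles - 3) * pi / 180)
  # constant up to the pixelation modulation of the per-angle estimates
  expect_lt((max(flat) - min(flat)) / mean(flat), 0.0075)
})

test_that("homogeneous striations give a position-insensitive map", {
  spec <- striation_spec(width = 90, height = 40, period_px = 4.32)
  img <- make_striation_image(spec)
  sm <- sensitivity_map(img, 11, 36, stride = 4, method = "finite",
                        detrend = TRUE, pixel_size_um = 0.411)
  expect_s3_class(sm, "sl_map")
  expect_true(all(sm$valid))
  spread <- (max(sm$sl_px) - min(sm$sl_px)) / mean(sm$sl_px)
  expect_lt(spread, 0.01)
  expect_equal(sm$sl_um, sm$sl_px * 0.411)
})

test_that("signal-free bands are masked invalid in the map", {
  spec <- striation_spec(width = 100, height = 30, period_px = 4.32)
  img <- make_striation_image(spec)
  img[, 41:60] <- 0.5                      # zero-amplitude fiber band
  sm <- sensitivity_map(img, 9, 14, stride = 3, method = "finite",
                        detrend = TRUE)
  inside <- sm$center_col >= 48 & sm$center_col <= 53
  outside <- sm$center_col <= 30 | sm$center_col >= 72
  expect_true(all(!sm$valid[inside]))
  expect_true(all(sm$valid[outside]))
})

test_that("the map resolves regional heterogeneity; large ROIs average it", {
  s1 <- striation_spec(width = 60, height = 40, period_px = 4.2)
  s2 <- striation_spec(width = 60, height = 40, period_px = 4.6)
  img <- cbind(make_striation_image(s1), make_striation_image(s2))
  sm <- sensitivity_map(img, 11, 24, stride = 6, method = "finite",
                        detrend = TRUE)
  left <- sm$valid & sm$center_col <= 40
  right <- sm$valid & sm$center_col > 80
  expect_lt(abs(mean(sm$sl_px[left]) / 4.2 - 1), 0.015)
  expect_lt(abs(mean(sm$sl_px[right]) / 4.6 - 1), 0.015)

  wide <- estimate_period(extract_roi(img, roi(c(20.5, 60.5), 21, 96)),
                          "finite", detrend = TRUE)
  expect_gt(wide$period_px, 4.25)
  expect_lt(wide$period_px, 4.55)
})

test_that("3-point rates: exact for linear and quadratic, NA propagation", {
  dt <- 0.005
  j <- 0:20
  expect_equal(rate_3pt(3 * j * dt, dt), rep(3, 21))
  sl <- (j * dt)^2
  r <- rate_3pt(sl, dt)
  expect_equal(r[2:20], 2 * j[2:20] * dt, tolerance = 1e-12)
  expect_equal(rate_3pt(c(1.8, 1.7, 1.6), dt)[2], -20)
  r2 <- rate_3pt(c(1, 2, NA, 4, 5), 1)
  expect_true(is.na(r2[2]) && is.na(r2[4]))   # NA neighbour propagates
  expect_identical(r2[3], 1)                  # both neighbours valid
  expect_identical(r2[1], 1)
  expect_error(rate_3pt(1:5, 0), class = "sarclen_bad_input")
})

test_that("pixel-to-micrometer conversion", {
  expect_equal(px_to_um(4.32, 0.411), 1.775, tolerance = 1e-3)
  expect_identical(px_to_um(0, 0.411), 0)
  expect_identical(px_to_um(3.3, 1), 3.3)
  expect_error(px_to_um(-1, 0.4), class = "sarclen_bad_input")
})

test_that("static stacks trace to a constant length with zero rate", {
  spec <- striation_spec(width = 60, height = 24, period_px = 4.32)
  frame <- make_striation_image(spec)
  tr <- trace_timeseries(rep(list(frame), 6), roi(c(12.5, 30.5), 11, 44),
                         method = "finite", detrend = TRUE)
  expect_true(all(tr$valid))
  expect_equal(diff(range(tr$sl_px)), 0)
  expect_equal(tr$rate_um_s, rep(0, 6))
  expect_equal(tr$sl_um, tr$sl_px * 0.411)
})

test_that("a fully occluded frame is invalid without harming neighbours", {
  spec <- striation_spec(width = 60, height = 24, period_px = 4.32)
  frame <- make_striation_image(spec)
  blank <- matrix(0.5, 24, 60)
  tr <- trace_timeseries(list(frame, blank, frame),
                         roi(c(12.5, 30.5), 11, 44),
                         method = "finite", detrend = TRUE)
  expect_identical(tr$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(tr$sl_um[2]))
  expect_false(anyNA(tr$sl_px[c(1, 3)]))
})

test_that("twitch stacks are traced within 1%; FFT baseline plateaus", {
  spec <- striation_spec(width = 72, height = 40, period_px = 4.35, seed = 7)
  stk <- make_contraction_stack(spec, frames = 80, t_on = 0.05)
  Pt <- attr(stk, "P_t")
  r <- roi(c(20.5, 36.5), 31, 54)
  tr <- trace_timeseries(stk, r, method = "finite", detrend = TRUE)
  expect_true(all(tr$valid))
  expect_lt(max(abs(tr$sl_px / Pt - 1)), 0.01)

  trf <- trace_timeseries(stk, r, method = "fft_spectrum", detrend = TRUE)
  runs <- rle(round(trf$sl_px, 3))
  expect_gte(max(runs$lengths), 3)

  # integrating the 3-point rate recovers the net length change, O(dt^2)
  mid <- 2:(nrow(tr) - 1)
  net <- sum(tr$rate_um_s[mid]) * attr(tr, "frame_interval_s")
  truth <- (tail(tr$sl_um, 2)[1] + tail(tr$sl_um, 1) -
              tr$sl_um[1] - tr$sl_um[2]) / 2
  expect_equal(net, truth, tolerance = 1e-9)
})
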