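#' Sampled sinusoid line profile
#'
#' Generates `f_i = sin(2 pi i / P + phase)`, `i = 0, ..., N-1`: the
#' canonical test input for period estimators, with exactly known ground
#' truth.
#'
#' @param N Number of samples (>= 4).
#' @param P True period in pixels (> 0).
#' @param phase Phase offset in radians.
#' @return Numeric vector of length `N`.
#' @export
make_sine_line <- function(N, P, phase = 0) {
  N <- as.integer(N)
  if (is.na(N) || N < 4L) {
    abort("`N` must be an integer >= 4.", class = "sarclen_bad_input")
  }
  if (!(P > 0)) abort("`P` must be positive.", class = "sarclen_bad_input")
  sin(2 * pi * (0:(N - 1L)) / P + phase)
}

#' Specification of a synthetic striation image
#'
#' Collects every knob of the synthetic striation generator: geometry,
#' true period and orientation, waveform asymmetry, smooth background
#' trend, additive Gaussian noise and occluding dark bands (stand-ins for
#' carbon fibers).  Defaults emulate a transmission image of a rat
#' cardiomyocyte at 0.411 um per pixel: period 4.32 px (~1.78 um
#' sarcomeres), amplitude 0.3 about an offset of 0.5 so images stay in
#' `[0, 1]` for TIFF export.
#'
#' @param width,height Image size in pixels.
#' @param period_px True striation period P (>= 3 px).
#' @param orientation_deg True pattern orientation `alpha0` in degrees
#'   (0 = striations perpendicular to image rows, i.e. period read along
#'   a row).
#' @param amplitude Oscillation amplitude (> 0).
#' @param w2 Weight of the second harmonic (waveform asymmetry;
#'   0 = pure sinusoid).
#' @param offset Constant intensity offset.
#' @param trend_row,trend_col Polynomial background coefficients (degree
#'   <= 2, constant first) in the 0-based row / column index.
#' @param noise_sigma Standard deviation of additive Gaussian noise, in
#'   intensity units (>= 0).
#' @param occlusions List of `list(center, width, depth)` vertical dark
#'   bands: the oscillation amplitude is multiplied by
#'   `1 - depth * exp(-((col - center) / width)^2 / 2)`.
#' @param phase Phase offset in radians.
#' @param seed Integer seed making the noise reproducible.
#' @return A `striation_spec` object.
#' @export
striation_spec <- function(width = 64, height = 32, period_px = 4.32,
                           orientation_deg = 0, amplitude = 0.3, w2 = 0,
                           offset = 0.5, trend_row = NULL, trend_col = NULL,
                           noise_sigma = 0, occlusions = NULL, phase = 0,
                           seed = NULL) {
  if (!(period_px >= 3)) {
    abort("`period_px` must be >= 3 pixels.", class = "sarclen_bad_input")
  }
  if (!(noise_sigma >= 0)) {
    abort("`noise_sigma` must be >= 0.", class = "sarclen_bad_input")
  }
  if (!(amplitude > 0)) {
    abort("`amplitude` must be > 0.", class = "sarclen_bad_input")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         period_px = period_px, orientation_deg = orientation_deg,
         amplitude = amplitude, w2 = w2, offset = offset,
         trend_row = trend_row, trend_col = trend_col,
         noise_sigma = noise_sigma, occlusions = occlusions,
         phase = phase, seed = seed),
    class = "striation_spec"
  )
}

#' Synthetic striation image with known ground truth
#'
#' Renders `I(r, c) = A(c) [sin(2 pi u / P + phase) +
#' w2 sin(4 pi u / P + 2 phase)] + T(r, c) + offset + noise` with the
#' striation coordinate `u = c cos(alpha0) + r sin(alpha0)` (0-based
#' indices), occlusion bands attenuating the amplitude `A`, a polynomial
#' trend `T` and seeded Gaussian noise.  Identical spec and seed give a
#' bit-identical image.
#'
#' @param spec A [striation_spec()].
#' @return Numeric `height x width` matrix with the generating spec
#'   attached as attribute `"spec"`.
#' @export
make_striation_image <- function(spec) {
  stopifnot(inherits(spec, "striation_spec"))
  img <- render_striation(spec, spec$period_px, spec$phase)
  if (spec$noise_sigma > 0) {
    noise <- if (!is.null(spec$seed)) {
      withr::with_seed(spec$seed,
                       rnorm(length(img), sd = spec$noise_sigma))
    } else {
      rnorm(length(img), sd = spec$noise_sigma)
    }
    img <- img + matrix(noise, nrow(img), ncol(img))
  }
  attr(img, "spec") <- spec
  img
}

render_striation <- function(spec, period, phase) {
  h <- spec$height; w <- spec$width
  r0 <- matrix(0:(h - 1L), h, w)
  c0 <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  al <- spec$orientation_deg * pi / 180
  u <- c0 * cos(al) + r0 * sin(al)
  base <- sin(2 * pi * u / period + phase) +
    spec$w2 * sin(4 * pi * u / period + 2 * phase)
  A <- matrix(spec$amplitude, h, w)
  for (occ in spec$occlusions %||% list()) {
    A <- A * (1 - occ$depth * exp(-0.5 * ((c0 - occ$center) / occ$width)^2))
  }
  tr <- matrix(0, h, w)
  if (!is.null(spec$trend_row)) {
    p <- spec$trend_row
    for (q in seq_along(p)) tr <- tr + p[q] * r0^(q - 1L)
  }
  if (!is.null(spec$trend_col)) {
    p <- spec$trend_col
    for (q in seq_along(p)) tr <- tr + p[q] * c0^(q - 1L)
  }
  A * base + tr + spec$offset
}

#' Synthetic contraction stack (twitch)
#'
#' Produces a time-lapse stack in which the striation period follows a
#' twitch `P(t) = P_dia - (P_dia - P_sys) h(t)`, with `h` a smooth
#' rise-and-decay waveform normalized to peak exactly at 1 over the frame
#' grid (so the minimum period equals `P_sys` at the peak frame).  The
#' phase is anchored at the image center so the pattern compresses
#' symmetrically, as a shortening cell does about its attachment.
#'
#' @param spec A [striation_spec()]; its `period_px` is ignored in favour
#'   of `P_dia`/`P_sys`.
#' @param frames Number of frames (>= 3).
#' @param P_dia,P_sys Diastolic (resting) and peak-systolic periods in
#'   pixels, `P_sys <= P_dia`.
#' @param t_on Contraction onset time in seconds.
#' @param tau_rise,tau_fall Rise and decay time constants in seconds.
#' @param frame_interval_s Frame interval in seconds.
#' @return List of `height x width` matrices with attributes `"P_t"`
#'   (true per-frame period), `"times"` and `"spec"`.
#' @export
make_contraction_stack <- function(spec, frames = 200, P_dia = 4.35,
                                   P_sys = 4.0, t_on = 0.1,
                                   tau_rise = 0.03, tau_fall = 0.25,
                                   frame_interval_s = 0.005) {
  stopifnot(inherits(spec, "striation_spec"))
  frames <- as.integer(frames)
  if (is.na(frames) || frames < 3L) {
    abort("`frames` must be an integer >= 3.", class = "sarclen_bad_input")
  }
  if (!(P_sys <= P_dia)) {
    abort("`P_sys` must not exceed `P_dia`.", class = "sarclen_bad_input")
  }
  times <- (seq_len(frames) - 1L) * frame_interval_s
  g <- ifelse(times < t_on, 0,
              (1 - exp(-(times - t_on) / tau_rise)) *
                exp(-(times - t_on) / tau_fall))
  h <- if (max(g) > 0) g / max(g) else g
  P_t <- P_dia - (P_dia - P_sys) * h
  al <- spec$orientation_deg * pi / 180
  u_c <- ((spec$width - 1) * cos(al) + (spec$height - 1) * sin(al)) / 2
  noise <- if (spec$noise_sigma > 0) {
    gen <- function() matrix(rnorm(spec$height * spec$width,
                                   sd = spec$noise_sigma),
                             spec$height, spec$width)
    if (!is.null(spec$seed)) {
      withr::with_seed(spec$seed, replicate(frames, gen(), simplify = FALSE))
    } else {
      replicate(frames, gen(), simplify = FALSE)
    }
  } else NULL
  stack <- lapply(seq_len(frames), function(j) {
    fr <- render_striation(spec, P_t[j],
                           spec$phase - 2 * pi * u_c / P_t[j])
    if (!is.null(noise)) fr <- fr + noise[[j]]
    fr
  })
  attr(stack, "P_t") <- P_t
  attr(stack, "times") <- times
  attr(stack, "spec") <- spec
  stack
}

#' Period-estimation error table on sinusoid test signals
#'
#' Sweeps line length(s) `N` and true period `P` over a grid, estimates
#' the period with the requested similarity methods and tabulates the
#' relative error `P_est / P - 1`.  In `"sampled"` mode the estimators
#' run on the pixel-sampled sinusoid through the piecewise-cubic
#' machinery ([build_similarity()] + [locate_fundamental()]), exposing
#' the pixelation error; in `"continuous"` mode
#' [continuous_reference_estimate()] evaluates the exact sinusoid,
#' isolating pure boundary bias.  Invalid estimates are kept as `NA`
#' rows, never dropped.
#'
#' @param Ns Integer vector of line lengths.
#' @param P_grid Numeric vector of true periods; defaults to
#'   `seq(3, 12, 0.05)` (continuous) or `seq(3.5, 10, 0.05)` (sampled).
#' @param methods Character vector of similarity method tags.
#' @param mode `"sampled"` or `"continuous"`.
#' @param s_min Lower search bound in pixels.
#' @return A tibble with columns `N`, `P`, `method`, `period_est`,
#'   `relative_error`, `valid`.
#' @export
period_error_table <- function(Ns = c(25L, 50L, 100L), P_grid = NULL,
                            methods = c("finite", "acf", "acf_periodic"),
                            mode = c("sampled", "continuous"),
                            s_min = 2) {
  mode <- match.arg(mode)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(P_grid)) {
    P_grid <- if (mode == "continuous") seq(3, 12, by = 0.05)
              else seq(3.5, 10, by = 0.05)
  }
  grid <- tidyr::expand_grid(N = as.integer(Ns), P = P_grid,
                             method = methods)
  est <- purrr::pmap(grid, function(N, P, method) {
    e <- if (mode == "continuous") {
      continuous_reference_estimate(P, N, method, s_min = s_min)
    } else {
      cur <- build_similarity(make_sine_line(N, P), method)
      locate_fundamental(cur, s_min = s_min, s_max = (N - 1) / 2)
    }
    tibble(period_est = e$period_px,
           relative_error = e$period_px / P - 1,
           valid = e$valid)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(est))
}
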