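#' Define a rectangular, possibly rotated region of interest
#'
#' A ROI is a `height x width` grid of sample points centered at `center`
#' and rotated counter-clockwise by `angle_deg`; its rows become the image
#' lines handed to the period estimators, so `width` is the line length.
#' Pixel centers sit at integer (row, column) coordinates, R-style
#' 1-based.
#'
#' @param center Numeric length-2 vector `c(row, col)` of the ROI center
#'   in pixel coordinates (may be fractional).
#' @param height Number of lines (rows) in the ROI, at least 1.
#' @param width Line length in pixels, at least 4.
#' @param angle_deg Rotation angle in degrees, counter-clockwise; 0 keeps
#'   ROI rows parallel to image rows.
#' @return An object of class `roi`.
#' @export
roi <- function(center, height, width, angle_deg = 0) {
  if (length(center) != 2L || !all(is.finite(center))) {
    abort("`center` must be c(row, col).", class = "sarclen_bad_input")
  }
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(width) || width < 4L) {
    abort("`width` must be an integer >= 4.", class = "sarclen_bad_input")
  }
  if (is.na(height) || height < 1L) {
    abort("`height` must be an integer >= 1.", class = "sarclen_bad_input")
  }
  structure(list(center = as.numeric(center), height = height,
                 width = width, angle_deg = as.numeric(angle_deg)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %d x %d at (%.2f, %.2f), angle %.2f deg\n",
              x$width, x$height, x$center[1], x$center[2], x$angle_deg))
  invisible(x)
}

roi_sample_coords <- function(image, roi) {
  h <- roi$height; w <- roi$width
  di <- seq_len(h) - (h + 1) / 2
  dj <- seq_len(w) - (w + 1) / 2
  th <- roi$angle_deg * pi / 180
  src_row <- roi$center[1L] + outer(di * cos(th), dj * sin(th), `+`)
  src_col <- roi$center[2L] + outer(-di * sin(th), dj * cos(th), `+`)
  eps <- 1e-9
  if (min(src_row) < 1 - eps || max(src_row) > nrow(image) + eps ||
      min(src_col) < 1 - eps || max(src_col) > ncol(image) + eps) {
    abort("rotated ROI footprint falls outside the image.",
          class = "sarclen_out_of_bounds")
  }
  list(row = src_row, col = src_col)
}

#' Extract a (rotated) ROI from an image by bilinear interpolation
#'
#' Samples the image on the rotated rectangular grid of the ROI.  With a
#' zero angle and integer-aligned coordinates this is an exact sub-block
#' copy; at other angles bilinear interpolation is used (exact for any
#' intensity field that is affine in the coordinates).
#'
#' @param image Numeric matrix.
#' @param roi A [roi()].
#' @return A `height x width` numeric matrix whose rows are the ROI image
#'   lines.
#' @export
extract_roi <- function(image, roi) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.", class = "sarclen_bad_input")
  }
  stopifnot(inherits(roi, "roi"))
  g <- roi_sample_coords(image, roi)
  bilinear_sample(image, g$row, g$col)
}

bilinear_sample <- function(image, r, c) {
  nr <- nrow(image); nc <- ncol(image)
  r0 <- pmin(pmax(floor(r), 1), nr - 1L)
  c0 <- pmin(pmax(floor(c), 1), nc - 1L)
  wr <- r - r0
  wc <- c - c0
  v00 <- image[cbind(as.vector(r0), as.vector(c0))]
  v10 <- image[cbind(as.vector(r0 + 1), as.vector(c0))]
  v01 <- image[cbind(as.vector(r0), as.vector(c0 + 1))]
  v11 <- image[cbind(as.vector(r0 + 1), as.vector(c0 + 1))]
  out <- (1 - as.vector(wr)) * (1 - as.vector(wc)) * v00 +
    as.vector(wr) * (1 - as.vector(wc)) * v10 +
    (1 - as.vector(wr)) * as.vector(wc) * v01 +
    as.vector(wr) * as.vector(wc) * v11
  matrix(out, nrow = nrow(r))
}

#' Sweep the ROI orientation and correct the period for misalignment
#'
#' Cutting a P-periodic lattice of striations at an angle `alpha` relative
#' to its optimal orientation `alpha0` stretches the observed period to
#' `P / cos(alpha - alpha0)`.  This function estimates the sarcomere
#' length at every requested ROI angle, fits the model by linear least
#' squares on the reciprocals,
#' `1/SL(alpha) = a cos(alpha) + b sin(alpha)`, and reports
#' `alpha0 = atan2(b, a)` together with the orientation-corrected length
#' `C = 1 / sqrt(a^2 + b^2)` (the model amplitude, equivalent to
#' multiplying the aligned estimate by `cos(alpha0)`).
#'
#' @param image Numeric matrix.
#' @param roi Base [roi()]; its angle is replaced by each scan angle.
#' @param angles_deg Numeric vector of ROI angles to evaluate (at least 3
#'   valid ones spanning at least 4 degrees are required for the fit).
#' @param ... Estimator options forwarded to [estimate_period()].
#' @return An object of class `orientation_scan`: list with the per-angle
#'   tibble `samples` (`angle_deg`, `sl_px`, `valid`, `contrast`),
#'   `alpha0_deg`, `corrected_sl_px` and the reciprocal-fit coefficients.
#'   [tidy()] returns the samples, [glance()] the fit summary,
#'   [autoplot()] the sweep with the fitted `P / cos` curve.
#' @export
orientation_scan <- function(image, roi, angles_deg, ...) {
  stopifnot(inherits(roi, "roi"))
  res <- purrr::map(angles_deg, function(a) {
    r <- roi; r$angle_deg <- a
    est <- tryCatch({
      lines <- extract_roi(image, r)
      estimate_period(lines, ...)
    }, sarclen_out_of_bounds = function(e) {
      new_period_estimate(NA_real_, FALSE, 0, "none")
    })
    tibble(angle_deg = a, sl_px = est$period_px,
           valid = est$valid, contrast = est$contrast)
  })
  samples <- dplyr::bind_rows(res)
  ok <- samples$valid
  if (sum(ok) < 3L || diff(range(samples$angle_deg[ok])) < 4) {
    abort("need at least 3 valid angles spanning >= 4 degrees for the orientation fit.",
          class = "sarclen_fit_failure")
  }
  th <- samples$angle_deg[ok] * pi / 180
  y <- 1 / samples$sl_px[ok]
  fit <- lm(y ~ 0 + cos(th) + sin(th))
  ab <- unname(coef(fit))
  alpha0 <- atan2(ab[2L], ab[1L]) * 180 / pi
  corrected <- 1 / sqrt(sum(ab^2))
  structure(
    list(samples = samples, alpha0_deg = alpha0,
         corrected_sl_px = corrected, coef = c(a = ab[1L], b = ab[2L])),
    class = "orientation_scan"
  )
}

#' @export
print.orientation_scan <- function(x, ...) {
  cat(sprintf(
    "<orientation_scan> %d angles, alpha0 = %.3f deg, corrected SL = %.4f px\n",
    nrow(x$samples), x$alpha0_deg, x$corrected_sl_px))
  invisible(x)
}

#' @rdname orientation_scan
#' @param x An `orientation_scan`.
#' @export
tidy.orientation_scan <- function(x, ...) x$samples

#' @rdname orientation_scan
#' @export
glance.orientation_scan <- function(x, ...) {
  tibble(alpha0_deg = x$alpha0_deg, corrected_sl_px = x$corrected_sl_px,
         n_angles = nrow(x$samples), n_valid = sum(x$samples$valid),
         angle_span_deg = diff(range(x$samples$angle_deg[x$samples$valid])))
}

#' Map the sensitivity of the period estimate to ROI placement
#'
#' Slides a fixed-size ROI over the image on a stride grid and estimates
#' the sarcomere length at every admissible center.  Centers where no
#' valid estimate exists (no striation contrast, e.g. under an occluding
#' fiber) are reported with `valid = FALSE` and `NA` length -- the white
#' pixels of a sensitivity map.
#'
#' @param image Numeric matrix.
#' @param roi_height,roi_width ROI size in pixels.
#' @param stride Center grid step in pixels (>= 1).
#' @param angle_deg ROI angle applied at every center.
#' @param pixel_size_um Optional pixel size; when given, an `sl_um`
#'   column is added.
#' @param ... Estimator options forwarded to [estimate_period()].
#' @return A tibble of class `sl_map` with columns `center_row`,
#'   `center_col`, `sl_px`, (`sl_um`,) `valid`, `contrast`.
#' @export
sensitivity_map <- function(image, roi_height, roi_width, stride = 1,
                            angle_deg = 0, pixel_size_um = NULL, ...) {
  if (!is.matrix(image)) {
    abort("`image` must be a matrix.", class = "sarclen_bad_input")
  }
  stride <- max(1L, as.integer(stride))
  if (roi_height > nrow(image) || roi_width > ncol(image)) {
    abort("ROI is larger than the image.", class = "sarclen_bad_input")
  }
  # admissible centers for the rotated footprint: use the axis-aligned
  # bounding box of the rotated ROI
  th <- abs(angle_deg * pi / 180)
  half_h <- ((roi_height - 1) * cos(th) + (roi_width - 1) * sin(th)) / 2
  half_w <- ((roi_width - 1) * cos(th) + (roi_height - 1) * sin(th)) / 2
  rows <- seq(ceiling(1 + half_h), floor(nrow(image) - half_h), by = stride)
  cols <- seq(ceiling(1 + half_w), floor(ncol(image) - half_w), by = stride)
  if (!length(rows) || !length(cols)) {
    abort("ROI does not fit in the image at any center.",
          class = "sarclen_bad_input")
  }
  grid <- expand.grid(center_row = rows, center_col = cols)
  est <- purrr::pmap(grid, function(center_row, center_col) {
    r <- roi(c(center_row, center_col), roi_height, roi_width, angle_deg)
    e <- tryCatch(estimate_period(extract_roi(image, r), ...),
                  sarclen_out_of_bounds = function(err) {
                    new_period_estimate(NA_real_, FALSE, 0, "none")
                  })
    tibble(sl_px = e$period_px, valid = e$valid, contrast = e$contrast)
  })
  out <- dplyr::bind_cols(as_tibble(grid), dplyr::bind_rows(est))
  if (!is.null(pixel_size_um)) {
    out <- dplyr::mutate(out, sl_um = px_to_um(.data$sl_px, pixel_size_um),
                         .after = "sl_px")
  }
  class(out) <- c("sl_map", class(out))
  out
}

#' Trace the mean sarcomere length through an image stack
#'
#' Applies the chosen period estimator to a fixed ROI in every frame of a
#' time-lapse stack, converts to physical units and computes the
#' shortening rate by the 3-point finite difference ([rate_3pt()]).
#' Frames without a valid estimate are reported as invalid, never
#' interpolated.
#'
#' @param stack A list of numeric matrices (frames) or a 3-D array with
#'   frames along the third dimension; all frames must share one shape.
#' @param roi The [roi()] to analyse, fixed across frames.
#' @param pixel_size_um Pixel size in micrometers (default 0.411).
#' @param frame_interval_s Frame interval in seconds (default 0.005,
#'   i.e. 200 Hz).
#' @param ... Estimator options forwarded to [estimate_period()]
#'   (method, detrending, bounds, ...).
#' @return A tibble of class `sarcomere_trace` with columns `time_s`,
#'   `sl_px`, `sl_um`, `rate_um_s`, `valid`, `contrast`, and attributes
#'   `pixel_size_um` and `frame_interval_s`.
#' @export
trace_timeseries <- function(stack, roi, pixel_size_um = 0.411,
                             frame_interval_s = 0.005, ...) {
  frames <- as_frame_list(stack)
  stopifnot(inherits(roi, "roi"))
  if (!(pixel_size_um > 0) || !(frame_interval_s > 0)) {
    abort("`pixel_size_um` and `frame_interval_s` must be positive.",
          class = "sarclen_bad_input")
  }
  ests <- purrr::map(frames, function(fr) {
    tryCatch(estimate_period(extract_roi(fr, roi), ...),
             error = function(e) new_period_estimate(NA_real_, FALSE, 0, "none"))
  })
  sl_px <- vapply(ests, `[[`, numeric(1), "period_px")
  valid <- vapply(ests, `[[`, logical(1), "valid")
  contrast <- vapply(ests, `[[`, numeric(1), "contrast")
  sl_um <- px_to_um(ifelse(valid, sl_px, NA_real_), pixel_size_um)
  rate <- rate_3pt(sl_um, frame_interval_s)
  rate[!valid] <- NA_real_                 # invalid frames carry no rate
  out <- tibble(
    time_s = (seq_along(frames) - 1) * frame_interval_s,
    sl_px = ifelse(valid, sl_px, NA_real_),
    sl_um = sl_um,
    rate_um_s = rate,
    valid = valid,
    contrast = contrast
  )
  attr(out, "pixel_size_um") <- pixel_size_um
  attr(out, "frame_interval_s") <- frame_interval_s
  class(out) <- c("sarcomere_trace", class(out))
  out
}

as_frame_list <- function(stack) {
  if (is.list(stack)) {
    frames <- stack
  } else if (is.array(stack) && length(dim(stack)) == 3L) {
    frames <- lapply(seq_len(dim(stack)[3L]), function(j) stack[, , j])
  } else if (is.matrix(stack)) {
    frames <- list(stack)
  } else {
    abort("`stack` must be a list of matrices or a 3-D array.",
          class = "sarclen_bad_input")
  }
  dims <- lapply(frames, dim)
  for (j in seq_along(dims)) {
    if (!identical(dims[[j]], dims[[1L]])) {
      abort(sprintf("frame %d has shape %s, expected %s.",
                    j, paste(dims[[j]], collapse = "x"),
                    paste(dims[[1L]], collapse = "x")),
            class = "sarclen_format_error")
    }
  }
  frames
}

#' Shortening rate by 3-point finite difference
#'
#' Interior samples use the central difference
#' `(sl[j+1] - sl[j-1]) / (2 dt)`; the endpoints use one-sided two-point
#' differences so the output has the same length as the input.  `NA`
#' (invalid) neighbours propagate to the rate.
#'
#' @param sl Numeric vector (e.g. sarcomere length in um), length >= 2;
#'   `NA` marks invalid frames.
#' @param dt Sampling interval (seconds), positive.
#' @return Numeric vector of rates, same length as `sl`.
#' @export
rate_3pt <- function(sl, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    abort("`dt` must be a single positive number.", class = "sarclen_bad_input")
  }
  n <- length(sl)
  if (n < 2L) {
    abort("`sl` must contain at least 2 samples.", class = "sarclen_bad_input")
  }
  r <- rep(NA_real_, n)
  if (n > 2L) {
    j <- 2:(n - 1L)
    r[j] <- (sl[j + 1L] - sl[j - 1L]) / (2 * dt)
  }
  r[1L] <- (sl[2L] - sl[1L]) / dt
  r[n] <- (sl[n] - sl[n - 1L]) / dt
  r
}

#' Convert a period in pixels to micrometers
#'
#' @param period_px Period estimate(s) in pixels (non-negative; `NA`
#'   passes through).
#' @param pixel_size_um Pixel size in micrometers per pixel
#'   (non-negative).
#' @return `period_px * pixel_size_um`.
#' @examples
#' px_to_um(4.32, 0.411)  # ~ 1.775 um
#' @export
px_to_um <- function(period_px, pixel_size_um) {
  if (any(period_px < 0, na.rm = TRUE) || any(pixel_size_um < 0)) {
    abort("lengths must be non-negative.", class = "sarclen_bad_input")
  }
  period_px * pixel_size_um
}
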