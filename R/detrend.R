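#' Gaussian blur of a line profile
#'
#' Convolves a line with a normalized Gaussian kernel specified by its
#' half-width at half-maximum, truncated at four standard deviations, with
#' reflect padding at the boundaries.  Used by the detrender with a
#' half-width of about one tenth of the expected sarcomere length, which
#' smooths pixel noise while keeping the striation oscillation (and hence
#' its local extrema) intact.
#'
#' @param values Numeric vector (length at least 2, finite).
#' @param half_width Kernel half-width at half-maximum, in pixels
#'   (positive; `sigma = half_width / sqrt(2 log 2)`).
#' @return Numeric vector of the same length; the kernel weights sum to
#'   one, so a constant line is returned unchanged.
#' @export
blur_line <- function(values, half_width) {
  if (!is.numeric(values) || length(values) < 2L) {
    abort("`values` must be a numeric vector of length >= 2.",
          class = "sarclen_bad_input")
  }
  if (!all(is.finite(values))) {
    abort("`values` contains non-finite entries.", class = "sarclen_bad_input")
  }
  if (!is.numeric(half_width) || length(half_width) != 1L || half_width <= 0) {
    abort("`half_width` must be a single positive number.",
          class = "sarclen_bad_input")
  }
  x <- as.numeric(values)
  n <- length(x)
  sigma <- half_width / sqrt(2 * log(2))
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-0.5 * ((-r:r) / sigma)^2)
  w <- w / sum(w)
  # symmetric (mirror-with-edge) padding, clamped if the kernel is wider
  # than the line itself
  idx <- seq(1L - r, n + r)
  idx <- ifelse(idx < 1L, 1L - idx, idx)             # reflect at left edge
  idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)     # reflect at right edge
  idx <- pmin(pmax(idx, 1L), n)
  xp <- x[idx]
  out <- vapply(seq_len(n), function(i) sum(w * xp[i:(i + 2L * r)]),
                numeric(1))
  out
}

#' Decompose a line profile into oscillation and trend
#'
#' Separates the striation oscillation of one image line from its slowly
#' varying background, given a hint of the spatial period.  The line is
#' first blurred ([blur_line()]) with half-width `period_hint / 10`; the
#' strict local maxima and minima of the blurred line (plateaus contribute
#' their center) define upper and lower envelopes by linear interpolation,
#' extended to the boundaries by holding the nearest extremum; the trend
#' is the envelope midline and the oscillatory part the remainder.  When
#' fewer than two maxima or two minima exist (no resolvable oscillation)
#' the trend falls back to the mean of the blurred line.
#'
#' @param line Numeric line profile (length greater than `period_hint`).
#' @param period_hint Expected period in pixels (at least 3, so the blur
#'   kernel remains resolvable).  Default 4.5 px, a typical sarcomere
#'   (about 1.8 um) at 0.4 um per pixel.
#' @return An object of class `detrend_result`: list with `oscillatory`,
#'   `trend` (both length `N`, summing exactly to the input) and
#'   `extrema_count = c(n_max, n_min)` of the blurred signal.
#' @examples
#' x <- make_sine_line(60, 5) + 0.02 * (0:59)
#' d <- detrend_line(x, 5)
#' range(d$oscillatory + d$trend - x)  # exact reconstruction
#' @export
detrend_line <- function(line, period_hint = 4.5) {
  x <- check_line(line)
  if (!is.numeric(period_hint) || length(period_hint) != 1L ||
      period_hint < 3) {
    abort("`period_hint` must be a single number >= 3 pixels.",
          class = "sarclen_bad_input")
  }
  n <- length(x)
  if (n <= period_hint) {
    abort("line is shorter than `period_hint`; nothing to detrend.",
          class = "sarclen_bad_input")
  }
  b <- blur_line(x, period_hint / 10)
  ex <- local_extrema(b)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L) {
    trend <- rep(mean(b), n)
  } else {
    upper <- approx(ex$maxima, b[ex$maxima], xout = seq_len(n), rule = 2)$y
    lower <- approx(ex$minima, b[ex$minima], xout = seq_len(n), rule = 2)$y
    trend <- (upper + lower) / 2
  }
  osc <- x - trend
  trend <- x - osc                     # re-derive so osc + trend == x exactly
  structure(
    list(oscillatory = osc, trend = trend,
         extrema_count = c(n_max = length(ex$maxima),
                           n_min = length(ex$minima))),
    class = "detrend_result"
  )
}

# strict local extrema with plateau handling: a plateau bounded by a rise
# on one side and a fall on the other contributes its center index
local_extrema <- function(b) {
  d <- diff(b)
  sgn <- sign(d)
  nz <- which(sgn != 0)
  maxima <- integer(0); minima <- integer(0)
  if (length(nz) >= 2L) {
    for (q in seq_len(length(nz) - 1L)) {
      s1 <- sgn[nz[q]]; s2 <- sgn[nz[q + 1L]]
      if (s1 == s2) next
      lo <- nz[q] + 1L                 # first index of the flat/extremal run
      hi <- nz[q + 1L]                 # last index before the next slope
      center <- as.integer(round((lo + hi) / 2))
      if (s1 > 0 && s2 < 0) maxima <- c(maxima, center)
      if (s1 < 0 && s2 > 0) minima <- c(minima, center)
    }
  }
  list(maxima = maxima, minima = minima)
}

#' @export
print.detrend_result <- function(x, ...) {
  cat(sprintf(
    "<detrend_result> %d samples, %d maxima / %d minima of blurred line\n",
    length(x$oscillatory), x$extrema_count[1L], x$extrema_count[2L]))
  invisible(x)
}

#' Detrend every line of an image
#'
#' Applies [detrend_line()] independently to each image row (striations
#' are assumed to run across rows after any ROI rotation).
#'
#' @param image Numeric matrix, one image line per row.
#' @param period_hint As in [detrend_line()].
#' @return A list with matrices `oscillatory` and `trend` of the same
#'   shape as `image`.
#' @export
detrend_image <- function(image, period_hint = 4.5) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.", class = "sarclen_bad_input")
  }
  osc <- image
  tr <- image
  for (i in seq_len(nrow(image))) {
    d <- tryCatch(
      detrend_line(image[i, ], period_hint),
      error = function(e) {
        abort(sprintf("detrending failed on image row %d: %s",
                      i, conditionMessage(e)),
              class = "sarclen_bad_input", parent = e)
      })
    osc[i, ] <- d$oscillatory
    tr[i, ] <- d$trend
  }
  list(oscillatory = osc, trend = tr)
}
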