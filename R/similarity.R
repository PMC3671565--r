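#' Similarity measures of a line profile as exact piecewise cubics
#'
#' Builds the similarity measure of an intensity line profile with its own
#' shifted copy, under the piecewise-linear model of the signal between
#' pixel centers.  Because the interpolant is linear on every unit pixel
#' interval, each similarity integral restricted to a unit shift interval
#' is a cubic polynomial of the fractional shift whose coefficients are
#' finite sums of products of sample values; those coefficients are
#' computed here exactly (no numerical integration).
#'
#' Three measures are supported.  Write `f(x)` for the piecewise-linear
#' interpolant of the samples on `x` in `[0, L]`, `L = N - 1`:
#'
#' * `finite`: the finite-extent least-squares difference
#'   `F(s) = integral_0^{L-s} (f(x+s) - f(x))^2 dx`.  It is evaluated over
#'   the overlap of the signal and its shifted copy only, so no assumption
#'   is made about the signal beyond its recorded extent.  For a perfectly
#'   periodic signal it vanishes exactly at the period, which is what makes
#'   the fundamental-period estimate unbiased.  Its extrema of interest are
#'   minima.
#' * `acf`: the overlap-only autocorrelation
#'   `F(s) = integral_0^{L-s} f(x+s) f(x) dx`, equivalent to extending the
#'   signal with zeros (maxima of interest).
#' * `acf_periodic`: the autocorrelation of the N-periodic extension of the
#'   sample sequence, `F(s) = integral_0^{N} f~(x+s) f~(x) dx`, where the
#'   wrap segment interpolates linearly from the last sample back to the
#'   first (the discrete-FFT convention; maxima of interest).
#'
#' @param values Numeric vector of pixel intensities along one image line
#'   (at least 4 samples, all finite).
#' @param method One of `"finite"`, `"acf"`, `"acf_periodic"`.
#' @return An object of class `similarity_curve`: a list with the segment
#'   coefficient matrix `coef` (one row per integer shift `k`, columns
#'   `a, b, c, d` so that `F(k + t) = a + b t + c t^2 + d t^3`), the
#'   number of segments `K`, the sample count `n`, the `method` tag and
#'   `extremum_kind` (`"minimum"` for `finite`, `"maximum"` otherwise).
#' @seealso [locate_fundamental()] to extract the period,
#'   [accumulate_curves()] to superpose lines of a region of interest,
#'   [predict.similarity_curve()] / [tidy.similarity_curve()] to evaluate.
#' @examples
#' f <- make_sine_line(50, 4.3)
#' cur <- build_similarity(f, "finite")
#' locate_fundamental(cur, 2, 10)
#' @export
build_similarity <- function(values,
                             method = c("finite", "acf", "acf_periodic")) {
  f <- check_line(values)
  method <- match.arg(method)
  n <- length(f)
  if (method == "acf_periodic") {
    coefs <- cross_coef_periodic(f)
  } else {
    cc <- cross_coef_overlap(f)
    if (method == "acf") {
      coefs <- cc
    } else {
      coefs <- finite_coef_from_cross(f, cc)
    }
  }
  new_similarity_curve(coefs, method, n)
}

new_similarity_curve <- function(coefs, method, n) {
  colnames(coefs) <- c("a", "b", "c", "d")
  structure(
    list(coef = coefs,
         K = nrow(coefs),
         n = n,
         method = method,
         extremum_kind = if (method == "finite") "minimum" else "maximum"),
    class = "similarity_curve"
  )
}

# Cross-correlation integral C(k+t) = int_0^{L-s} f(x+s) f(x) dx for the
# overlap-only measures. For x in cell [j, j+1] (0-based) and shift
# s = k + t, the shifted copy lives on cell j+k for u in [0, 1-t] and on
# cell j+k+1 for u in [1-t, 1]; both pieces integrate to cubics in t with
# product-of-samples coefficients (derived once from the linear model).
cross_coef_overlap <- function(f) {
  n <- length(f)
  K <- n - 1L
  out <- matrix(0, K, 4L)
  for (k in 0:(K - 1L)) {
    M <- n - 1L - k
    j <- seq_len(M)                      # 1-based index of f_j, j = 0..M-1
    a0 <- f[j]
    a1 <- f[j + 1L] - f[j]
    b0 <- f[j + k]
    b1 <- f[j + k + 1L] - f[j + k]
    c0 <- sum(a0 * b0 + (a1 * b0 + a0 * b1) / 2 + a1 * b1 / 3)
    c1 <- -sum(a0 * b0 + a1 * b0 + a1 * b1 / 2)
    c2 <- sum(a1 * b0 - a0 * b1) / 2
    c3 <- sum(a1 * b1) / 6
    if (M >= 2L) {
      j2 <- seq_len(M - 1L)
      a1s <- f[j2 + 1L] - f[j2]
      e0 <- f[j2 + 1L]
      d0 <- f[j2 + k + 1L]
      g1 <- f[j2 + k + 2L] - f[j2 + k + 1L]
      c1 <- c1 + sum(e0 * d0)
      c2 <- c2 + sum(e0 * g1 - a1s * d0) / 2
      c3 <- c3 - sum(a1s * g1) / 6
    }
    out[k + 1L, ] <- c(c0, c1, c2, c3)
  }
  out
}

# Periodic autocorrelation over one full period of the N-periodic
# extension: every one of the N cells contributes both pieces, indices
# taken modulo N (wrap cell interpolates node N-1 -> node 0).
cross_coef_periodic <- function(f) {
  n <- length(f)
  fp <- c(f, f, f[1L])                   # covers index j + k + 2 <= 2n + 1
  out <- matrix(0, n, 4L)
  j <- seq_len(n)
  a0 <- fp[j]
  a1 <- fp[j + 1L] - fp[j]
  e0 <- fp[j + 1L]
  for (k in 0:(n - 1L)) {
    b0 <- fp[j + k]
    b1 <- fp[j + k + 1L] - fp[j + k]
    d0 <- fp[j + k + 1L]
    g1 <- fp[j + k + 2L] - fp[j + k + 1L]
    out[k + 1L, ] <- c(
      sum(a0 * b0 + (a1 * b0 + a0 * b1) / 2 + a1 * b1 / 3),
      -sum(a0 * b0 + a1 * b0 + a1 * b1 / 2) + sum(e0 * d0),
      sum(a1 * b0 - a0 * b1) / 2 + sum(e0 * g1 - a1 * d0) / 2,
      sum(a1 * b1) / 6 - sum(a1 * g1) / 6
    )
  }
  out
}

# F_finite = Q1 + Q2 - 2 C with Q1, Q2 the squared-signal integrals over
# the (shift-dependent) overlap window; both reduce to cumulative sums of
# per-cell integrals of f^2 plus a cubic boundary correction.
finite_coef_from_cross <- function(f, cc) {
  n <- length(f)
  K <- n - 1L
  cell <- (f[-n]^2 + f[-n] * f[-1L] + f[-1L]^2) / 3  # int of f^2 per cell
  S2 <- c(0, cumsum(cell))                           # S2[m+1] = int_0^m f^2
  k <- 0:(K - 1L)
  M <- n - 1L - k
  fM0 <- f[M]                                        # f_{M-1}
  fM1 <- f[M + 1L]                                   # f_M
  g <- fM1 - fM0
  fk <- f[k + 1L]
  gk <- f[k + 2L] - f[k + 1L]
  a <- S2[M + 1L] + S2[n] - S2[k + 1L] - 2 * cc[, 1L]
  b <- -fM1^2 - fk^2 - 2 * cc[, 2L]
  c_ <- fM1 * g - fk * gk - 2 * cc[, 3L]
  d <- -g^2 / 3 - gk^2 / 3 - 2 * cc[, 4L]
  cbind(a, b, c_, d, deparse.level = 0)
}

#' Superpose similarity curves of several image lines
#'
#' The similarity measure of a multi-line region of interest is the sum of
#' the per-line similarity measures; summation is exact (coefficient-wise)
#' because each curve is a piecewise cubic on the same shift grid.
#'
#' @param curves A list of `similarity_curve` objects sharing the same
#'   method and number of segments.
#' @return A single `similarity_curve` with coefficient-wise summed
#'   segments.
#' @export
accumulate_curves <- function(curves) {
  if (inherits(curves, "similarity_curve")) curves <- list(curves)
  if (!is.list(curves) || length(curves) == 0L ||
      !all(vapply(curves, inherits, logical(1), "similarity_curve"))) {
    abort("`curves` must be a non-empty list of similarity_curve objects.",
          class = "sarclen_bad_input")
  }
  meth <- vapply(curves, `[[`, character(1), "method")
  Ks <- vapply(curves, `[[`, integer(1), "K")
  if (length(unique(meth)) != 1L || length(unique(Ks)) != 1L) {
    abort("curves have mixed methods or segment counts and cannot be summed.",
          class = "sarclen_incompatible_curves")
  }
  total <- Reduce(`+`, lapply(curves, `[[`, "coef"))
  new_similarity_curve(total, meth[1L], curves[[1L]]$n)
}

#' Evaluate a similarity curve at arbitrary shifts
#'
#' @param object A `similarity_curve`.
#' @param shift Numeric vector of shifts in `[0, K]` pixels.
#' @param ... Unused.
#' @return Numeric vector of curve values.
#' @export
predict.similarity_curve <- function(object, shift, ...) {
  s <- as.numeric(shift)
  if (any(!is.finite(s)) || any(s < 0) || any(s > object$K + 1e-9)) {
    abort(sprintf("`shift` must lie in [0, %d].", object$K),
          class = "sarclen_bad_input")
  }
  k <- pmin(floor(s), object$K - 1L)
  t <- s - k
  cf <- object$coef[k + 1L, , drop = FALSE]
  cf[, 1L] + t * (cf[, 2L] + t * (cf[, 3L] + t * cf[, 4L]))
}

#' @export
print.similarity_curve <- function(x, ...) {
  cat(sprintf(
    "<similarity_curve> method=%s, %d cubic segments (n = %d samples), %s-seeking\n",
    x$method, x$K, x$n, x$extremum_kind))
  invisible(x)
}

#' Tabulate a similarity curve on a shift grid
#'
#' @param x A `similarity_curve`.
#' @param step Grid step in pixels.
#' @param ... Unused.
#' @return A tibble with columns `shift` and `value` (CSV-friendly).
#' @export
tidy.similarity_curve <- function(x, step = 0.01, ...) {
  s <- seq(0, x$K, by = step)
  tibble(shift = s, value = predict(x, s))
}

#' Locate the fundamental period of a similarity curve in closed form
#'
#' Scans the cubic segments of the curve inside the configured shift
#' bounds, solves the quadratic derivative of each segment analytically,
#' classifies critical points by the second derivative, and returns the
#' first qualifying extremum: for the finite-extent measure, the first
#' local minimum that follows a local maximum at a smaller shift (which
#' skips the trivial zero-shift well); for the autocorrelation measures,
#' the first local maximum preceded by a local minimum.  A derivative sign
#' change across a segment node with no interior root yields the node
#' itself as the critical point.
#'
#' The relative depth of the located extremum against the preceding
#' opposite extremum is reported as `contrast`; the estimate is flagged
#' valid only when `contrast >= contrast_threshold`.  If the first
#' candidate is too shallow the scan continues and the first sufficiently
#' deep extremum is returned; when none qualifies the result carries
#' `valid = FALSE`, `period_px = NA` and `contrast = 0`.
#'
#' @param curve A `similarity_curve`.
#' @param s_min,s_max Search bounds for the period, in pixels.  Defaults:
#'   2 and `(n-1)/2`.
#' @param contrast_threshold Minimum relative extremum depth for a valid
#'   estimate (default 0.1).
#' @return A `period_estimate` object; see [estimate_period()].
#' @export
locate_fundamental <- function(curve, s_min = 2,
                               s_max = (curve$n - 1) / 2,
                               contrast_threshold = 0.1) {
  stopifnot(inherits(curve, "similarity_curve"))
  s_max <- min(s_max, curve$K)
  if (!(s_min > 0) || !(s_min < s_max)) {
    abort("need 0 < s_min < s_max <= curve support.",
          class = "sarclen_bad_input")
  }
  cp <- critical_points(curve, s_max)
  walk_extrema(cp, curve, s_min, s_max, contrast_threshold,
               target = curve$extremum_kind, method = curve$method)
}

# All critical points of the piecewise cubic on (0, s_max]: interior roots
# of each segment's derivative plus derivative sign changes across nodes.
critical_points <- function(curve, s_max) {
  cf <- curve$coef
  K <- curve$K
  scale_d <- max(abs(cf[, 2:4]), 1e-300)
  tol <- 1e-12 * scale_d
  ss <- numeric(0); kind <- character(0)
  kmax <- min(K, ceiling(s_max))
  for (k in seq_len(kmax)) {
    b <- cf[k, 2L]; c2 <- cf[k, 3L]; d3 <- cf[k, 4L]
    roots <- numeric(0)
    if (abs(d3) > tol * 1e-3) {
      disc <- c2 * c2 - 3 * b * d3
      if (disc >= 0) {
        sq <- sqrt(disc)
        roots <- c((-c2 - sq) / (3 * d3), (-c2 + sq) / (3 * d3))
      }
    } else if (abs(c2) > tol * 1e-3) {
      roots <- -b / (2 * c2)
    }
    for (t in roots) {
      # closed interval: extrema can sit exactly on a node (e.g. integer
      # periods); duplicates from adjacent segments are merged below
      if (t > -1e-9 && t < 1 + 1e-9) {
        t <- min(max(t, 0), 1)
        curv <- 2 * c2 + 6 * d3 * t
        if (curv > tol) {
          ss <- c(ss, k - 1L + t); kind <- c(kind, "minimum")
        } else if (curv < -tol) {
          ss <- c(ss, k - 1L + t); kind <- c(kind, "maximum")
        }
      }
    }
    # node between segment k and k+1 (1-based coef rows)
    if (k < K) {
      dl <- cf[k, 2L] + 2 * cf[k, 3L] + 3 * cf[k, 4L]
      dr <- cf[k + 1L, 2L]
      if (dl < -tol && dr > tol) {
        ss <- c(ss, k); kind <- c(kind, "minimum")
      } else if (dl > tol && dr < -tol) {
        ss <- c(ss, k); kind <- c(kind, "maximum")
      }
    }
  }
  if (length(ss)) {
    ord <- order(ss)
    ss <- ss[ord]; kind <- kind[ord]
    keep <- c(TRUE, diff(ss) > 1e-9)
    ss <- ss[keep]; kind <- kind[keep]
  }
  list(s = ss, kind = kind)
}

walk_extrema <- function(cp, curve, s_min, s_max, contrast_threshold,
                         target, method) {
  opposite <- if (target == "minimum") "maximum" else "minimum"
  last_opp <- NULL
  first_candidate <- NULL
  for (i in seq_along(cp$s)) {
    s <- cp$s[i]
    if (s > s_max + 1e-12) break
    v <- predict(curve, s)
    if (cp$kind[i] == opposite) {
      last_opp <- list(s = s, value = v)
    } else if (s >= s_min - 1e-12 && !is.null(last_opp)) {
      num <- if (target == "minimum") last_opp$value - v else v - last_opp$value
      den <- abs(last_opp$value)
      contrast <- if (den > 0) num / den else if (num > 0) Inf else 0
      cand <- list(s = min(max(s, s_min), s_max), contrast = contrast)
      if (is.null(first_candidate)) first_candidate <- cand
      if (contrast >= contrast_threshold) {
        return(new_period_estimate(cand$s, TRUE, contrast, method))
      }
    }
  }
  new_period_estimate(NA_real_, FALSE, 0, method)
}

new_period_estimate <- function(period_px, valid, contrast, method,
                                mode = NA_character_, n_lines = NA_integer_) {
  structure(
    list(period_px = period_px, valid = valid, contrast = contrast,
         method = method, mode = mode, n_lines = n_lines),
    class = "period_estimate"
  )
}

#' @export
print.period_estimate <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<period_estimate> %.6f px (method %s, contrast %.3g)\n",
                x$period_px, x$method, x$contrast))
  } else {
    cat(sprintf("<period_estimate> invalid (method %s)\n", x$method))
  }
  invisible(x)
}

#' @rdname tidy.similarity_curve
#' @export
tidy.period_estimate <- function(x, ...) {
  tibble(method = x$method, mode = x$mode, period_px = x$period_px,
         valid = x$valid, contrast = x$contrast, n_lines = x$n_lines)
}
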