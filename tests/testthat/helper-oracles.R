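# Independent oracles used to pin the implementation.  They share no code
# with the package internals: similarity values come from piecewise Gauss
# quadrature of the linear-interpolant integrand, continuous-sinusoid
# values from closed-form antiderivatives, and the spectral baselines from
# naive O(N^2) transforms.

# --- piecewise quadrature of the similarity integrands -------------------
# The integrand is smooth between breakpoints (integers and integer-minus-
# shift points); 3-point Gauss per piece is exact for the quadratic
# product of two linear interpolants.
oracle_similarity <- function(f, s, method) {
  N <- length(f)
  L <- N - 1
  g3x <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  g3w <- c(5, 8, 5) / 9
  if (method == "acf_periodic") {
    nodes <- 0:(2 * N)
    vals <- c(f, f, f[1])
    W <- N
    s <- s %% N
    br <- sort(unique(c(0:N, (ceiling(s):(N + floor(s))) - s)))
  } else {
    nodes <- 0:L
    vals <- f
    W <- L - s
    br <- sort(unique(c(0:floor(W), W, (ceiling(s):L) - s)))
  }
  br <- br[br >= -1e-12 & br <= W + 1e-12]
  if (length(br) < 2) return(0)
  a <- head(br, -1)
  b <- tail(br, -1)
  mid <- (a + b) / 2
  h <- (b - a) / 2
  x <- as.vector(outer(g3x, h) + rep(mid, each = 3))   # 3 nodes per piece
  w <- as.vector(outer(g3w, h))
  fa <- approx(nodes, vals, xout = x + s)$y
  fb <- approx(nodes, vals, xout = x)$y
  if (method == "finite") sum(w * (fa - fb)^2) else sum(w * fa * fb)
}

# --- closed forms for the continuous sinusoid ----------------------------
# int_a^b sin(omega x + p1) sin(omega x + p2) dx
sin_prod_int <- function(a, b, p1, p2, omega) {
  0.5 * ((b - a) * cos(p1 - p2) -
           (sin(2 * omega * b + p1 + p2) - sin(2 * omega * a + p1 + p2)) /
           (2 * omega))
}

oracle_continuous <- function(P, N, s, method) {
  omega <- 2 * pi / P
  L <- N - 1
  switch(method,
    finite = {
      W <- L - s
      sin_prod_int(0, W, omega * s, omega * s, omega) +
        sin_prod_int(0, W, 0, 0, omega) -
        2 * sin_prod_int(0, W, omega * s, 0, omega)
    },
    acf = sin_prod_int(0, L - s, omega * s, 0, omega),
    acf_periodic = {
      sm <- s %% L
      sin_prod_int(0, L - sm, omega * sm, 0, omega) +
        sin_prod_int(L - sm, L, omega * (sm - L), 0, omega)
    })
}

# first qualifying extremum of the closed-form continuous measure,
# located independently of the package machinery
oracle_continuous_estimate <- function(P, N, method, s_min = 2,
                                       s_max = (N - 1) / 2) {
  fun <- function(s) oracle_continuous(P, N, s, method)
  g <- seq(0.01, s_max, by = 0.005)
  fv <- vapply(g, fun, numeric(1))
  target_min <- method == "finite"
  d <- diff(fv)
  ext <- which(sign(head(d, -1)) != sign(tail(d, -1)) &
                 head(d, -1) != 0) + 1L
  for (i in ext) {
    is_min <- fv[i] < fv[i - 1]
    if (is_min == target_min && g[i] >= s_min) {
      r <- optimize(fun, c(g[i - 1], g[i + 1]), maximum = !target_min,
                    tol = 1e-10)
      return(if (target_min) r$minimum else r$maximum)
    }
  }
  NA_real_
}

# --- naive spectral baselines --------------------------------------------
naive_power_spectrum <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(m) {
    ang <- -2 * pi * m * (0:(N - 1)) / N
    Mod(sum(x * complex(real = cos(ang), imaginary = sin(ang))))^2
  }, numeric(1))
}

oracle_fft_estimate <- function(lines, s_min = 2, s_max = NULL,
                                window = "hann") {
  m <- if (is.matrix(lines)) lines else matrix(lines, nrow = 1)
  N <- ncol(m)
  if (is.null(s_max)) s_max <- (N - 1) / 2
  w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / N))
       else rep(1, N)
  S <- colMeans(t(apply(m, 1, function(x) naive_power_spectrum(x * w))))
  ms <- max(2, ceiling(N / s_max)):min(floor(N / s_min), floor(N / 2) - 1)
  mstar <- ms[which.max(S[ms + 1])]
  y <- S[mstar + c(0, 1, 2)]           # S[m-1], S[m], S[m+1] (1-based)
  den <- y[1] - 2 * y[2] + y[3]
  delta <- if (abs(den) <= 1e-15 * y[2]) 0 else (y[1] - y[3]) / (2 * den)
  N / (mstar + delta)
}

oracle_acf_estimate <- function(lines, s_min = 2, s_max = NULL) {
  m <- if (is.matrix(lines)) lines else matrix(lines, nrow = 1)
  N <- ncol(m)
  if (is.null(s_max)) s_max <- (N - 1) / 2
  acf1 <- function(x) {
    vapply(0:(N - 1), function(l) sum(x * x[((0:(N - 1) + l) %% N) + 1]),
           numeric(1))
  }
  A <- colMeans(t(apply(m, 1, acf1)))
  for (l in max(1, ceiling(s_min)):min(floor(s_max), N - 2)) {
    if (A[l + 1] > A[l] && A[l + 1] >= A[l + 2]) {
      y <- A[l + c(0, 1, 2)]
      den <- y[1] - 2 * y[2] + y[3]
      delta <- if (abs(den) <= 1e-15 * max(abs(y[2]), max(abs(A)))) 0
               else (y[1] - y[3]) / (2 * den)
      return(l + delta)
    }
  }
  NA_real_
}

# shared small fixtures
fixture_roi_lines <- function(P = 4.32, n_lines = 31, N = 54, seed = 5,
                              phase_sd = 0.25, amp_range = c(0.6, 1.4)) {
  withr::with_seed(seed, {
    ph <- rnorm(n_lines, sd = phase_sd)
    am <- runif(n_lines, amp_range[1], amp_range[2])
    t(mapply(function(p, a) a * make_sine_line(N, P, p), ph, am))
  })
}
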