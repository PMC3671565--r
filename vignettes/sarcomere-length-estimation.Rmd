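---
title: "Estimating sarcomere length as the fundamental period of a striation pattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sarcomere length as the fundamental period of a striation pattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarclen)
```

## The measurement problem

In a transmission image of a striated muscle cell the sarcomeres appear as
a quasi-periodic sequence of darker and lighter bands. The mean sarcomere
length (SL) within a region of interest (ROI) is the spatial fundamental
period of that pattern. The measurement is awkward for three reasons: a
sarcomere spans only 4–5 pixels at typical magnifications (1.8 µm at
~0.4 µm/pixel), the usable ROI is short (bounded by cell size, morphology
and occluding carbon fibers), and during a twitch SL changes by a few
percent between frames recorded at hundreds of hertz. The estimator must
therefore be subpixel-accurate on finite, noisy windows.

## Signal model and similarity measures

A single image line is a vector of samples `f_i`, `i = 0..N−1`. We model
the underlying intensity as the piecewise-linear interpolant `f(x)` on
`0 ≤ x ≤ L`, `L = N − 1`. Three similarity measures of the line with its
shifted copy are implemented (`build_similarity()`):

* **finite** (the package's central estimator):
  `F(s) = ∫₀^{L−s} [f(x+s) − f(x)]² dx`, the least-squares mismatch over
  the *overlap* of the line and its copy. It assumes nothing about the
  signal beyond its recorded extent, is invariant to intensity offset and
  to reversing the line, and vanishes exactly at the period of a periodic
  signal. SL is its first local minimum after a local maximum.
* **acf**: `∫₀^{L−s} f(x+s) f(x) dx`, the overlap-only (zero-padding)
  autocorrelation; SL is its first positive local maximum.
* **acf_periodic**: the autocorrelation of the N-periodic extension of the
  sample sequence over one full period (the discrete-FFT convention; the
  wrap segment interpolates from the last sample back to the first).

Because `f` is linear on every unit cell, each measure restricted to
`s ∈ [k, k+1]` is a cubic polynomial in `t = s − k` whose four
coefficients are finite sums of products of sample values. The package
derives these coefficients exactly — integration is symbolic, done once in
the implementation — so the curve can be evaluated, summed across ROI
lines (`accumulate_curves()`), and minimised in closed form
(`locate_fundamental()` solves the quadratic derivative per segment and
classifies critical points by the second derivative). The tests pin this
algebra against an independent piecewise Gauss-quadrature oracle at 500
random shifts per curve to 1e−8 relative.

### Why the finite measure is the default

The two ACF variants impose a signal extension. When the imposed period
(or the zeros) disagrees with the pattern at the window ends, the located
extremum shifts; the error is systematic, changes with the ratio of window
length to period, and for the periodic variant alternates in sign as `P`
varies. The continuous-signal reference (`continuous_reference_estimate()`,
which integrates the exact sinusoid rather than its interpolant) isolates
this boundary bias from pixelation: there the finite measure recovers the
period to better than 1e−6 relative for every tested `(N, P)`, while both
ACF variants carry errors up to several percent. One consequence worth
stating explicitly: under the overlap-only definition used here the plain
ACF maximum is always dragged toward smaller shifts by the shrinking
overlap envelope, so its error is magnitude-modulated but one-sided; only
the periodic variant shows sign-alternating errors.

### Locating the fundamental period

The search runs over `s ∈ [s_min, s_max]` (defaults 2 px and `(N−1)/2`).
For minimum-seeking curves the estimate is the first local minimum that
follows a local maximum at a smaller shift, which skips the trivial well
at `s = 0`; maxima are treated symmetrically for the ACF measures. Each
located extremum gets a `contrast`: its relative depth against the
preceding opposite extremum. An estimate is valid only if
`contrast ≥ 0.1` (configurable); if the first candidate is too shallow the
scan continues and returns the first sufficiently deep extremum, and if
none qualifies the result is flagged invalid (`period_px = NA`,
`contrast = 0`) rather than guessed. Critical points falling exactly on a
segment node (integer periods do this) are detected by accepting
closed-interval derivative roots and merging duplicates; a derivative sign
change across a node with no interior root yields the node itself, and
ties resolve toward the smaller shift.

The raw measure is used unnormalized — that is what makes it an exact
piecewise cubic. A normalized variant `F(s)/(L−s)` is available
(`normalize = TRUE`) for noisy lines where the shrinking overlap tilts the
raw curve; it is located numerically on the exact curve. For periodic
signals both variants give the same minimum (tested).

## Pixelation error — the remaining bias

With pixel sampling, linear interpolation is only an approximation of the
band profile, and the located minimum moves slightly. On sampled
sinusoids with `N = 50` the error stays below 1 % near 4.3 px/period for
the finite measure (the periodic ACF adds boundary bias on top, up to
2 %), and it shrinks as the number of samples per period grows — longer
waveforms interpolate better. Two practical consequences:

* Averaged over phase, the residual bias at ~4.3 px/period is about
  −0.5 %. It depends on the observed period, so it drifts slowly across
  an orientation sweep; fitting the `1/SL` model then displaces the
  recovered orientation `α₀` by up to ~0.5° even on noise-free synthetic
  data. The orientation-*corrected* SL is much less affected (the cosine
  is flat near its maximum). This is the accuracy floor of the method at
  this sampling density, not a fittable parameter.
* Error tables over `(N, P)` grids are available from
  `period_error_table()` in both `sampled` and `continuous` mode, so the
  two error sources can be separated at will.

## Detrending

Real lines sit on an uneven background (nuclei, fibers, illumination).
`detrend_line()` decomposes a line given a period hint (default 4.5 px,
a typical sarcomere at 0.4 µm/pixel):

1. blur with a Gaussian kernel of half-width-at-half-maximum
   `period_hint/10` (truncated at 4σ, mirror-padded) — strong enough to
   suppress pixel noise, weak enough to keep the striation oscillation
   (theoretical attenuation `exp(−2π²σ²/P²) ≈ 0.87`);
2. take the strict local maxima and minima of the blurred line (plateaus
   contribute their centers), interpolate an upper and a lower envelope
   linearly, holding the nearest extremum toward the boundaries;
3. the trend is the envelope midline; the oscillatory part is the
   original minus the trend, so the two add back to the input to machine
   rounding. With fewer than two maxima or two minima (no resolvable
   oscillation) the trend falls back to the mean of the blurred line.

The envelope-midpoint construction is this package's committed variant of
"extract the oscillation through local extrema processing": it uses only
local extrema, honours the period hint through the blur scale, and is
isolated behind one function so an alternative can be swapped in. The
oscillatory part keeps its amplitude variation on purpose — amplitude is
information about signal quality, and flattening it would distort the
relative weighting of lines in a summed ROI curve. Detrending also brings
lines to near-zero mean, which the ACF/FFT baselines need.

## ROI geometry and orientation correction

ROIs are `height × width` grids of sample points centered anywhere in the
image and rotated counter-clockwise by `angle_deg`; rows become the lines
handed to the estimator. Pixel centers sit at integer 1-based (row, col)
coordinates, and sampling uses bilinear interpolation (exact for affine
intensity fields; an axis-aligned integer ROI is an exact copy).

Cutting a P-periodic lattice of striations at angle `α` relative to its
optimal orientation `α₀` stretches the observed period to
`P / cos(α − α₀)`. `orientation_scan()` estimates SL at each requested
angle and fits the equivalent linear model
`1/SL = a·cos α + b·sin α`, giving `α₀ = atan2(b, a)` and the corrected
length `C = 1/√(a²+b²)` in one least-squares pass, with invalid angles
excluded (at least 3 valid angles spanning ≥ 4° are required). `C` is the
primary corrected output; it equals the aligned estimate multiplied by
`cos α₀` under the model.

`sensitivity_map()` slides a fixed ROI over a stride grid and reports SL
per center with a validity mask — signal-free centers (occluded by a
fiber, outside the cell) appear as invalid entries, the blank pixels of a
sensitivity map. For homogeneous synthetic striations the valid entries
agree to well under 1 % once the ROI spans ≥ 8 periods.

## Time series

`trace_timeseries()` applies the estimator to a fixed ROI in every frame,
converts to micrometers (`px_to_um()`, default pixel size 0.411 µm) and
differentiates with a 3-point stencil (`rate_3pt()`: central differences
inside, one-sided at the ends, invalid neighbours propagate). Invalid
frames are reported, never interpolated. On synthetic twitch stacks
(diastolic period 4.35 px, systolic 4.0 px, 200 frames at 5 ms) the
finite-method trace follows the true per-frame period to better than 1 %,
while the FFT baseline on the same stack shows plateaus — runs of frames
with an identical estimate while the true period changes — which is the
artifact that motivates the finite measure.

## The synthetic generator

`make_striation_image()` renders
`I = A·[sin(2πu/P) + w₂·sin(4πu/P)] + T + offset + ε` with striation
coordinate `u = c·cos α₀ + r·sin α₀`, polynomial background `T` (degree
≤ 2 per axis), Gaussian occlusion bands multiplying the amplitude (carbon
fiber stand-ins), and seeded additive Gaussian noise ε. Defaults emulate
the imaging setup the package targets: period 4.32 px, amplitude 0.3
about offset 0.5 (so images stay in [0, 1] for float-TIFF export), noise
off unless requested. `make_contraction_stack()` drives the period
through a smooth twitch `P(t) = P_dia − (P_dia−P_sys)·h(t)` (delayed
exponential rise and decay, normalized to peak exactly at 1, phase
anchored at the image center so the pattern compresses symmetrically),
and records `P(t)` as ground truth.

What the generator deliberately does **not** model: the optical point
spread function, photon shot noise, sarcomere-to-sarcomere length
disorder, and myofibril misregistration across lines. Passing the
package's tests therefore demonstrates correctness of the estimator on
the stated signal model and robustness to trend, Gaussian noise and
occlusion — not performance on every real-cell pathology. The waveform
asymmetry weight `w₂` exists because real band profiles are not
sinusoidal; it defaults to 0 so that error tables are comparable to the
sinusoid theory.

## Numerical choices

* Similarity coefficients are exact finite sums; no tolerance is involved
  in building curves.
* `continuous_reference_estimate()` evaluates its integrals by composite
  Gauss–Legendre quadrature with 12 nodes per ≤ 1-unit panel — effectively
  exact for trigonometric integrands and deterministic — scans the shift
  grid at 0.01 px and refines extrema by bracketed scalar minimisation to
  1e−9. The periodic continuous variant extends the signal with period
  `L = N − 1` (its domain length) and splits the integral at the wrap
  kink; the discrete periodic variant uses period N samples, matching the
  DFT convention.
* The FFT baseline uses a periodic Hann window (denominator N), so an
  on-bin sinusoid occupies exactly three symmetric bins and the
  three-point parabolic refinement is exact there; a degenerate parabola
  denominator (≤ 1e−15 of the peak) yields a zero offset.
* Defaults: `s_min = 2` px, `s_max = (N−1)/2`, `contrast_threshold = 0.1`,
  `period_hint = 4.5` px, pixel size 0.411 µm, frame interval 5 ms.
  All are exposed in function arguments and in `run_config()`.
* Degenerate inputs are first-class: constant lines give an identically
  zero finite measure and an invalid estimate; all-flat ROIs give
  `valid = FALSE`; fewer than 4 samples is an error.

Test and verification problem sizes are kept modest by design — lines of
24–64 samples, images up to ~140×100, stacks of 80–200 frames, sweeps of
a few hundred grid points — which exercises every code path while keeping
the whole suite to a few minutes.

## Known limitations

* At 4–5 samples per period the piecewise-linear model leaves a
  phase-averaged bias of up to ~0.5 % (shrinking rapidly for longer
  periods); orientation recovery inherits an uncertainty of ~0.5° from
  its drift, as discussed above.
* Detrending is strictly per line; no 2-D background model.
* The orientation fit assumes a single coherent lattice within the ROI;
  strongly heterogeneous ROIs average regional periods instead
  (observable with `sensitivity_map()`).
* The CLI covers single-ROI workflows; batch orchestration is left to the
  caller.
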