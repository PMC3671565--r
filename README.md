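# sarclen

Subpixel estimation of the mean sarcomere length of striated muscle cells
from transmission microscopy images.

## The problem

The striation pattern of a cardiomyocyte — alternating dark Z-disks and
lighter band regions — is a quasi-periodic intensity signal whose spatial
fundamental period *is* the mean sarcomere length (SL). At typical imaging
scales a single sarcomere spans only 4–5 pixels, the usable region of
interest (ROI) is short, and the cell shortens by several percent during a
twitch, so SL must be resolved well below one pixel from a few dozen noisy
samples per line.

Conventional estimators read the period off the autocorrelation function
(ACF) or the discrete Fourier spectrum. Both implicitly extend the finite
image line — with zeros or periodically — and the resulting boundary
mismatch biases the estimate in a P-dependent way, producing the familiar
staircase ("plateau") artifacts in SL-versus-time curves.

## The estimator

`sarclen` builds its estimate on a **finite-extent least-squares similarity
measure**. For a line profile modelled as the piecewise-linear interpolant
`f(x)` of pixel samples on `0 <= x <= L`,

    F(s) = ∫₀^{L-s} [ f(x+s) − f(x) ]² dx

compares the line with its own shifted copy **over their overlap only**: no
assumption is made about the signal beyond its recorded extent, and for a
perfectly periodic signal `F` vanishes exactly at the period. Because `f`
is piecewise linear, `F` restricted to each unit shift interval is a cubic
polynomial of the fractional shift whose coefficients are finite sums of
products of sample values; the package computes those coefficients exactly
and finds the first qualifying minimum of `F` **in closed form** — no FFT,
no grid search, no interpolation of the similarity curve. Multi-line ROIs
are handled by summing per-line curves (or averaging per-line minima).

Around the core estimator the package provides:

* `detrend_line()` / `detrend_image()` — envelope-midpoint decomposition of
  each line into striation oscillation and slowly varying background;
* `extract_roi()`, `orientation_scan()` — rotated-ROI extraction (bilinear)
  and the `P / cos(α − α₀)` orientation correction;
* `sensitivity_map()` — SL as a function of ROI placement, with a validity
  mask for signal-free (e.g. fiber-occluded) regions;
* `trace_timeseries()`, `rate_3pt()` — per-frame SL in µm and shortening
  rate in µm/s for image stacks;
* `estimate_period_fft()`, `estimate_period_acf_quadratic()`, and the
  `acf` / `acf_periodic` similarity measures — the conventional baselines,
  for comparison;
* `make_striation_image()`, `make_contraction_stack()`,
  `period_error_table()` — synthetic striation images, twitch stacks and
  sinusoid error tables with exact ground truth;
* `run_cli()` — an `estimate | trace | sensitivity | orientation |
  simulate | benchmark` command-line interface (launcher in `inst/cli/`).

Results come back as tibbles or small S3 objects with `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

```r
library(sarclen)

spec <- striation_spec(width = 96, height = 40, period_px = 4.32,
                       noise_sigma = 0.006, seed = 42)
img  <- make_striation_image(spec)

est <- estimate_period(extract_roi(img, roi(c(20.5, 48.5), 31, 54)),
                       method = "finite", detrend = TRUE)
est
#> <period_estimate> 4.299871 px (method finite, contrast 0.993)
px_to_um(est$period_px, 0.411)
#> [1] 1.767247
```

The synthetic cell has a true period of 4.32 px; the estimate of
4.2999 px (≈ 1.767 µm at 0.411 µm/pixel) is 0.47 % low — the residual
piecewise-linear pixelation error at ~4.3 samples per period, the only
error source this estimator has (boundary bias is absent by construction).
The `contrast` column is the relative depth of the located minimum; values
below the 0.1 threshold are reported as invalid rather than guessed.

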