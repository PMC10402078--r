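---
title: "Deblurring by pixel reassignment: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deblurring by pixel reassignment: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpr)
```

## The model

A fluorescence microscope images each point source as its point spread
function (PSF): the recorded image is the sample convolved with a blur
kernel whose width sets the resolution. Deconvolution undoes this blur by
division in Fourier space (Wiener) or by iteration (Richardson–Lucy), but
both amplify noise near the diffraction limit and need regularization or a
stopping rule. This package takes a different route, operating entirely in
real space and in a single pass: every pixel's intensity is *displaced*
toward where its photons most likely originated, under the single
assumption that PSF centroids coincide with local intensity peaks.

The displacement direction and magnitude come from the **log-image
gradient** $\nabla \log I = \nabla I / I$. For a Gaussian PSF of RMS width
$\sigma$, $\nabla \log I = -\mathbf{r}/\sigma^2$: the field points at the
centre with magnitude proportional to distance, so reassignment contracts
the spot linearly about its peak. Because intensity is only moved — each
source pixel's value is split over the four grid points surrounding its
landing position with bilinear weights that sum to one — the method
conserves total intensity exactly, can never produce negative values, and
touches flat regions not at all (zero gradient means zero displacement, so
extended structures keep their interiors, unlike radiality- or
curvature-based sharpening which hollows them out).

## The pipeline

`run_dpr_frame()` / `run_dpr_stack()` apply, in order:

1. **Background subtraction** — each frame's global minimum is removed
   (per frame, so drifting offsets do not leak across time).
2. **Normalization** — division by the single stack-wide maximum
   (`per_frame_norm = TRUE` switches to per-frame maxima). Stack-wide
   scaling keeps frame-to-frame ratios intact, which the temporal
   variance needs to be meaningful.
3. **Local equalization** — subtraction of a disk local-minimum filter
   (radius `local_min_radius_px`), removing slowly varying background so
   the vector field follows structure rather than pedestals. Radius 0
   disables the step; a radius larger than the frame degenerates to
   global-minimum subtraction.
4. **Subpixel resampling** — separable cubic-spline interpolation onto a
   grid of period PSF FWHM / 8, so the PSF always spans 8 subpixels
   regardless of camera sampling. Negative spline overshoots are clamped
   to 0.
5. **Zero padding** — `pad_subpx` (default 16) zeros on every side, so
   border-directed reassignments land on the canvas; the padding is
   removed at the end. Splats into the border are the only intensity a
   run can lose, and only for structure within the cap distance of the
   frame edge.
6. **Local normalization** — the equalized image is divided by a Gaussian
   lowpass of itself (`lowpass_sigma_subpx`, default 8 subpixels = one
   PSF FWHM), flattening large-scale brightness so dim and bright
   regions steer reassignment equally.
7. **Vector field** — raw (unnormalized) 3×3 Sobel responses of the
   locally normalized image, divided by the pixel values plus
   `gradient_offset`, times `gain`. Vectors longer than 10 subpixels
   (1.25 PSF FWHM) are zeroed — the pixel stays put — never rescaled.
8. **Reassignment** — bilinear scatter ("splatting") of the resampled
   *input* image (not the equalized one) along the field.
9. **Temporal reduction** — optional pixelwise mean and/or population
   variance (divide by $T$, the second-order fluctuation convention)
   across the enhanced frames. `reduce_first = TRUE` instead averages raw
   frames before one DPR pass; it is offered for comparison and is
   inferior, because averaging washes out the structure the gradient
   field feeds on.

## Parameters that matter

| parameter | unit | default | role |
|---|---|---|---|
| `psf_fwhm_px` | raw px | — | sets the fine-grid period (FWHM/8); need not be exact; `rayleigh_resolution(lambda, NA)/pixel_size` is a fine estimate |
| `gain` | — | 1 | scales every displacement; more gain, more sharpening, more under-separation bias |
| `local_min_radius_px` | raw px | 0 (off) | background equalization scale; practical values a few times the PSF FWHM |
| `gradient_offset` | — | 0.01 | stabilizes the division in dark regions (~1% of the locally normalized scale) |
| `lowpass_sigma_subpx` | subpx | 8 | local-normalization scale; one PSF FWHM |
| `pad_subpx` | subpx | 16 | reassignment canvas margin; must be ≥ the 10-subpixel cap |

Two constants are fixed by design and validated in `dpr_config()`: 8
subpixels per PSF FWHM, and the displacement cap of 10 subpixels = 1.25
FWHM with *zeroing* semantics.

## Measured gain response, and a convention that had to be chosen

The only genuinely open numerical convention in the algorithm is the
scale of the discrete gradient: a 3×3 Sobel response can be reported raw
(a unit slope gives 8) or normalized by its weight sum. This package uses
the **raw** response. On the fine grid a Gaussian PSF spans 8 subpixels,
so the raw Sobel approximates $8\,\partial I$ and the field magnitude is
$\approx 8 g r/\sigma_n^2$ — about $0.6\,g\,r$ per unit gain once the
lowpass widening is accounted for. A normalized Sobel would move pixels
by well under a subpixel and do essentially nothing.

With this convention the package's own measurements (computed by the test
suite and by `scripts/acceptance.R`) on a noiseless Gaussian spot with
FWHM = 8 subpixels are:

* FWHM reduction ≈ **2.2×** at gain 1 and ≈ **6.1×** at gain 2;
* minimum Sparrow-resolvable two-point separation ≈ **1.20 σ** at gains 1
  and 2, versus ≈ **2.02 σ** for the unprocessed two-Gaussian image
  (the closed-form Sparrow limit is exactly 2 σ) — an enhancement ratio
  of ≈ **0.59**;
* at 1.66 σ separation and gain 1 the dip factor is ≈ 0.90; at 1.43 σ and
  gain 2, ≈ 0.81.

A caution about chasing stronger sharpening by rescaling the field: the
measured FWHM reduction is **not monotone** in the total field strength.
A controlled experiment with a synthetic linear contraction field
$d = -c\,\mathbf{r}$ (capped and splatted exactly as in the pipeline)
shows the reduction peaking near 8× at $c = 1$ and then *collapsing* as
pixels overshoot the centre and fold over ($c = 1.5$ measures worse than
$c = 0.6$). Since the field scales linearly with gain, no scalar gradient
convention can make both working points sit at the fold-free optimum at
once; the raw-Sobel choice puts gain 2 close to the peak of the curve
while gain 1 remains conservative. Users who want maximum single-image
sharpening should prefer gain 2; users who care about separation accuracy
should prefer gain 1 (peaks closer than ~1.9 σ are pulled toward each
other, with a bias that grows with gain — see `separation_error()`).

## What the phantoms emulate — and what they do not

`render_phantom()` produces the noiseless test objects used throughout:
point sources as *analytic* Gaussians sampled at pixel centres (not
deltas convolved numerically, avoiding discretization error), line pairs
as Gaussian-profile ridges, and a Siemens star (binary template, 4×
supersampled, then PSF-convolved). `add_noise()` applies Poisson shot
noise plus Gaussian readout noise, clipped at zero like a real detector
(the clip slightly biases the mean upward at very low SNR — documented,
not corrected). The peak signal-to-noise ratio follows
$\mathrm{SNR} = I_0/\sqrt{I_0 + \sigma_\mathrm{read}^2}$, and
`solve_i0_for_snr()` inverts it in closed form, so stacks at SNR 5.0,
7.7, 14.1 and 20.3 (the standard comparison points) are one call away.
The classic two-point benchmark is σ = 84.93 nm on a 40 nm grid at
160 nm separation, 45 frames per SNR; the readout level is set to 4
counts here since only the resulting SNR is specified by the benchmark.

The phantoms deliberately do **not** model emitter photophysics
(blinking/bleaching), aberrations, scattering backgrounds, or pixel
cross-talk. Passing the phantom suites therefore demonstrates the
geometry and statistics of the method — sharpening, conservation,
noise-response trends — not performance on any particular real sample.

## Numerical choices

* **Interpolation**: separable natural cubic splines (`stats::spline`,
  FMM boundary); overshoots clamped at 0.
* **Boundary handling**: every neighbourhood filter (Sobel, minimum
  filter, Gaussian lowpass, box average) replicates edges; zeros are
  used only for the reassignment canvas.
* **Tie-breaks**: a landing point exactly on a grid point receives the
  full value through degenerate bilinear weights; no special case.
* **Cap semantics**: over-cap vectors are zeroed, not rescaled — a pixel
  whose reassignment would be implausibly long is left untouched.
* **Peak localization**: 3-point parabolic refinement, accurate to about
  0.1 subpixel on Gaussian peaks; `dip_between_peaks()` requires a
  strict interior minimum (relative depth > 1e-3) and ignores candidate
  peaks below 30% of the profile maximum to reject tail ripples. The dip
  factor is normalized by the mean of the two peak values by default
  (`denominator = "max"` is available).
* **Conservation statistic**: `local_conservation_curve()` evaluates
  std(blurred difference)/mean(blurred raw) over a *fixed* signal
  support — the region where the unblurred raw image exceeds 1% of its
  maximum — so the curve is comparable across kernel sizes. On the
  Gaussian-spot phantom it decreases monotonically and is far below 10%
  by a kernel of 4.5 PSF FWHM (36 subpixels).
* **Temporal variance**: population convention (divide by $T$).
* **Seeds**: frame $t$ of a noisy stack uses `seed + t - 1`, so any
  sub-range of a stack can be regenerated independently.
* **Output canvas**: an $N$-pixel frame resamples to
  $\lfloor (N-1)\cdot 8/\mathrm{FWHM} \rfloor + 1$ fine pixels; padding
  is an implementation detail removed before output, so enhanced frames
  are slightly different in size from a naive $8N/\mathrm{FWHM}$.

## Problem sizes used by the tests

The suites run on deliberately small canvases: 33–81 raw pixels for
pipeline and phantom tests, 45-frame stacks at four SNR levels for the
noisy-stack trend check, and 0.01 σ-precision separation scans bracketed
coarsely at 0.1 σ. These sizes put every statistic well into its
converged regime for the isolated-spot and two-point geometries (checked
against 97- and 129-pixel canvases during development) while keeping the
whole suite fast.

## Known limitations

* Reassignment is strictly 2D; axial (z) blur is untouched.
* The temporal variance output is nonlinear in sample brightness; only
  the temporal mean preserves the linear sample–image relation.
* Sub-Sparrow pairs are resolved at the price of an under-separation
  bias growing with gain; report separations from gain-1 runs, or
  correct with `separation_error()` calibrations on matched phantoms.
* The local-minimum filter radius is the one parameter with no safe
  universal default: too small erodes real structure, too large leaves
  background. Radii of 1.5–3 PSF FWHM work well on the phantom suite.
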