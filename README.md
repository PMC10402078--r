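# dpr — deblurring by pixel reassignment

Fluorescence microscopy images are blurred by the microscope's point
spread function (PSF). Classical remedies — Wiener or Richardson–Lucy
deconvolution — work in Fourier space or by iteration and amplify noise
near the diffraction limit unless carefully regularized. `dpr`
implements a single-pass, real-space alternative for microscopists and
image-analysis pipelines: every pixel's intensity is displaced along the
locally normalized image gradient (the log-image gradient
∇ log I = ∇I / I), which points at PSF centroids, and is deposited on
the four surrounding grid points with bilinear weights.

Because intensity is *moved*, never rescaled in place:

* total intensity is conserved exactly (to floating point);
* no negative values can arise;
* zero-gradient regions are fixed points — large structures keep their
  interiors and only their edges sharpen.

For a Gaussian PSF of RMS width σ the log-image gradient is −**r**/σ²,
so reassignment is a linear contraction about the peak, scaled by a user
gain g and hard-limited to displacements of 1.25 PSF FWHM. The package
contains the full pipeline for frames and time stacks (background
subtraction, local equalization by disk minimum filter, cubic-spline
resampling to a PSF-FWHM/8 grid, Sobel-based vector fields, bilinear
splatting, temporal mean/variance), the synthetic phantoms used to
characterize it (Gaussian point/line pairs, Siemens stars, Poisson +
Gaussian camera noise at controlled SNR), and resolution metrics (FWHM,
two-point dip factor, Sparrow-criterion scans, separation error, local
intensity conservation, error maps, SSIM).

## Worked example

Sharpen a noiseless Gaussian spot rendered on the engine's fine grid
(PSF FWHM = 8 px, so the resampling factor is 1):

```r
library(dpr)
n <- 65; s <- 8 / 2.3548
x <- 1:n
spot <- outer(exp(-(x - 33)^2 / (2 * s^2)), exp(-(x - 33)^2 / (2 * s^2)))
cfg <- dpr_config(psf_fwhm_px = 8, gain = 1)
out <- run_dpr_frame(spot, cfg)
measure_fwhm(spot)                        # 8.000073
measure_fwhm(out)                         # 3.654672
attr(out, "conservation_residual")        # 0
```

The spot's full width at half maximum drops from 8.0 to 3.65 subpixels
(a 2.2× reduction at gain 1; gain 2 gives ≈ 6.1×) while the padded-canvas
intensity balance is conserved to machine precision.

A noisy two-point benchmark: two sources 160 nm apart imaged with a
σ = 84.93 nm Gaussian PSF on a 40 nm grid — 1.88 σ separation, below the
2 σ Sparrow limit, so the raw image shows a single blob:

```r
sp <- phantom_spec("two_points", sigma = 84.93, separation = 160,
                   grid_pitch = 40, image_size = 33,
                   i0 = solve_i0_for_snr(14.1, readout_sigma = 4))  # I0 = 213.7
st  <- make_noisy_stack(sp, noise_model(readout_sigma = 4, seed = 7), 45)
res <- run_dpr_stack(st, dpr_config(psf_fwhm_px = 5, gain = 1,
                                    temporal_mode = "mean"))
dip_between_peaks(peak_profile(res$temporal_mean, "x"))
#> <resolution_report> resolved | dip factor 0.695 | separation 6.72 samples
```

After per-frame DPR and temporal averaging the pair is resolved with a
clear dip (0.695) and a measured separation of 6.72 subpixels against a
ground truth of 6.40 — a 0.32-subpixel (≈ 13 nm) error at SNR 14.1.

## Command line

A thin CLI over the same functions ships in `inst/cli/dpr.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/dpr.R", package = "dpr"))')
Rscript $CLI simulate two-points --sigma 84.93 --separation 160 --pitch 40 \
        --i0 200 --readout 4 --frames 45 --seed 3 -o tp.tif
Rscript $CLI process tp.tif --psf-fwhm 5 --gain 1 --temporal mean -o tp_dpr.tif
Rscript $CLI evaluate two-point-scan --gain 2 --json scan.json
```

`process` accepts 8/16-bit integer and 32-bit float grayscale TIFFs
(multi-page = time), writes 32-bit float TIFF output plus a JSON run
manifest, and logs stage timings and the conservation residual.

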