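# Shared fixtures, all generated in code.

# Isotropic Gaussian spot sampled at pixel centres (peak 1).
gauss_spot <- function(n, sigma, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  x <- seq_len(n)
  outer(exp(-(x - cy)^2 / (2 * sigma^2)), exp(-(x - cx)^2 / (2 * sigma^2)))
}

# Two-point image: Gaussians at +/- sep/2 along x (peak of each 1).
two_point_image <- function(n, sigma, sep, cx = (n + 1) / 2) {
  x <- seq_len(n)
  gy <- exp(-(x - (n + 1) / 2)^2 / (2 * sigma^2))
  outer(gy, exp(-(x - cx - sep / 2)^2 / (2 * sigma^2))) +
    outer(gy, exp(-(x - cx + sep / 2)^2 / (2 * sigma^2)))
}

# Dense 1-D evaluation of a symmetric two-Gaussian sum (the analytic
# oracle for dip factors and peak positions, independent of the engine).
two_gauss_profile <- function(sep_sigma, sigma = 1, step = 1e-3) {
  x <- seq(-4 * sigma - sep_sigma * sigma, 4 * sigma + sep_sigma * sigma, by = step)
  h <- sep_sigma * sigma / 2
  list(x = x, y = exp(-(x - h)^2 / (2 * sigma^2)) + exp(-(x + h)^2 / (2 * sigma^2)))
}

default_cfg <- function(...) dpr_config(psf_fwhm_px = 4, ...)
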