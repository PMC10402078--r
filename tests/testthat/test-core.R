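test_that("local equalization removes pedestals and matches a sliding-min oracle", {
  n <- 41
  frame <- gauss_spot(n, 2) + 0.3            # peak on a flat pedestal
  eq <- local_equalize(frame, radius_px = 15)
  expect_true(all(abs(eq[1:5, 1:5]) < 1e-12))          # pedestal gone
  expect_equal(eq[21, 21], frame[21, 21] - 0.3, tolerance = 1e-6)
  # strictly increasing ramp, radius 1: output = ramp - left/up-neighbour min
  ramp <- outer(1:6, 1:6, function(i, j) i + 10 * j)
  eq1 <- local_equalize(ramp, 1)
  brute <- ramp
  for (i in 1:6) for (j in 1:6) {
    vals <- c()
    for (d in list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      vals <- c(vals, ramp[min(max(i + d[1], 1), 6), min(max(j + d[2], 1), 6)])
    }
    brute[i, j] <- ramp[i, j] - min(vals)
  }
  expect_equal(eq1, brute)
  expect_identical(local_equalize(frame, 0), frame)    # radius 0 disables
  expect_true(all(local_equalize(frame, 3) >= 0))
  # radius beyond the frame: global-min subtraction
  expect_equal(local_equalize(frame, 100), frame - min(frame))
})

test_that("figure-caption settings run cleanly on a two-line phantom", {
  spec <- phantom_spec("two_lines", sigma = 4 / 2.3548, separation = 8,
                       grid_pitch = 1, image_size = 49)
  img <- render_phantom(spec)
  out <- run_dpr_frame(img, dpr_config(psf_fwhm_px = 4, gain = 2,
                                       local_min_radius_px = 7))
  expect_true(all(out$data >= 0))
  expect_true(max(out$data) > 0)
})

test_that("local normalization flattens smooth images to ~1 and keeps gradient directions", {
  const <- local_normalize(matrix(3, 33, 33), 4)
  expect_equal(const[10:24, 10:24], matrix(1, 15, 15), tolerance = 1e-6)
  # very smooth image ~ its own lowpass
  smooth <- gaussian_lowpass(gauss_spot(41, 12), 2) + 1
  ln <- local_normalize(smooth, 2)
  expect_true(all(abs(ln[5:37, 5:37] - 1) < 0.05))
  # normalization must not turn the gradient field away from the spot core
  spot <- gauss_spot(61, 6)
  ln2 <- local_normalize(spot, 8, eps = 1e-8)
  g_raw <- sobel_gradients(spot)
  g_nrm <- sobel_gradients(ln2)
  core <- as.vector(abs(row(spot) - 31) <= 8 & abs(col(spot) - 31) <= 8 &
                      (row(spot) != 31 | col(spot) != 31))
  ang <- function(g) atan2(as.vector(g$gy)[core], as.vector(g$gx)[core])
  dd <- (ang(g_raw) - ang(g_nrm) + pi) %% (2 * pi) - pi
  expect_true(max(abs(dd)) < 0.05)
})

test_that("displacement field follows gain x Sobel / (value + offset), capped by zeroing", {
  expect_equal(compute_displacement_field(matrix(1, 9, 9), gain = 2)$dx,
               matrix(0, 9, 9))                        # constant -> zero field
  # hand-computed responses on a small frame, gain small enough to stay
  # under the cap
  set.seed(3)
  m <- matrix(runif(25, 0.5, 1), 5, 5)
  g <- sobel_gradients(m)
  f <- compute_displacement_field(m, gain = 0.5, gradient_offset = 0.01)
  expect_equal(f$dx, 0.5 * g$gx / (m + 0.01))
  expect_equal(f$dy, 0.5 * g$gy / (m + 0.01))
  # vectors beyond the cap are zeroed, never rescaled
  spike <- matrix(1e-4, 7, 7); spike[4, 4] <- 1
  fs <- compute_displacement_field(spike, gain = 5, gradient_offset = 1e-4,
                                   cap_subpx = 10)
  len <- sqrt(fs$dx^2 + fs$dy^2)
  expect_true(all(len <= 10 + 1e-12))
  expect_true(any(fs$dx == 0 & fs$dy == 0))
  raw_len <- with(sobel_gradients(spike),
                  sqrt((5 * gx / (spike + 1e-4))^2 + (5 * gy / (spike + 1e-4))^2))
  expect_true(all(len[raw_len > 10] == 0))
})

test_that("for a Gaussian spot the field is radial, inward, linear in distance", {
  spot <- gauss_spot(81, 8 / 2.3548)        # PSF FWHM 8 subpixels
  f <- compute_displacement_field(spot, gain = 1, gradient_offset = 0.01)
  ctr <- 41
  rr <- 2:8                                  # central region, along +x
  dx <- f$dx[ctr, ctr + rr]
  expect_true(all(dx < 0))                   # pointing back toward the centre
  fit <- stats::lm(dx ~ 0 + rr)
  expect_gt(summary(fit)$r.squared, 0.99)    # magnitude linear in distance
  expect_equal(f$dy[ctr, ctr + rr], numeric(length(rr)), tolerance = 1e-10)
})

test_that("reassignment splats bilinearly and conserves intensity exactly", {
  m <- matrix(runif(81), 9, 9)
  zero <- compute_displacement_field(matrix(1, 9, 9), gain = 0)
  expect_identical(reassign_pixels(m, zero), m)        # identity
  one <- matrix(0, 9, 9); one[5, 5] <- 1
  f <- zero; f$dx[5, 5] <- 1                           # integer displacement
  moved <- reassign_pixels(one, f)
  expect_equal(moved[5, 6], 1)
  expect_equal(sum(moved), 1)
  f$dx[5, 5] <- 0.25; f$dy[5, 5] <- 0.75               # fractional landing
  frac <- reassign_pixels(one, f)
  expect_equal(frac[5, 5], 0.75 * 0.25)                # (1-dx)(1-dy)
  expect_equal(frac[5, 6], 0.25 * 0.25)                # dx(1-dy)
  expect_equal(frac[6, 5], 0.75 * 0.75)                # (1-dx)dy
  expect_equal(frac[6, 6], 0.25 * 0.75)                # dx dy
  expect_equal(sum(frac), 1)
})

test_that("vectorized splatting equals the naive per-pixel double loop", {
  naive_splat <- function(m, dx, dy) {
    ny <- nrow(m); nx <- ncol(m)
    out <- matrix(0, ny, nx)
    for (corner in 1:4) {
      for (j in seq_len(nx)) for (i in seq_len(ny)) {
        v <- m[i, j]
        if (v <= 0) next
        ly <- i + dy[i, j]; lx <- j + dx[i, j]
        y0 <- floor(ly); x0 <- floor(lx)
        fy <- ly - y0; fx <- lx - x0
        w <- switch(corner, (1 - fy) * (1 - fx), (1 - fy) * fx,
                    fy * (1 - fx), fy * fx)
        yy <- y0 + c(0L, 0L, 1L, 1L)[corner]
        xx <- x0 + c(0L, 1L, 0L, 1L)[corner]
        if (w > 0) out[yy, xx] <- out[yy, xx] + w * v
      }
    }
    out
  }
  set.seed(42)
  for (rep in 1:4) {
    m <- matrix(runif(32 * 32), 32, 32)
    dx <- matrix(runif(32 * 32, -3, 3), 32, 32)
    dy <- matrix(runif(32 * 32, -3, 3), 32, 32)
    # keep landings inside the canvas for this shape-level check
    dx[, 1:4] <- abs(dx[, 1:4]); dx[, 29:32] <- -abs(dx[, 29:32])
    dy[1:4, ] <- abs(dy[1:4, ]); dy[29:32, ] <- -abs(dy[29:32, ])
    field <- structure(list(dx = dx, dy = dy, cap_subpx = 10),
                       class = "displacement_field")
    expect_equal(reassign_pixels(m, field), naive_splat(m, dx, dy),
                 tolerance = 1e-14)
  }
})

test_that("the full frame pipeline conserves, stays non-negative, and is gain-monotone", {
  spot <- gauss_spot(49, 4 / 2.3548)
  cfg0 <- default_cfg(gain = 0)
  out0 <- run_dpr_frame(spot, cfg0)
  # gain 0 equals the preconditioned, resampled input
  pre <- normalize_stack(subtract_background(image_stack(spot)), per_frame = TRUE)
  expect_equal(out0$data, resample_to_subpixel(pre$frames[[1]], 4)$data,
               tolerance = 1e-12)
  fw <- vapply(c(0, 0.5, 1, 1.5, 2), function(g) {
    out <- run_dpr_frame(spot, default_cfg(gain = g))
    expect_true(all(out$data >= 0))
    expect_lt(attr(out, "conservation_residual"), 1e-9)
    measure_fwhm(out$data)
  }, numeric(1))
  expect_true(all(diff(fw) <= 1e-9))         # FWHM non-increasing in gain
})

test_that("brightness scaling and mirror symmetry are preserved", {
  spot <- gauss_spot(49, 4 / 2.3548)
  cfg <- default_cfg(gain = 1)
  a <- run_dpr_frame(spot, cfg)
  b <- run_dpr_frame(37.5 * spot, cfg)       # max-normalization cancels scale
  expect_equal(a$data, b$data, tolerance = 1e-12)
  expect_equal(a$data, t(a$data), tolerance = 1e-9)            # x/y mirror
  expect_equal(a$data, a$data[nrow(a$data):1, ], tolerance = 1e-9)
  # centroid of the symmetric spot stays put to within a subpixel
  w <- a$data / sum(a$data)
  cy <- sum(row(a$data) * w); cx <- sum(col(a$data) * w)
  expect_equal(cy, (nrow(a$data) + 1) / 2, tolerance = 1)
  expect_equal(cx, (ncol(a$data) + 1) / 2, tolerance = 1)
})

test_that("zero-gradient regions are fixed points of reassignment", {
  # flat-interior plateau much wider than the lowpass reach: the vector
  # field vanishes in the interior, so DPR sharpens only the edges
  m <- matrix(0, 81, 81); m[11:71, 11:71] <- 1
  eqn <- local_normalize(m, 4)        # kernel reach 12 px < 20 px margin
  f <- compute_displacement_field(eqn, gain = 1)
  inner <- 31:51
  expect_equal(f$dx[inner, inner], matrix(0, 21, 21), tolerance = 1e-9)
  expect_equal(f$dy[inner, inner], matrix(0, 21, 21), tolerance = 1e-9)
  # and a uniformly zero field reproduces the image bit-for-bit
  zf <- compute_displacement_field(matrix(1, 81, 81), gain = 1)
  expect_identical(reassign_pixels(m, zf), m)
})

test_that("stack runs reduce correctly over time", {
  spot <- gauss_spot(33, 4 / 2.3548)
  stack <- image_stack(list(spot, spot, spot))
  res <- run_dpr_stack(stack, default_cfg(gain = 1, temporal_mode = "both"))
  single <- run_dpr_frame(spot, default_cfg(gain = 1))
  expect_equal(res$temporal_mean, single$data, tolerance = 1e-12)
  expect_equal(res$temporal_var, 0 * res$temporal_var)
  expect_length(res$enhanced, 3)
  expect_error(run_dpr_stack(image_stack(spot), default_cfg(temporal_mode = "var")),
               "at least 2 frames")
  # population variance (divide by T) on a genuinely varying stack
  stack2 <- image_stack(list(spot, 3 * spot))
  r2 <- run_dpr_stack(stack2, default_cfg(gain = 0, temporal_mode = "var",
                                          per_frame_norm = FALSE))
  e <- lapply(r2$enhanced, `[[`, "data")
  expect_equal(r2$temporal_var, (e[[1]] - e[[2]])^2 / 4, tolerance = 1e-12)
  # reduce-first averages the raw frames then runs one DPR pass
  rf <- run_dpr_stack(stack2, default_cfg(gain = 1, temporal_mode = "mean",
                                          reduce_first = TRUE))
  expect_length(rf$enhanced, 1)
})

test_that("Rayleigh resolution follows 0.61 lambda / NA", {
  expect_equal(rayleigh_resolution(520, 0.8), 396.5)
  expect_equal(rayleigh_resolution(610, 1.0), 372.1)
  expect_equal(rayleigh_resolution(520, 0.8) / rayleigh_resolution(520, 1.6), 2)
  expect_error(rayleigh_resolution(-520, 0.8))
  expect_error(rayleigh_resolution(520, 0))
  expect_error(rayleigh_resolution(520, 1.8))
})
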