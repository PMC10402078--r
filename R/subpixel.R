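#' Subpixel frames
#'
#' A `subpixel_frame` is one image frame living on the engine's fine grid,
#' whose period is 1/8 of the PSF FWHM in raw-pixel units (so the PSF
#' always spans 8 subpixels regardless of the camera sampling). It keeps
#' the bookkeeping needed to undo zero padding exactly.
#'
#' @param data numeric matrix of non-negative fine-grid intensities.
#' @param subpx_per_raw_px resampling factor (fine pixels per raw pixel).
#' @param pad current zero-padding width in subpixels (0 if unpadded).
#' @param provenance free-form note on where the frame came from.
#' @return an object of class `subpixel_frame`.
#' @export
subpixel_frame <- function(data, subpx_per_raw_px, pad = 0L, provenance = NULL) {
  stopifnot(is.matrix(data), is.numeric(data),
            is.numeric(subpx_per_raw_px), subpx_per_raw_px > 0,
            pad >= 0)
  structure(list(data = data, subpx_per_raw_px = subpx_per_raw_px,
                 pad = as.integer(pad), provenance = provenance),
            class = "subpixel_frame")
}

#' @export
print.subpixel_frame <- function(x, ...) {
  cat(sprintf("<subpixel_frame> %d x %d, %.3g subpx per raw px, pad %d%s\n",
              nrow(x$data), ncol(x$data), x$subpx_per_raw_px, x$pad,
              if (is.null(x$provenance)) "" else paste0(" (", x$provenance, ")")))
  invisible(x)
}

.frame_data <- function(x) if (inherits(x, "subpixel_frame")) x$data else x

#' Resample a frame onto the fine (subpixel) grid
#'
#' Maps a raw frame onto a grid of period `psf_fwhm_px / 8` raw pixels by
#' separable cubic-spline interpolation, so the PSF FWHM spans 8
#' subpixels. Negative interpolation overshoots are clamped to 0 to keep
#' every pipeline stage non-negative. A FWHM of 8 raw pixels gives factor
#' 1 and returns the frame on its own grid.
#'
#' @param frame numeric matrix (one raw frame).
#' @param psf_fwhm_px estimated PSF FWHM in raw pixels (> 0).
#' @param max_factor largest admissible upsampling factor (default 16);
#'   a smaller FWHM than 8/`max_factor` raw pixels is rejected as
#'   misspecified.
#' @return a [subpixel_frame()] (unpadded).
#' @examples
#' f <- matrix(runif(64), 8, 8)
#' resample_to_subpixel(f, psf_fwhm_px = 4)  # 2x upsampling -> 15 x 15
#' @export
resample_to_subpixel <- function(frame, psf_fwhm_px, max_factor = 16) {
  stopifnot(is.matrix(frame), psf_fwhm_px > 0)
  factor <- 8 / psf_fwhm_px
  if (factor > max_factor) {
    stop(sprintf(paste0("psf_fwhm_px = %g implies a %.1fx upsampling (limit %g); ",
                        "the PSF FWHM is probably misspecified"),
                 psf_fwhm_px, factor, max_factor))
  }
  period <- psf_fwhm_px / 8
  if (isTRUE(all.equal(period, 1))) {
    return(subpixel_frame(frame, 1, pad = 0L, provenance = "identity resample"))
  }
  nx <- ncol(frame)
  ny <- nrow(frame)
  xout <- seq(1, nx, by = period)
  yout <- seq(1, ny, by = period)
  tmp <- matrix(0, ny, length(xout))
  for (i in seq_len(ny)) {
    tmp[i, ] <- stats::spline(seq_len(nx), frame[i, ], xout = xout, method = "fmm")$y
  }
  out <- matrix(0, length(yout), length(xout))
  for (j in seq_along(xout)) {
    out[, j] <- stats::spline(seq_len(ny), tmp[, j], xout = yout, method = "fmm")$y
  }
  subpixel_frame(pmax(out, 0), 1 / period, pad = 0L, provenance = "spline resample")
}

#' Zero-pad / crop the reassignment canvas
#'
#' `pad_frame()` surrounds the fine grid with a zero border of `pad_subpx`
#' subpixels so off-image reassignments land on the canvas instead of
#' being lost; `crop_pad()` removes the border exactly, making
#' `crop_pad(pad_frame(x, p))` bit-for-bit equal to `x`. Intensity
#' splatted into the border is retained while padded and discarded by the
#' crop (that deficit is the only intensity DPR can lose).
#'
#' @param sub a [subpixel_frame()] (or plain matrix, treated as unpadded).
#' @param pad_subpx border width in subpixels; must be at least the
#'   displacement cap in force (10 by default) so no vector can leave the
#'   canvas.
#' @param cap_subpx the displacement cap used for validation.
#' @return a `subpixel_frame` with updated `pad`.
#' @export
pad_frame <- function(sub, pad_subpx, cap_subpx = 10) {
  if (!inherits(sub, "subpixel_frame")) sub <- subpixel_frame(sub, 1)
  pad_subpx <- as.integer(pad_subpx)
  if (pad_subpx < cap_subpx) {
    stop(sprintf("pad_subpx (%d) must be >= the displacement cap (%g)", pad_subpx, cap_subpx))
  }
  if (sub$pad > 0L) stop("frame is already padded")
  m <- sub$data
  out <- matrix(0, nrow(m) + 2L * pad_subpx, ncol(m) + 2L * pad_subpx)
  out[pad_subpx + seq_len(nrow(m)), pad_subpx + seq_len(ncol(m))] <- m
  sub$data <- out
  sub$pad <- pad_subpx
  sub
}

#' @rdname pad_frame
#' @export
crop_pad <- function(sub) {
  stopifnot(inherits(sub, "subpixel_frame"))
  if (sub$pad == 0L) stop("frame is not padded; nothing to crop")
  p <- sub$pad
  m <- sub$data
  sub$data <- m[(p + 1L):(nrow(m) - p), (p + 1L):(ncol(m) - p), drop = FALSE]
  sub$pad <- 0L
  sub
}
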