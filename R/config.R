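#' DPR run configuration
#'
#' Collects every user parameter of one DPR run and validates the
#' invariants that tie them together. Two quantities are fixed by the
#' algorithm's design and are not user-settable: the fine grid always
#' spans the PSF full width at half maximum (FWHM) with 8 subpixels
#' (grid period = `psf_fwhm_px / 8` raw pixels), and reassignment
#' vectors are hard-limited to 10 subpixels = 1.25 PSF FWHM (longer
#' vectors are zeroed, leaving those pixels in place).
#'
#' @param psf_fwhm_px estimated PSF FWHM in raw-pixel units (> 0). Need
#'   not be exact; [rayleigh_resolution()] divided by the physical pixel
#'   size gives a reasonable estimate.
#' @param gain scalar reassignment gain (>= 0). Larger gain sharpens more
#'   but biases nearby sources toward each other; 1 and 2 are the usual
#'   working points, 0 disables reassignment entirely.
#' @param local_min_radius_px radius of the local-minimum (background
#'   equalization) filter in raw pixels; 0 disables local equalization.
#' @param temporal_mode one of `"none"`, `"mean"`, `"var"`, `"both"`:
#'   which temporal reduction(s) of the per-frame DPR outputs to compute.
#' @param gradient_offset small positive constant added to the locally
#'   normalized image before dividing the Sobel responses by it; keeps
#'   the log-image gradient finite and soft-limits vectors in dark
#'   regions. The locally normalized image has typical scale ~1, so the
#'   default 0.01 is 1% of signal.
#' @param lowpass_sigma_subpx standard deviation, in subpixels, of the
#'   Gaussian lowpass used for local normalization. Default 8 subpixels
#'   = one PSF FWHM.
#' @param pad_subpx zero-padding width in subpixels added around the fine
#'   grid before reassignment and removed at the end; must be at least
#'   the displacement cap (10).
#' @param per_frame_norm normalize each frame to its own maximum instead
#'   of the stack-wide maximum.
#' @param reduce_first average the raw frames before applying DPR once,
#'   instead of applying DPR per frame and then reducing. Offered for
#'   comparison experiments; per-frame DPR then reduction is the
#'   recommended order because averaging first washes out the spatial
#'   structure the gradient field feeds on.
#' @param max_upsample largest admissible resampling factor (8 /
#'   `psf_fwhm_px`); guards against a misspecified, too-small FWHM.
#' @param strict abort a run whose padded-canvas conservation residual
#'   exceeds 1e-6 (relative).
#' @return an object of class `dpr_config` (a validated named list, with
#'   derived constants `subpx_per_fwhm = 8` and
#'   `displacement_cap_subpx = 10`).
#' @examples
#' dpr_config(psf_fwhm_px = 4, gain = 1, local_min_radius_px = 7)
#' @export
dpr_config <- function(psf_fwhm_px,
                       gain = 1,
                       local_min_radius_px = 0,
                       temporal_mode = c("none", "mean", "var", "both"),
                       gradient_offset = 0.01,
                       lowpass_sigma_subpx = 8,
                       pad_subpx = 16,
                       per_frame_norm = FALSE,
                       reduce_first = FALSE,
                       max_upsample = 16,
                       strict = FALSE) {
  temporal_mode <- match.arg(temporal_mode)
  subpx_per_fwhm <- 8L
  displacement_cap_subpx <- 1.25 * subpx_per_fwhm  # = 10 subpixels
  stopifnot(
    is.numeric(psf_fwhm_px), length(psf_fwhm_px) == 1L, psf_fwhm_px > 0,
    is.numeric(gain), length(gain) == 1L, gain >= 0,
    is.numeric(local_min_radius_px), local_min_radius_px >= 0,
    is.numeric(gradient_offset), gradient_offset > 0,
    is.numeric(lowpass_sigma_subpx), lowpass_sigma_subpx > 0,
    is.numeric(pad_subpx), is.numeric(max_upsample), max_upsample > 0,
    is.logical(per_frame_norm), is.logical(reduce_first), is.logical(strict)
  )
  pad_subpx <- as.integer(pad_subpx)
  if (pad_subpx < displacement_cap_subpx) {
    stop(sprintf("pad_subpx (%d) must be at least the displacement cap (%g subpixels)",
                 pad_subpx, displacement_cap_subpx))
  }
  if (subpx_per_fwhm / psf_fwhm_px > max_upsample) {
    stop(sprintf(paste0("psf_fwhm_px = %g would require a %0.1fx upsampling ",
                        "(limit %g); the PSF FWHM is probably misspecified"),
                 psf_fwhm_px, subpx_per_fwhm / psf_fwhm_px, max_upsample))
  }
  structure(list(
    psf_fwhm_px = psf_fwhm_px,
    gain = gain,
    local_min_radius_px = local_min_radius_px,
    temporal_mode = temporal_mode,
    subpx_per_fwhm = subpx_per_fwhm,
    displacement_cap_subpx = displacement_cap_subpx,
    gradient_offset = gradient_offset,
    lowpass_sigma_subpx = lowpass_sigma_subpx,
    pad_subpx = pad_subpx,
    per_frame_norm = per_frame_norm,
    reduce_first = reduce_first,
    max_upsample = max_upsample,
    strict = strict
  ), class = "dpr_config")
}

#' @export
print.dpr_config <- function(x, ...) {
  cat(sprintf(paste0("<dpr_config> PSF FWHM %g px | gain %g | local-min radius %g px | ",
                     "temporal %s\n  grid period FWHM/8, cap %g subpx, pad %d subpx, ",
                     "offset %g, lowpass sigma %g subpx\n"),
              x$psf_fwhm_px, x$gain, x$local_min_radius_px, x$temporal_mode,
              x$displacement_cap_subpx, x$pad_subpx, x$gradient_offset,
              x$lowpass_sigma_subpx))
  invisible(x)
}

#' Load a DPR configuration from a YAML/JSON file plus overrides
#'
#' Resolution order: package defaults, then the config file, then
#' `overrides` (e.g. parsed command-line flags). The merged set is passed
#' through [dpr_config()], so every invariant is validated before any
#' computation starts.
#'
#' @param path path to a YAML (or JSON, a YAML subset) file whose keys
#'   mirror the [dpr_config()] arguments; `NULL` for defaults only.
#' @param overrides named list of arguments taking precedence over the file.
#' @return a validated `dpr_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  args <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    args <- yaml::read_yaml(path)
    if (!is.list(args)) stop("config file must contain a mapping of parameter: value")
  }
  args[names(overrides)] <- overrides
  known <- names(formals(dpr_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(dpr_config, args)
}
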