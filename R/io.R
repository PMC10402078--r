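#' Read a grayscale TIFF (single- or multi-page) as an image stack
#'
#' Pages are read in file order as the time axis. Integer TIFFs (8/16
#' bit) are read with their native values preserved exactly; 32-bit
#' float TIFFs are returned as stored. RGB or other multi-channel
#' photometric layouts are rejected explicitly.
#'
#' @param path path to a TIFF file.
#' @param pixel_size optional physical pixel pitch recorded on the stack.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(
    tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
             error = function(e) {
               # float TIFFs reject as.is; they are returned unscaled anyway
               if (grepl("floating point", conditionMessage(e))) {
                 tiff::readTIFF(path, all = TRUE)
               } else {
                 stop(e)
               }
             }),
    error = function(e) stop("cannot read TIFF (truncated or not a TIFF?): ",
                             conditionMessage(e), call. = FALSE))
  if (is.matrix(pages) || (is.array(pages) && length(dim(pages)) == 3L)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] == 1L) p <- p[, , 1L]
      else stop("multi-channel (e.g. RGB) TIFF is not supported; provide grayscale input")
    }
    storage.mode(p) <- "double"
    p
  })
  image_stack(frames, pixel_size = pixel_size)
}

# Minimal uncompressed 32-bit IEEE-float grayscale multi-page TIFF writer
# (little-endian; one strip per page). Float samples preserve reassigned
# intensities above 1 exactly, which integer-scaled storage cannot.
.write_float_tiff <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  n <- length(frames)
  sizes <- vapply(frames, function(f) 4L * nrow(f) * ncol(f), integer(1))
  data_off <- 8L + c(0L, cumsum(sizes))[seq_len(n)]
  ifd_len <- 2L + 10L * 12L + 4L
  ifd_off <- 8L + sum(sizes) + ifd_len * (seq_len(n) - 1L)
  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(ifd_off[1L])
  for (f in frames) {
    writeBin(as.numeric(t(f)), con, size = 4L, endian = "little")
  }
  entry <- function(tag, type, value) {  # type 3 = SHORT, 4 = LONG
    w2(tag); w2(type); w4(1L)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (i in seq_len(n)) {
    f <- frames[[i]]
    w2(10L)
    entry(256L, 4L, ncol(f))            # ImageWidth
    entry(257L, 4L, nrow(f))            # ImageLength
    entry(258L, 3L, 32L)                # BitsPerSample
    entry(259L, 3L, 1L)                 # Compression: none
    entry(262L, 3L, 1L)                 # Photometric: BlackIsZero
    entry(273L, 4L, data_off[i])        # StripOffsets
    entry(277L, 3L, 1L)                 # SamplesPerPixel
    entry(278L, 4L, nrow(f))            # RowsPerStrip
    entry(279L, 4L, sizes[i])           # StripByteCounts
    entry(339L, 3L, 3L)                 # SampleFormat: IEEE float
    w4(if (i < n) ifd_off[i + 1L] else 0L)
  }
  invisible(path)
}

#' Write an image stack as a 32-bit float TIFF
#'
#' Writes an uncompressed grayscale multi-page TIFF with IEEE-float
#' samples (values preserved bit-exactly, including intensities above 1),
#' plus an optional JSON run-manifest sidecar (`<path>.json`) recording
#' how the stack was produced.
#'
#' @param stack an [image_stack()], [subpixel_frame()], matrix, or
#'   `dpr_result` (its enhanced frames are written).
#' @param path output TIFF path.
#' @param manifest optional [run_manifest()] written alongside.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, manifest = NULL) {
  frames <- if (inherits(stack, "dpr_result")) {
    lapply(stack$enhanced, `[[`, "data")
  } else if (inherits(stack, "subpixel_frame")) {
    list(stack$data)
  } else if (is.matrix(stack)) {
    list(stack)
  } else {
    as_image_stack(stack)$frames
  }
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "double"
    f
  })
  .write_float_tiff(frames, path)
  if (!is.null(manifest)) write_manifest(manifest, paste0(path, ".json"))
  invisible(path)
}

#' Run manifests
#'
#' A `run_manifest` records everything needed to reproduce one DPR run:
#' input path(s), the resolved configuration, seeds, the package version,
#' the conservation residual and per-stage wall-clock timings. Manifests
#' round-trip exactly through their JSON serialization.
#'
#' @param input input path(s) or a short description of the input.
#' @param config a [dpr_config()].
#' @param seed integer seed(s) used by any stochastic stage (NULL if none).
#' @param conservation_residual relative padded-canvas residual(s).
#' @param timings named numeric vector/list of per-stage seconds.
#' @return an object of class `run_manifest`.
#' @export
run_manifest <- function(input, config, seed = NULL,
                         conservation_residual = NULL, timings = NULL) {
  stopifnot(inherits(config, "dpr_config"))
  user <- config[c("psf_fwhm_px", "gain", "local_min_radius_px", "temporal_mode",
                   "gradient_offset", "lowpass_sigma_subpx", "pad_subpx",
                   "per_frame_norm", "reduce_first", "max_upsample", "strict")]
  structure(list(
    software = "dpr",
    version = as.character(utils::packageVersion("dpr")),
    input = input,
    config = user,
    seed = seed,
    conservation_residual = conservation_residual,
    timings = as.list(timings)
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$config <- as.list(x$config)
  cfg <- do.call(dpr_config, x$config)
  m <- run_manifest(x$input, cfg, seed = x$seed,
                    conservation_residual = x$conservation_residual,
                    timings = x$timings)
  m$version <- x$version
  m
}
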