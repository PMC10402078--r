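#' Image stacks
#'
#' An `image_stack` is an ordered sequence of 2D intensity frames sharing
#' one shape and (optionally) one physical pixel pitch. It is the container
#' for raw camera data entering the DPR pipeline: time axis first, then
#' rows (y), then columns (x).
#'
#' @param frames a numeric matrix (one frame), a list of matrices, or a 3D
#'   array with the time axis first (`[t, y, x]`). Intensities must be
#'   finite and non-negative.
#' @param pixel_size optional physical length per raw pixel (e.g. in nm);
#'   purely metadata, carried into output manifests.
#' @return an object of class `image_stack`: a list with elements `frames`
#'   (list of H x W matrices) and `pixel_size`.
#' @examples
#' s <- image_stack(matrix(1:12, 3, 4))
#' n_frames(s)
#' @export
image_stack <- function(frames, pixel_size = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[1]), function(t) frames[t, , ])
  }
  if (!is.list(frames) || length(frames) < 1L) {
    stop("'frames' must be a matrix, a list of matrices, or a [t, y, x] array with T >= 1")
  }
  frames <- lapply(frames, function(f) {
    if (!is.matrix(f) || !is.numeric(f)) stop("every frame must be a numeric matrix")
    storage.mode(f) <- "double"
    f
  })
  d <- dim(frames[[1L]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) stop("all frames must share the same dimensions")
  finite <- vapply(frames, function(f) all(is.finite(f)), logical(1))
  if (!all(finite)) stop("frame contains non-finite values (NA/NaN/Inf)")
  neg <- vapply(frames, function(f) any(f < 0), logical(1))
  if (any(neg)) stop("frame contains negative intensities")
  if (!is.null(pixel_size)) stopifnot(is.numeric(pixel_size), pixel_size > 0)
  structure(list(frames = frames, pixel_size = pixel_size), class = "image_stack")
}

#' @rdname image_stack
#' @param x object to coerce or test.
#' @export
as_image_stack <- function(x, pixel_size = NULL) {
  if (inherits(x, "image_stack")) return(x)
  image_stack(x, pixel_size = pixel_size)
}

#' @rdname image_stack
#' @export
is_image_stack <- function(x) inherits(x, "image_stack")

#' @rdname image_stack
#' @export
n_frames <- function(x) length(as_image_stack(x)$frames)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  rng <- range(unlist(lapply(x$frames, range)))
  cat(sprintf("<image_stack> %d frame(s) of %d x %d, intensity range [%.4g, %.4g]%s\n",
              length(x$frames), d[1], d[2], rng[1], rng[2],
              if (is.null(x$pixel_size)) "" else sprintf(", pixel size %g", x$pixel_size)))
  invisible(x)
}

#' Subtract the per-frame global background
#'
#' Removes uniform background and camera offset by subtracting each frame's
#' own global minimum, so every output frame has minimum exactly 0. This is
#' the first preconditioning step of the DPR pipeline and is applied
#' independently to each raw frame.
#'
#' @param stack an [image_stack()] (or anything coercible to one).
#' @return an `image_stack` of the same shape.
#' @examples
#' s <- subtract_background(image_stack(matrix(c(5, 6, 7, 9), 2, 2)))
#' min(s$frames[[1]])  # exactly 0
#' @export
subtract_background <- function(stack) {
  stack <- as_image_stack(stack)
  stack$frames <- lapply(stack$frames, function(f) f - min(f))
  stack
}

#' Normalize a stack to its overall maximum
#'
#' Divides every frame by the single maximum over the whole stack, so the
#' global maximum becomes 1 while frame-to-frame intensity ratios are
#' preserved -- a requirement for the temporal variance reduction to remain
#' meaningful. Per-frame normalization (each frame to its own maximum) is
#' available for single-frame workflows and comparison experiments.
#'
#' @param stack an [image_stack()] (or anything coercible to one).
#' @param per_frame normalize each frame by its own maximum instead.
#' @return an `image_stack` with global (or per-frame) maximum 1.
#' @export
normalize_stack <- function(stack, per_frame = FALSE) {
  stack <- as_image_stack(stack)
  if (per_frame) {
    mx <- vapply(stack$frames, max, numeric(1))
    if (any(mx <= 0)) stop("blank input: a frame has maximum <= 0")
    stack$frames <- Map(function(f, m) f / m, stack$frames, mx)
  } else {
    mx <- max(vapply(stack$frames, max, numeric(1)))
    if (mx <= 0) stop("blank input: stack maximum is not positive")
    stack$frames <- lapply(stack$frames, function(f) f / mx)
  }
  stack
}
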