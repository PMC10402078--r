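# Internal spatial filters for the DPR engine.
#
# Every neighbourhood filter here uses replicate-edge boundary handling.
# Zero padding is reserved for the reassignment canvas (see pad_frame),
# where out-of-image deposits must land on zeros, not on mirrored signal.

# Band operator matrix applying a 1-D kernel along one dimension with
# replicated edges. Separable 2-D filtering is then two matrix products,
# which keeps the hot path fully vectorized.
.op_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (t in seq_along(kernel)) {
    j <- pmin(pmax(idx + (t - r - 1L), 1L), n)
    ij <- cbind(idx, j)
    K[ij] <- K[ij] + kernel[t]
  }
  K
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)
}

#' Gaussian lowpass filter with replicated edges
#'
#' Separable Gaussian blur (kernel truncated at 3 sigma), used by
#' [local_normalize()] and by the phantom renderer for PSF convolution.
#'
#' @param m numeric matrix.
#' @param sigma kernel standard deviation in pixels of `m`'s grid;
#'   `sigma <= 0` returns `m` unchanged.
#' @return filtered matrix of the same shape.
#' @export
gaussian_lowpass <- function(m, sigma) {
  stopifnot(is.matrix(m), is.numeric(sigma), length(sigma) == 1L)
  if (sigma <= 0) return(m)
  k <- .gauss_kernel(sigma)
  .op_matrix(nrow(m), k) %*% m %*% t(.op_matrix(ncol(m), k))
}

#' Raw 3x3 Sobel gradients
#'
#' Unnormalized Sobel responses (smoothing \eqn{[1,2,1]} crossed with
#' difference \eqn{[-1,0,1]}), so a unit slope along x produces a response
#' of 8. The x axis is the column index, y the row index; `gx > 0` where
#' intensity increases with x. Edges are replicated.
#'
#' @param m numeric matrix.
#' @return list with matrices `gx` and `gy`.
#' @export
sobel_gradients <- function(m) {
  stopifnot(is.matrix(m))
  s <- c(1, 2, 1)
  d <- c(-1, 0, 1)
  Sy <- .op_matrix(nrow(m), s)
  Dy <- .op_matrix(nrow(m), d)
  Sx <- .op_matrix(ncol(m), s)
  Dx <- .op_matrix(ncol(m), d)
  list(gx = Sy %*% m %*% t(Dx), gy = Dy %*% m %*% t(Sx))
}

#' Greyscale local-minimum filter over a disk
#'
#' Morphological erosion with a disk structuring element of the given
#' radius (pixels whose centre lies within `radius` of the target pixel),
#' with replicated edges. A radius at least as large as the largest frame
#' dimension degenerates to the global minimum.
#'
#' @param m numeric matrix.
#' @param radius disk radius in pixels of `m`'s grid; 0 returns `m`.
#' @return filtered matrix of the same shape.
#' @export
local_min_filter <- function(m, radius) {
  stopifnot(is.matrix(m), radius >= 0)
  radius <- as.integer(round(radius))
  if (radius == 0L) return(m)
  ny <- nrow(m)
  nx <- ncol(m)
  if (radius >= max(ny, nx)) {
    return(matrix(min(m), ny, nx))
  }
  out <- m
  iy0 <- seq_len(ny)
  ix0 <- seq_len(nx)
  for (dy in -radius:radius) {
    span <- floor(sqrt(radius^2 - dy^2))
    iy <- pmin(pmax(iy0 + dy, 1L), ny)
    for (dx in -span:span) {
      ix <- pmin(pmax(ix0 + dx, 1L), nx)
      out <- pmin(out, m[iy, ix])
    }
  }
  out
}

# Box (moving-average) filter of odd size k, replicated edges.
.box_filter <- function(m, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k %% 2L == 1L)
  if (k == 1L) return(m)
  kern <- rep(1 / k, k)
  .op_matrix(nrow(m), kern) %*% m %*% t(.op_matrix(ncol(m), kern))
}
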