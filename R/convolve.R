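# Small 2-D convolution helpers on plain matrices.
# Borders use replicate (edge-clamp) padding so that uniform regions stay
# uniform and no spurious responses appear at the image frame.

# Shift a matrix by (dy, dx) with replicate padding.
shift_matrix <- function(m, dy, dx) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Convolve along one axis with a centred odd-length kernel.
convolve_axis <- function(m, kernel, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  half <- (length(kernel) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(kernel)) {
    off <- k - half - 1L
    out <- out + kernel[k] *
      (if (axis == "rows") shift_matrix(m, off, 0L)
       else shift_matrix(m, 0L, off))
  }
  out
}

# Discrete Gaussian kernel truncated at +/- 4 sigma (renormalised).
gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(4 * sigma))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur of a matrix
#'
#' Separable Gaussian convolution with replicate padding at the borders,
#' kernel truncated at four standard deviations.
#'
#' @param m Numeric matrix.
#' @param sigma Standard deviation in pixels; `0` returns `m` unchanged.
#' @return Blurred matrix of the same dimension.
#' @export
gaussian_blur <- function(m, sigma) {
  stopifnot(is.matrix(m), is.finite(sigma), sigma >= 0)
  if (sigma == 0) return(m)
  k <- gaussian_kernel(sigma)
  convolve_axis(convolve_axis(m, k, "rows"), k, "cols")
}

# 3x3 Sobel gradient magnitude with replicate padding.
sobel_magnitude <- function(m) {
  # smoothing kernel (1, 2, 1) along one axis, derivative (-1, 0, 1) along
  # the other; separable implementation
  sm <- c(1, 2, 1)
  dv <- c(-1, 0, 1)
  gx <- convolve_axis(convolve_axis(m, dv, "cols"), sm, "rows")
  gy <- convolve_axis(convolve_axis(m, dv, "rows"), sm, "cols")
  sqrt(gx^2 + gy^2)
}
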