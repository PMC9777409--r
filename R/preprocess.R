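# Gaussian pre-filtering. The smoothing operator is the isotropic 2-D
# Gaussian density evaluated on the integer window grid and renormalised to
# sum to one, so constant images pass through unchanged.

#' Specify a Gaussian smoothing kernel
#'
#' @param sigma standard deviation of the Gaussian, in pixels. Larger sigma
#'   means stronger smoothing.
#' @param size odd window side length in pixels, at least 3.
#' @return object of class `gaussian_kernel_spec`.
#' @export
gaussian_kernel_spec <- function(sigma = 1.0, size = 5L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  size <- as.integer(size)
  if (is.na(size) || size < 3L || size %% 2L == 0L) {
    stop("size must be an odd integer >= 3", call. = FALSE)
  }
  structure(list(sigma = sigma, size = size), class = "gaussian_kernel_spec")
}

#' Build the 2-D Gaussian kernel matrix
#'
#' Entry (x, y), with x and y measured from the window centre, is
#' \deqn{G(x, y) = \frac{1}{2\pi\sigma^2} e^{-(x^2 + y^2)/(2\sigma^2)}}
#' optionally renormalised so the discrete window sums to exactly 1.
#'
#' @param spec a [gaussian_kernel_spec()].
#' @param normalize renormalise to unit sum (default `TRUE`). `FALSE` returns
#'   the raw density values, useful for inspecting the continuous operator.
#' @return `size x size` numeric matrix.
#' @export
gaussian_kernel_2d <- function(spec, normalize = TRUE) {
  if (!inherits(spec, "gaussian_kernel_spec")) spec <- do.call(gaussian_kernel_spec, spec)
  r <- (spec$size - 1L) / 2L
  g1 <- exp(-(seq(-r, r)^2) / (2 * spec$sigma^2))
  k <- outer(g1, g1) / (2 * pi * spec$sigma^2)
  if (normalize) k <- k / sum(k)
  k
}

# symmetric (edge-repeating) reflection indices for pad width r
reflect_index <- function(n, r) {
  if (r >= n) stop("kernel window larger than image", call. = FALSE)
  c(r:1, 1:n, n:(n - r + 1L))
}

#' Smooth an image with a Gaussian kernel
#'
#' Each channel is convolved with the normalised kernel from
#' [gaussian_kernel_2d()]. Boundaries use symmetric reflection padding, which
#' avoids the darkened borders that zero padding would feed into the texture
#' branch downstream.
#'
#' @param image `H x W x C` array (or matrix).
#' @param spec a [gaussian_kernel_spec()].
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth <- function(image, spec = gaussian_kernel_spec()) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  d <- dim(image)
  k <- gaussian_kernel_2d(spec)
  r <- (spec$size - 1L) / 2L
  iy <- reflect_index(d[1], r)
  ix <- reflect_index(d[2], r)
  out <- array(0, dim = d)
  for (ch in seq_len(d[3])) {
    pad <- image[iy, ix, ch]
    acc <- matrix(0, d[1], d[2])
    for (i in seq_len(spec$size)) {
      for (j in seq_len(spec$size)) {
        acc <- acc + k[i, j] * pad[i:(i + d[1] - 1L), j:(j + d[2] - 1L)]
      }
    }
    out[, , ch] <- acc
  }
  # convex combination of input pixels: clamp away round-off excursions
  pmin(pmax(out, min(image)), max(image))
}
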