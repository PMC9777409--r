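# Local binary patterns, radius 1, 8 neighbours on the 3 x 3 window.
# Bit i of a code compares neighbour i against the centre pixel:
# bit = 1 when neighbour >= centre (ties count as 1). Neighbours are indexed
# clockwise starting at the top-left corner; the ordering is frozen for
# reproducibility, any fixed ordering gives an equivalent descriptor.

.lbp_offsets <- list(
  c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
  c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L)
)

#' LBP code of a single 3 x 3 patch
#'
#' Returns \eqn{\sum_{i=0}^{7} 2^i \, g(I_i - I_c)} where \eqn{I_c} is the
#' centre pixel, \eqn{I_i} the i-th neighbour clockwise from the top-left,
#' and \eqn{g(v) = 1} for \eqn{v \ge 0}, else 0.
#'
#' @param patch 3 x 3 numeric matrix of scalar pixel values.
#' @return integer code in `[0, 255]`.
#' @export
lbp_code <- function(patch) {
  if (!is.matrix(patch) || !all(dim(patch) == c(3L, 3L))) {
    stop("patch must be a 3 x 3 matrix", call. = FALSE)
  }
  centre <- patch[2L, 2L]
  code <- 0L
  for (i in seq_along(.lbp_offsets)) {
    off <- .lbp_offsets[[i]]
    if (patch[2L + off[1], 2L + off[2]] >= centre) code <- code + 2L^(i - 1L)
  }
  as.integer(code)
}

#' LBP code image of a grayscale image
#'
#' Computes the code of every interior pixel; the one-pixel border is
#' excluded rather than padded (padding would invent texture).
#'
#' @param gray grayscale image: matrix or `H x W x 1` array, `H, W >= 3`.
#' @return `(H-2) x (W-2)` integer matrix of codes in `[0, 255]`.
#' @export
lbp_image <- function(gray) {
  if (is.array(gray) && length(dim(gray)) == 3L) {
    if (dim(gray)[3] != 1L) stop("lbp_image expects a single channel", call. = FALSE)
    gray <- gray[, , 1L]
  }
  if (!is.matrix(gray)) stop("lbp_image expects a matrix", call. = FALSE)
  h <- nrow(gray); w <- ncol(gray)
  if (h < 3L || w < 3L) stop("image must be at least 3 x 3 for LBP", call. = FALSE)
  centre <- gray[2:(h - 1L), 2:(w - 1L)]
  codes <- matrix(0L, h - 2L, w - 2L)
  for (i in seq_along(.lbp_offsets)) {
    off <- .lbp_offsets[[i]]
    nb <- gray[(2L + off[1]):(h - 1L + off[1]), (2L + off[2]):(w - 1L + off[2])]
    codes <- codes + as.integer(2L^(i - 1L)) * (nb >= centre)
  }
  storage.mode(codes) <- "integer"
  codes
}

#' Occurrence histogram of LBP codes
#'
#' The 256-bin histogram summarising one image's texture; normalised by
#' default so the branch is on a scale comparable with the deep features at
#' fusion time. This vector is the hand-crafted feature branch.
#'
#' @param codes integer matrix from [lbp_image()] (values in `[0, 255]`).
#' @param normalize divide counts by the total (default `TRUE`).
#' @return numeric vector of length 256 (bins for codes 0..255).
#' @export
lbp_histogram <- function(codes, normalize = TRUE) {
  if (length(codes) == 0L) stop("empty code image", call. = FALSE)
  if (min(codes) < 0L || max(codes) > 255L) {
    stop("codes must lie in [0, 255]", call. = FALSE)
  }
  bins <- tabulate(as.integer(codes) + 1L, nbins = 256L)
  bins <- as.numeric(bins)
  if (normalize) bins <- bins / sum(bins)
  bins
}
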