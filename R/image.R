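# Images are plain numeric arrays of shape H x W x C (C = 1 or 3) with
# intensities in [0, 1] (the convention of png::readPNG). Grayscale matrices
# are promoted to H x W x 1 so every stage sees the same shape.

#' Coerce pixels to an image tensor
#'
#' Promotes a matrix to an `H x W x 1` array and validates shape, channel
#' count and intensity range. Intensities may be declared on either the
#' `[0, 1]` or the `[0, 255]` scale; the declared range is only checked,
#' never rescaled.
#'
#' @param pixels numeric matrix (grayscale) or `H x W x C` array, `C` 1 or 3.
#' @param range length-2 numeric, the declared intensity range.
#' @return numeric `H x W x C` array.
#' @export
as_image_tensor <- function(pixels, range = c(0, 1)) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(dim(pixels), 1L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("image must be an H x W x C array (or a matrix)", call. = FALSE)
  }
  if (!dim(pixels)[3] %in% c(1L, 3L)) {
    stop("image must have 1 or 3 channels, got ", dim(pixels)[3], call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("image contains non-finite pixel values", call. = FALSE)
  }
  if (min(pixels) < range[1] - 1e-8 || max(pixels) > range[2] + 1e-8) {
    stop("pixel values fall outside the declared range [",
         range[1], ", ", range[2], "]", call. = FALSE)
  }
  pixels
}

#' Read a PNG or JPEG image
#'
#' Decodes via [png::readPNG()] / [jpeg::readJPEG()] depending on the file
#' extension. Alpha channels are dropped; grayscale images come back as
#' `H x W x 1`. Intensities are on the `[0, 1]` scale.
#'
#' @param path file path ending in .png, .jpg or .jpeg (case-insensitive).
#' @return numeric `H x W x C` array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pix <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image extension '", ext, "' for ", path, call. = FALSE)
  )
  if (is.matrix(pix)) pix <- array(pix, dim = c(dim(pix), 1L))
  if (dim(pix)[3] == 4L) pix <- pix[, , 1:3, drop = FALSE]
  if (dim(pix)[3] == 2L) pix <- pix[, , 1L, drop = FALSE]  # gray + alpha
  as_image_tensor(pix)
}

#' Write an image as 8-bit PNG
#'
#' Pixels are quantised to 8 bits before writing so that a written-then-read
#' round trip is bit-exact, which the seeded corpus generator relies on.
#'
#' @param image `H x W x C` array in `[0, 1]`.
#' @param path output path.
#' @export
write_image_png <- function(image, path) {
  image <- as_image_tensor(image)
  img8 <- round(image * 255) / 255
  if (dim(img8)[3] == 1L) img8 <- img8[, , 1L]
  png::writePNG(img8, target = path)
  invisible(path)
}

#' Discover a per-class image directory layout
#'
#' Expects `<root>/<class_name>/*.{png,jpg,jpeg}` and returns one row per
#' image. Class names are taken from the directory names (e.g. `benign`,
#' `malignant`).
#'
#' @param root dataset root directory.
#' @return data.frame with columns `path`, `class`.
#' @export
discover_images <- function(root) {
  if (!dir.exists(root)) stop("data root does not exist: ", root, call. = FALSE)
  classes <- sort(list.dirs(root, full.names = FALSE, recursive = FALSE))
  if (length(classes) < 2L) {
    stop("data root must contain at least two class directories, found ",
         length(classes), call. = FALSE)
  }
  rows <- lapply(classes, function(cl) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) return(NULL)
    data.frame(path = files, class = cl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("no images found under ", root, call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Convert an RGB image to grayscale
#'
#' Uses the ITU-R BT.601 luma weights `0.299 R + 0.587 G + 0.114 B`.
#' Already-grayscale images are returned unchanged.
#'
#' @param image `H x W x C` array.
#' @return `H x W x 1` array.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (dim(image)[3] == 1L) return(image)
  if (dim(image)[3] != 3L) {
    stop("to_grayscale expects 1 or 3 channels", call. = FALSE)
  }
  g <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
  array(g, dim = c(dim(image)[1:2], 1L))
}

#' Resize an image with bilinear interpolation
#'
#' Maps output pixel centres onto the input grid with the align-corners
#' convention, so resizing to the original size is the identity and constant
#' images stay constant.
#'
#' @param image `H x W x C` array.
#' @param side target side length in pixels (output is `side x side`);
#'   alternatively give `height`/`width` for non-square targets.
#' @param height,width optional explicit output dimensions (override `side`).
#' @return resized `height x width x C` array.
#' @export
resize_image <- function(image, side = NULL, height = side, width = side) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  d <- dim(image)
  if (d[1] < 2L || d[2] < 2L) {
    stop("degenerate input: images must be at least 2 x 2", call. = FALSE)
  }
  if (is.null(height) || is.null(width)) stop("target size missing", call. = FALSE)
  if (height < 1L || width < 1L) stop("target size must be positive", call. = FALSE)

  src <- function(n_out, n_in) {
    if (n_out == 1L) return(list(i0 = 1L, i1 = 1L, w = 0))
    pos <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
    i0 <- pmin(floor(pos), n_in - 2)
    list(i0 = as.integer(i0) + 1L, i1 = as.integer(i0) + 2L, w = pos - i0)
  }
  ry <- src(height, d[1]); rx <- src(width, d[2])

  out <- array(0, dim = c(height, width, d[3]))
  for (ch in seq_len(d[3])) {
    m <- image[, , ch]
    # rows first (weights recycle down columns), then columns
    v <- m[ry$i0, , drop = FALSE] * (1 - ry$w) + m[ry$i1, , drop = FALSE] * ry$w
    out[, , ch] <- v[, rx$i0, drop = FALSE] * rep(1 - rx$w, each = height) +
                   v[, rx$i1, drop = FALSE] * rep(rx$w, each = height)
  }
  out
}
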