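# Synthetic dermoscopy-style corpus generator. Two balanced classes of
# lesion-on-skin images distinguished by the clinical ABCD cues: mole
# diameter, colour uniformity, asymmetry and border irregularity. A lesion
# is a radial-harmonic-perturbed ellipse on a noisy skin-tone background:
#   r(theta) = R * (1 + sum_k a_k sin(k * theta + phi_k))
# Benign archetype: smaller diameter, near-zero harmonic amplitudes, a
# single uniform colour, mild elongation. Malignant archetype: larger
# diameter, strong harmonics (irregular border), >= 3 darker colour patches,
# stronger elongation. Every image is seeded individually so the corpus is
# bit-reproducible.

#' Describe one lesion
#'
#' @param center length-2 vector (row, col) of the lesion centre in pixels.
#' @param base_radius mean lesion radius in pixels.
#' @param boundary_harmonics numeric amplitudes `a_k` for harmonics
#'   k = 2, 3, ... (border irregularity; zero vector = smooth ellipse).
#' @param n_patches number of colour patches inside the lesion (colour
#'   uniformity cue; 1 = uniform).
#' @param patch_contrast colour offset magnitude of the patches.
#' @param asymmetry elongation factor >= 1 applied along a random axis.
#' @param color length-3 base RGB colour of the lesion in `[0, 1]`.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, base_radius, boundary_harmonics = numeric(0),
                        n_patches = 1L, patch_contrast = 0.1, asymmetry = 1.0,
                        color = c(0.45, 0.30, 0.22)) {
  if (base_radius <= 0) stop("base_radius must be positive", call. = FALSE)
  if (asymmetry < 1) stop("asymmetry (elongation) must be >= 1", call. = FALSE)
  structure(list(center = center, base_radius = base_radius,
                 boundary_harmonics = boundary_harmonics,
                 n_patches = as.integer(n_patches),
                 patch_contrast = patch_contrast,
                 asymmetry = asymmetry, color = color),
            class = "lesion_spec")
}

#' Synthetic-corpus configuration
#'
#' Defaults mirror a 1000-image balanced corpus of 600 x 450 images; the
#' `small` preset (64 x 64, 50 per class) keeps test and CI runs fast.
#'
#' @param n_per_class images per class (default 500).
#' @param height,width image dimensions in pixels (defaults 450 x 600).
#' @param seed corpus seed; fixed seed means a bit-identical corpus.
#' @param noise_sd standard deviation of the additive background noise.
#' @param small logical; switch to the 64 x 64, 50-per-class preset.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 500L, height = 450L, width = 600L,
                         seed = 0L, noise_sd = 0.02, small = FALSE) {
  if (isTRUE(small)) {
    n_per_class <- 50L; height <- 64L; width <- 64L
  }
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  structure(list(n_per_class = n_per_class, height = as.integer(height),
                 width = as.integer(width), seed = as.integer(seed),
                 noise_sd = noise_sd), class = "synth_config")
}

# class-conditional lesion parameter draws (uses the current RNG stream);
# radii are fractions of the shorter image side
draw_lesion_spec <- function(class, height, width) {
  m <- min(height, width)
  jitter <- stats::runif(2L, -0.06, 0.06) * m
  center <- c(height / 2, width / 2) + jitter
  if (class == "benign") {
    radius <- stats::runif(1L, 0.12, 0.20) * m / 2
    harmonics <- stats::runif(4L, 0, 0.02)
    n_patches <- 1L
    contrast <- 0.02
    asym <- stats::runif(1L, 1.0, 1.1)
    color <- c(0.55, 0.38, 0.30) + stats::runif(3L, -0.03, 0.03)
  } else {
    radius <- stats::runif(1L, 0.18, 0.30) * m / 2
    harmonics <- stats::runif(4L, 0.04, 0.15)
    n_patches <- sample(3:5, 1L)
    contrast <- stats::runif(1L, 0.10, 0.18)
    asym <- stats::runif(1L, 1.2, 1.6)
    color <- c(0.35, 0.22, 0.16) + stats::runif(3L, -0.03, 0.03)
  }
  lesion_spec(center, radius, harmonics, n_patches, contrast, asym, color)
}

#' Render one synthetic lesion image
#'
#' Draws from the current RNG stream (seed it before calling for
#' reproducibility).
#'
#' @param spec a [lesion_spec()].
#' @param height,width output dimensions in pixels.
#' @param noise_sd background noise standard deviation (0 = noiseless).
#' @return `height x width x 3` array in `[0, 1]`.
#' @export
generate_lesion_image <- function(spec, height, width, noise_sd = 0.02) {
  max_r <- spec$base_radius * spec$asymmetry *
    (1 + sum(abs(spec$boundary_harmonics)))
  if (max_r > min(height, width) / 2) {
    stop("lesion larger than the image", call. = FALSE)
  }
  skin <- c(0.85, 0.68, 0.60)
  img <- array(rep(skin, each = height * width), dim = c(height, width, 3L))
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), sd = noise_sd), dim = dim(img))
  }

  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  dy <- rows - spec$center[1]; dx <- cols - spec$center[2]
  phi <- stats::runif(1L, 0, 2 * pi)            # elongation axis
  u <- (cos(phi) * dx + sin(phi) * dy) / spec$asymmetry
  v <- -sin(phi) * dx + cos(phi) * dy
  d <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  rb <- rep(spec$base_radius, length(theta))
  if (length(spec$boundary_harmonics) > 0L) {
    phases <- stats::runif(length(spec$boundary_harmonics), 0, 2 * pi)
    for (k in seq_along(spec$boundary_harmonics)) {
      rb <- rb + spec$base_radius * spec$boundary_harmonics[k] *
        sin((k + 1L) * theta + phases[k])
    }
  }
  # soft edge over ~1.5 px keeps the border band textured, not aliased
  alpha <- pmin(pmax((rb - d) / 1.5 + 0.5, 0), 1)

  lesion <- array(rep(spec$color, each = height * width),
                  dim = c(height, width, 3L))
  if (spec$n_patches > 1L) {
    for (pp in seq_len(spec$n_patches - 1L)) {
      pc <- spec$center + stats::runif(2L, -0.5, 0.5) * spec$base_radius
      pr <- stats::runif(1L, 0.25, 0.5) * spec$base_radius
      off <- stats::runif(3L, -spec$patch_contrast, spec$patch_contrast)
      pd <- sqrt((rows - pc[1])^2 + (cols - pc[2])^2)
      pa <- pmin(pmax((pr - pd) / 1.5 + 0.5, 0), 1)
      for (ch in 1:3) {
        lesion[, , ch] <- lesion[, , ch] + pa * off[ch]
      }
    }
  }
  for (ch in 1:3) {
    img[, , ch] <- (1 - alpha) * img[, , ch] + alpha * lesion[, , ch]
  }
  pmin(pmax(img, 0), 1)
}

image_seed <- function(corpus_seed, index) {
  as.integer((as.numeric(corpus_seed) * 7919 + index * 104729) %% 2147483647)
}

#' Generate a labelled corpus on disk
#'
#' Writes `<root>/benign/*.png` and `<root>/malignant/*.png`
#' (`n_per_class` each) plus `manifest.csv` with columns
#' `filename, class, seed, diameter, n_patches`. Per-image seeds derive from
#' the corpus seed, so two runs with the same config produce bit-identical
#' files.
#'
#' @param config a [synth_config()].
#' @param root output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
generate_dataset <- function(config, root) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop("cannot create output root: ", root, call. = FALSE)
  classes <- c("benign", "malignant")
  rows <- vector("list", 2L * config$n_per_class)
  idx <- 0L
  for (cl in classes) {
    dir.create(file.path(root, cl), showWarnings = FALSE)
    for (i in seq_len(config$n_per_class)) {
      idx <- idx + 1L
      sd_i <- image_seed(config$seed, idx)
      set.seed(sd_i)
      spec <- draw_lesion_spec(cl, config$height, config$width)
      img <- generate_lesion_image(spec, config$height, config$width,
                                   config$noise_sd)
      fname <- sprintf("%s_%04d.png", cl, i)
      write_image_png(img, file.path(root, cl, fname))
      rows[[idx]] <- data.frame(
        filename = file.path(cl, fname), class = cl, seed = sd_i,
        diameter = 2 * spec$base_radius, n_patches = spec$n_patches,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Stratified train/validation split
#'
#' Each class contributes exactly `floor(n_class * train_fraction)` images to
#' the training set via a seeded shuffle; the split is disjoint and
#' exhaustive.
#'
#' @param manifest data.frame with at least a `class` column (e.g. from
#'   [generate_dataset()] or [discover_images()]).
#' @param train_fraction fraction per class for training, in (0, 1);
#'   default 0.75.
#' @param seed shuffle seed.
#' @return list of data.frames `train` and `validation`.
#' @export
split_dataset <- function(manifest, train_fraction = 0.75, seed = 0L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  }
  classes <- sort(unique(manifest$class))
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in classes) {
    idx <- which(manifest$class == cl)
    if (length(idx) < 2L) {
      stop("class '", cl, "' has fewer than 2 images", call. = FALSE)
    }
    n_train <- floor(length(idx) * train_fraction)
    if (n_train < 1L || n_train >= length(idx)) {
      stop("train_fraction leaves an empty split for class '", cl, "'",
           call. = FALSE)
    }
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  train_idx <- sort(train_idx)
  list(train = manifest[train_idx, , drop = FALSE],
       validation = manifest[-train_idx, , drop = FALSE])
}
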