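test_that("single-image rendering honours the spec and is seeded", {
  # benign archetype with no noise: one lesion colour plus background only
  spec <- lesion_spec(center = c(32, 32), base_radius = 8,
                      boundary_harmonics = numeric(0), n_patches = 1L,
                      asymmetry = 1.0, color = c(0.4, 0.3, 0.2))
  set.seed(1); img <- generate_lesion_image(spec, 64L, 64L, noise_sd = 0)
  expect_identical(dim(img), c(64L, 64L, 3L))
  # interior of the lesion is exactly the base colour
  expect_equal(as.vector(img[32, 32, ]), c(0.4, 0.3, 0.2), tolerance = 1e-12)
  # far corner is skin tone
  expect_equal(as.vector(img[2, 2, ]), c(0.85, 0.68, 0.60), tolerance = 1e-12)

  set.seed(99); a <- generate_lesion_image(spec, 64L, 64L)
  set.seed(99); b <- generate_lesion_image(spec, 64L, 64L)
  expect_identical(a, b)

  expect_error(generate_lesion_image(lesion_spec(c(10, 10), 40), 32L, 32L),
               "larger than the image")
})

test_that("corpus generation writes the declared layout and is bit-reproducible", {
  root1 <- tempfile(); root2 <- tempfile()
  cfg <- synth_config(n_per_class = 3L, height = 48L, width = 48L, seed = 5L)
  m1 <- generate_dataset(cfg, root1)
  m2 <- generate_dataset(cfg, root2)

  expect_equal(nrow(m1), 6L)
  expect_identical(sort(list.files(file.path(root1, "benign"))),
                   sprintf("benign_%04d.png", 1:3))
  expect_identical(m1, m2)
  h1 <- tools::md5sum(sort(list.files(root1, recursive = TRUE, full.names = TRUE)))
  h2 <- tools::md5sum(sort(list.files(root2, recursive = TRUE, full.names = TRUE)))
  expect_identical(unname(h1), unname(h2))

  # different seed changes the corpus
  m3 <- generate_dataset(synth_config(n_per_class = 3L, height = 48L,
                                      width = 48L, seed = 6L), tempfile())
  expect_false(identical(m1$seed, m3$seed))
})

test_that("stratified split has exact per-class counts, disjoint and exhaustive", {
  manifest <- data.frame(path = sprintf("img%03d", 1:40),
                         class = rep(c("benign", "malignant"), each = 20L))
  sp <- split_dataset(manifest, 0.75, seed = 1L)
  expect_equal(sum(sp$train$class == "benign"), 15L)
  expect_equal(sum(sp$train$class == "malignant"), 15L)
  expect_equal(nrow(sp$validation), 10L)
  expect_length(intersect(sp$train$path, sp$validation$path), 0L)
  expect_setequal(c(sp$train$path, sp$validation$path), manifest$path)

  sp2 <- split_dataset(manifest[1:8, ], 0.5, seed = 2L)
  expect_equal(nrow(sp2$train), 4L)

  expect_error(split_dataset(manifest, 1.2), "train_fraction")
  expect_error(split_dataset(data.frame(class = c("a", "a", "b")), 0.5),
               "fewer than 2")
})

test_that("the generated classes are separable in texture and in diameter", {
  root <- small_corpus()
  manifest <- utils::read.csv(file.path(root, "manifest.csv"))

  # a trivial threshold on lesion diameter alone beats 80% accuracy
  thr <- mean(tapply(manifest$diameter, manifest$class, mean))
  acc <- mean((manifest$diameter > thr) == (manifest$class == "malignant"))
  expect_gte(acc, 0.8)

  # mean between-class LBP histogram chi-square distance exceeds the
  # within-class distance
  hists <- lapply(manifest$filename, function(f) {
    g <- to_grayscale(read_image(file.path(root, f)))
    lbp_histogram(lbp_image(g))
  })
  H <- do.call(rbind, hists)
  mean_hist <- function(idx) colMeans(H[idx, , drop = FALSE])
  chisq <- function(a, b) {
    keep <- (a + b) > 0
    sum((a[keep] - b[keep])^2 / (a[keep] + b[keep]))
  }
  ben <- which(manifest$class == "benign")
  mal <- which(manifest$class == "malignant")
  between <- chisq(mean_hist(ben), mean_hist(mal))
  within <- mean(c(
    chisq(mean_hist(ben[1:25]), mean_hist(ben[26:50])),
    chisq(mean_hist(mal[1:25]), mean_hist(mal[26:50]))
  ))
  expect_gt(between, within)
})
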