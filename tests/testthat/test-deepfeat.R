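test_that("label smoothing produces the stated distribution", {
  hard <- smooth_labels(2L, 2L, 0)
  expect_equal(hard$distribution, c(0, 1))

  s <- smooth_labels(1L, 2L, 0.1)
  expect_equal(s$distribution, c(0.95, 0.05))

  for (eps in c(0, 0.1, 0.5, 0.9)) {
    for (K in c(2L, 3L, 7L)) {
      d <- smooth_labels(1L, K, eps)$distribution
      expect_equal(sum(d), 1, tolerance = 1e-9)
      expect_equal(d[1], (1 - eps) + eps / K, tolerance = 1e-12)
      if (K > 1L) expect_equal(d[-1], rep(eps / K, K - 1L), tolerance = 1e-12)
    }
  }
  expect_error(smooth_labels(1L, 2L, 1), "epsilon")
  expect_error(smooth_labels(1L, 2L, -0.1), "epsilon")
})

test_that("smoothed cross-entropy satisfies the two-term decomposition identity", {
  # concentrated prediction, no smoothing -> loss ~ 0
  expect_lt(smoothed_cross_entropy(c(30, 0), smooth_labels(1L, 2L, 0)), 1e-10)

  # uniform logits, K = 2 -> loss = log 2 for any epsilon
  for (eps in c(0, 0.2, 0.7)) {
    expect_equal(smoothed_cross_entropy(c(1, 1), smooth_labels(1L, 2L, eps)),
                 log(2), tolerance = 1e-12)
  }

  # smoothed CE = (1-eps) * CE(onehot) + eps * CE(uniform), within 1e-6
  set.seed(5)
  for (eps in c(0, 0.1, 0.5)) {
    for (rep in 1:10) {
      K <- 5L
      logits <- rnorm(K, sd = 2)
      z <- sample.int(K, 1L)
      lhs <- smoothed_cross_entropy(logits, smooth_labels(z, K, eps))
      onehot <- replace(rep(0, K), z, 1)
      rhs <- (1 - eps) * smoothed_cross_entropy(logits, onehot) +
        eps * smoothed_cross_entropy(logits, rep(1 / K, K))
      expect_equal(lhs, rhs, tolerance = 1e-6)
    }
  }
})

test_that("cross-entropy gradient is p - s, bounded in [-1, 1], and matches finite differences", {
  expect_equal(cross_entropy_gradient(c(0.3, 0.7), c(0.3, 0.7)), c(0, 0))
  expect_equal(cross_entropy_gradient(c(1, 0), c(0, 1)), c(1, -1))

  set.seed(6)
  for (rep in 1:20) {
    K <- sample(2:6, 1L)
    p <- runif(K); p <- p / sum(p)
    s <- runif(K); s <- s / sum(s)
    g <- cross_entropy_gradient(p, s)
    expect_true(all(g >= -1 & g <= 1))
  }

  # finite-difference check of the softmax + CE composite
  skip_if_not_installed("numDeriv")
  set.seed(8)
  K <- 4L
  logits <- rnorm(K)
  s <- runif(K); s <- s / sum(s)
  num <- numDeriv::grad(function(x) smoothed_cross_entropy(x, s), logits)
  p <- exp(logits - max(logits)); p <- p / sum(p)
  expect_equal(cross_entropy_gradient(p, s), num, tolerance = 1e-6)

  expect_error(cross_entropy_gradient(c(0.5, 0.9), c(0.5, 0.5)), "probability")
})

test_that("valid convolution output shape follows the stride-1 formula", {
  expect_identical(conv_output_shape(5, 5, 3, 3), c(3L, 3L))
  expect_identical(conv_output_shape(10, 7, 1, 1), c(10L, 7L))
  expect_identical(conv_output_shape(299, 299, 3, 3), c(297L, 297L))
  expect_error(conv_output_shape(4, 4, 5, 3), "larger")
})

test_that("backbone contract: declared dimensions, determinism, continuity", {
  spec <- backbone_spec("smallcnn", 64L, 48L)
  bb <- create_backbone(spec, seed = 3L)
  img <- random_image(64, 64, seed = 21L)

  f1 <- extract_features(img, bb)
  f2 <- extract_features(img, bb)
  expect_identical(f1, f2)                    # pure given fixed weights
  expect_length(f1, 48L)
  expect_true(all(is.finite(f1)))

  # continuity smoke test: vanishing input noise -> vanishing feature change
  dev <- sapply(c(0.1, 0.01, 0.001), function(s) {
    set.seed(30)
    noisy <- pmin(pmax(img + array(rnorm(length(img), sd = s), dim(img)), 0), 1)
    sqrt(sum((extract_features(noisy, bb) - f1)^2))
  })
  expect_true(all(diff(dev) < 0))

  expect_error(extract_features(random_image(32, 32, seed = 1L), bb), "input side")
  expect_error(backbone_spec("inceptionv3-like", 227L, 2048L), "299")
})

test_that("backbone head training reduces loss and fits separable synthetic images", {
  root <- small_corpus()
  manifest <- utils::read.csv(file.path(root, "manifest.csv"))
  imgs <- lapply(manifest$filename, function(f) {
    resize_image(read_image(file.path(root, f)), 64L)
  })
  bb <- create_backbone(backbone_spec("smallcnn", 64L, 64L), seed = 0L)

  # zero epochs leave the weights untouched
  bb0 <- train_backbone(imgs, manifest$class, bb, epochs = 0L, seed = 0L)
  expect_identical(bb0$W1, bb$W1)
  expect_identical(bb0$conv1, bb$conv1)

  trained <- train_backbone(imgs, manifest$class, bb, epochs = 5L, seed = 0L)
  lh <- attr(trained, "loss_history")
  expect_lte(lh[length(lh)], lh[1])
  acc <- mean(predict_backbone(imgs, trained) == manifest$class)
  expect_gte(acc, 0.9)

  expect_error(train_backbone(imgs[1:3], rep("benign", 3), bb), ">= 2 classes")
})

test_that("step-decay schedule never increases the learning rate", {
  lrs <- sapply(1:40, function(ep) lr_schedule(0.001, ep, 0.1, 10))
  expect_true(all(diff(lrs) <= 0))
  expect_equal(lr_schedule(0.001, 35, 0.1, 10), 0.001 * 0.1^3)
  expect_equal(lr_schedule(0.001, 7, 0.5, Inf), 0.001)   # constant default
})

test_that("Adam defaults follow the published settings", {
  a <- adam_config()
  expect_equal(a$learning_rate, 0.001)
  expect_equal(a$beta1, 0.98)
  expect_equal(a$beta2, 0.999)
  expect_equal(a$epsilon, 1e-7)
})
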