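test_that("sequence chunking pads and reshapes row-major", {
  s <- to_sequence(seq_len(1186), 7L)
  expect_identical(dim(s), c(170L, 7L))
  expect_equal(sum(s == 0), 4L)            # 170 * 7 - 1186 padding zeros
  expect_equal(s[1, ], 1:7)                # row-major fill
  expect_equal(s[170, 1:4], c(1184, 1185, 1186, 0))

  expect_identical(dim(to_sequence(1:14, 7L)), c(2L, 7L))
  expect_identical(dim(to_sequence(1:9, 9L)), c(1L, 9L))
  expect_error(to_sequence(1:5, 0L), "step_width")
  expect_error(to_sequence(numeric(0), 7L), "empty")
})

test_that("forward pass is a softmax, deterministic, and uniform for zero weights", {
  cfg <- lstm_config(step_width = 5L, hidden = 8L, fc_units = 4L, seed = 2L)
  params <- lesionfuse:::init_classifier_params(cfg)
  model <- structure(list(config = cfg, params = params,
                          running = list(mean = rep(0, 8), var = rep(1, 8)),
                          classes = c("benign", "malignant"), input_dim = 15L),
                     class = "lstm_classifier")
  seqm <- to_sequence(rnorm(15), 5L)

  p1 <- lstm_forward(seqm, model)
  p2 <- lstm_forward(seqm, model)
  expect_identical(p1, p2)
  expect_equal(sum(p1$probabilities), 1, tolerance = 1e-6)
  expect_identical(p1$label, which.max(p1$probabilities))

  zero <- model
  zero$params <- lesionfuse:::tree_map(function(p) p * 0, params)
  pz <- lstm_forward(seqm, zero)
  expect_equal(pz$probabilities, c(0.5, 0.5), tolerance = 1e-9)

  expect_error(lstm_forward(to_sequence(rnorm(12), 4L), model), "step_width")
})

test_that("analytic gradients match finite differences on a tiny network", {
  skip_if_not_installed("numDeriv")
  set.seed(42)
  cfg <- lstm_config(step_width = 2L, hidden = 3L, fc_units = 4L, seed = 1L)
  params <- lesionfuse:::init_classifier_params(cfg)
  running <- list(mean = rep(0, 3), var = rep(1, 3))
  n <- 4L
  feats <- matrix(rnorm(n * 6L), n, 6L)
  S <- t(sapply(sample(1:2, n, TRUE),
                function(z) smooth_labels(z, 2L, 0.1)$distribution))
  X <- lesionfuse:::features_to_batch(feats, cfg$step_width)

  fwd <- lesionfuse:::classifier_forward_batch(X, params, running, training = TRUE)
  g_an <- unlist(lesionfuse:::classifier_backward_batch(fwd, S, params))
  g_num <- numDeriv::grad(function(v) {
    p <- utils::relist(v, params)
    out <- lesionfuse:::classifier_forward_batch(X, p, running, training = TRUE)
    -sum(S * log(pmax(out$probs, 1e-300))) / n
  }, unlist(params))
  expect_equal(g_an, g_num, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("training separates Gaussian feature clusters and is class-symmetric", {
  sep <- separable_features(n = 200L, d = 70L, seed = 0L)
  cfg <- lstm_config(hidden = 32L, seed = 0L)
  model <- train_classifier(sep$X, sep$y, cfg, epochs = 30L)

  expect_length(model$loss_history, 30L)
  # smoothed loss trend decreases
  expect_lt(mean(tail(model$loss_history, 5)), mean(head(model$loss_history, 5)))

  pred <- predict_classifier(model, sep$X)
  expect_gte(mean(pred$labels == sep$y), 0.95)

  # flipping every label trains an equally good mirror classifier
  flipped <- ifelse(sep$y == "benign", "malignant", "benign")
  model_f <- train_classifier(sep$X, flipped, cfg, epochs = 30L)
  pred_f <- predict_classifier(model_f, sep$X)
  expect_gte(mean(pred_f$labels == flipped), 0.95)

  # zero epochs: freshly initialised weights, loss history empty
  m0 <- train_classifier(sep$X, sep$y, cfg, epochs = 0L)
  expect_identical(m0$params, lesionfuse:::init_classifier_params(cfg))
  expect_length(m0$loss_history, 0L)

  expect_error(train_classifier(sep$X, rep("benign", 200L), cfg), ">= 2 classes")
})

test_that("identical config, seed and data reproduce identical weights", {
  sep <- separable_features(n = 60L, d = 35L, seed = 3L)
  cfg <- lstm_config(hidden = 16L, seed = 5L)
  m1 <- train_classifier(sep$X, sep$y, cfg, epochs = 5L)
  m2 <- train_classifier(sep$X, sep$y, cfg, epochs = 5L)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$running, m2$running)
})
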