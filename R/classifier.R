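# LSTM benign/malignant classifier over the selected fused features.
#
# A flat feature vector is chunked row-major into timesteps of width
# `step_width` (default 7, zero-padded at the tail), then passed through:
#   LSTM-1 -> batch-norm -> ReLU -> residual addition -> LSTM-2
#   -> dense (ReLU) -> dense -> softmax
# The output head is 2-way for the binary task. Everything is implemented
# with batched matrix operations and hand-written backpropagation through
# time; training uses mini-batch Adam. Batch-norm uses batch statistics
# while training and exponential running statistics at inference, so
# prediction is deterministic.

#' LSTM classifier configuration
#'
#' @param step_width features per timestep (default 7).
#' @param hidden LSTM hidden size (default 128).
#' @param num_classes output classes (>= 2, default 2).
#' @param fc_units width of the penultimate dense layer.
#' @param seed integer seed for weight initialisation and batch order.
#' @return object of class `lstm_config`.
#' @export
lstm_config <- function(step_width = 7L, hidden = 128L, num_classes = 2L,
                        fc_units = 16L, seed = 0L) {
  step_width <- as.integer(step_width); hidden <- as.integer(hidden)
  num_classes <- as.integer(num_classes)
  if (step_width < 1L) stop("step_width must be >= 1", call. = FALSE)
  if (hidden < 1L) stop("hidden must be >= 1", call. = FALSE)
  if (num_classes < 2L) stop("num_classes must be >= 2", call. = FALSE)
  structure(list(step_width = step_width, hidden = hidden,
                 num_classes = num_classes, fc_units = as.integer(fc_units),
                 seed = as.integer(seed)), class = "lstm_config")
}

#' Reshape a flat feature vector into LSTM timesteps
#'
#' Zero-pads to a multiple of `step_width` and fills row-major, so timestep t
#' holds features `(t-1)*step_width + 1 .. t*step_width`.
#'
#' @param features non-empty numeric vector.
#' @param step_width features per timestep.
#' @return `T x step_width` matrix, `T = ceiling(length(features)/step_width)`.
#' @export
to_sequence <- function(features, step_width = 7L) {
  step_width <- as.integer(step_width)
  if (step_width < 1L) stop("step_width must be >= 1", call. = FALSE)
  if (length(features) == 0L) stop("empty feature vector", call. = FALSE)
  tt <- ceiling(length(features) / step_width)
  pad <- tt * step_width - length(features)
  matrix(c(as.numeric(features), rep(0, pad)), nrow = tt, byrow = TRUE)
}

# ---- parameter initialisation --------------------------------------------

# gate layout in the 4H-wide stacks: [input | forget | cell | output]
init_lstm_layer <- function(input_dim, hidden) {
  s <- 1 / sqrt(hidden)
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -s, s), nr, nc)
  b <- rep(0, 4L * hidden)
  b[(hidden + 1L):(2L * hidden)] <- 1     # forget-gate bias
  list(Wx = u(input_dim, 4L * hidden), Wh = u(hidden, 4L * hidden), b = b)
}

init_classifier_params <- function(config) {
  set.seed(config$seed)
  h <- config$hidden
  s <- function(fan_in) sqrt(2 / fan_in)
  list(
    l1 = init_lstm_layer(config$step_width, h),
    bn = list(gamma = rep(1, h), beta = rep(0, h)),
    l2 = init_lstm_layer(h, h),
    fc1 = list(W = matrix(stats::rnorm(h * config$fc_units, sd = s(h)), h, config$fc_units),
               b = rep(0, config$fc_units)),
    fc2 = list(W = matrix(stats::rnorm(config$fc_units * config$num_classes,
                                       sd = s(config$fc_units)),
                          config$fc_units, config$num_classes),
               b = rep(0, config$num_classes))
  )
}

# ---- batched LSTM layer ---------------------------------------------------

lstm_layer_forward <- function(X, p) {
  n <- nrow(X[[1L]]); tt <- length(X); h <- nrow(p$Wh)
  hs <- matrix(0, n, h); cs <- matrix(0, n, h)
  H <- vector("list", tt); cache <- vector("list", tt)
  for (t in seq_len(tt)) {
    z <- X[[t]] %*% p$Wx + hs %*% p$Wh
    z <- sweep(z, 2L, p$b, `+`)
    ig <- sigmoid(z[, 1:h, drop = FALSE])
    fg <- sigmoid(z[, (h + 1):(2 * h), drop = FALSE])
    gg <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
    og <- sigmoid(z[, (3 * h + 1):(4 * h), drop = FALSE])
    c_prev <- cs
    cs <- fg * c_prev + ig * gg
    tc <- tanh(cs)
    h_prev <- hs
    hs <- og * tc
    H[[t]] <- hs
    cache[[t]] <- list(x = X[[t]], h_prev = h_prev, c_prev = c_prev,
                       i = ig, f = fg, g = gg, o = og, tc = tc)
  }
  list(H = H, cache = cache)
}

lstm_layer_backward <- function(dH, fwd, p) {
  tt <- length(fwd$cache)
  n <- nrow(dH[[1L]]); h <- nrow(p$Wh)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dh_next <- matrix(0, n, h); dc_next <- matrix(0, n, h)
  dX <- vector("list", tt)
  for (t in rev(seq_len(tt))) {
    cc <- fwd$cache[[t]]
    dh <- dH[[t]] + dh_next
    do <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + t(cc$x) %*% dz
    dWh <- dWh + t(cc$h_prev) %*% dz
    db <- db + colSums(dz)
    dX[[t]] <- dz %*% t(p$Wx)
    dh_next <- dz %*% t(p$Wh)
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dX = dX)
}

# ---- batch normalisation --------------------------------------------------

.bn_eps <- 1e-5

bn_forward <- function(x, gamma, beta, running, training, momentum = 0.9) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2L, mu)^2)          # biased variance
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean; v <- running$var
  }
  inv <- 1 / sqrt(v + .bn_eps)
  xhat <- sweep(sweep(x, 2L, mu), 2L, inv, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = y, cache = list(xhat = xhat, inv = inv, gamma = gamma),
       running = running)
}

bn_backward <- function(dy, cache) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, cache$gamma, `*`)
  t1 <- sweep(dxhat, 2L, colSums(dxhat) / n)
  t2 <- sweep(cache$xhat, 2L, colSums(dxhat * cache$xhat) / n, `*`)
  dx <- sweep(t1 - t2, 2L, cache$inv, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- full network ---------------------------------------------------------

# X: list of T (n x step_width) matrices
classifier_forward_batch <- function(X, params, running, training = FALSE) {
  n <- nrow(X[[1L]]); tt <- length(X)
  f1 <- lstm_layer_forward(X, params$l1)
  H1s <- do.call(rbind, f1$H)                       # (n*T) x hidden
  bn <- bn_forward(H1s, params$bn$gamma, params$bn$beta, running, training)
  A <- relu(bn$y)
  Rs <- A + H1s                                     # residual addition
  R <- lapply(seq_len(tt), function(t) Rs[((t - 1L) * n + 1L):(t * n), , drop = FALSE])
  f2 <- lstm_layer_forward(R, params$l2)
  h2 <- f2$H[[tt]]
  fc1_pre <- sweep(h2 %*% params$fc1$W, 2L, params$fc1$b, `+`)
  fc1_out <- relu(fc1_pre)
  logits <- sweep(fc1_out %*% params$fc2$W, 2L, params$fc2$b, `+`)
  probs <- softmax_rows(logits)
  list(probs = probs, running = bn$running,
       cache = list(f1 = f1, bn = bn, bn_y = bn$y, A = A, H1s = H1s, R = R,
                    f2 = f2, h2 = h2, fc1_pre = fc1_pre, fc1_out = fc1_out,
                    n = n, tt = tt))
}

classifier_backward_batch <- function(fwd, S, params) {
  cc <- fwd$cache
  n <- cc$n; tt <- cc$tt
  dlog <- (fwd$probs - S) / n
  gfc2 <- list(W = t(cc$fc1_out) %*% dlog, b = colSums(dlog))
  dfc1 <- (dlog %*% t(params$fc2$W)) * (cc$fc1_pre > 0)
  gfc1 <- list(W = t(cc$h2) %*% dfc1, b = colSums(dfc1))
  dh2 <- dfc1 %*% t(params$fc1$W)
  dH2 <- lapply(seq_len(tt), function(t) matrix(0, n, ncol(dh2)))
  dH2[[tt]] <- dh2
  b2 <- lstm_layer_backward(dH2, cc$f2, params$l2)
  dRs <- do.call(rbind, b2$dX)
  dA <- dRs                                         # branch through ReLU(BN)
  dbn_y <- dA * (cc$bn_y > 0)
  bnb <- bn_backward(dbn_y, cc$bn$cache)
  dH1s <- dRs + bnb$dx                              # identity + BN paths
  dH1 <- lapply(seq_len(tt), function(t) dH1s[((t - 1L) * n + 1L):(t * n), , drop = FALSE])
  b1 <- lstm_layer_backward(dH1, cc$f1, params$l1)
  list(l1 = b1$grads,
       bn = list(gamma = bnb$dgamma, beta = bnb$dbeta),
       l2 = b2$grads,
       fc1 = gfc1, fc2 = gfc2)
}

# rows of `features` -> list of T (n x w) timestep matrices
features_to_batch <- function(features, step_width) {
  features <- as.matrix(features)
  d <- ncol(features)
  tt <- ceiling(d / step_width)
  pad <- tt * step_width - d
  if (pad > 0L) features <- cbind(features, matrix(0, nrow(features), pad))
  lapply(seq_len(tt), function(t) {
    features[, ((t - 1L) * step_width + 1L):(t * step_width), drop = FALSE]
  })
}

#' Forward pass of the LSTM classifier on one sequence
#'
#' Runs the network in inference mode (running batch-norm statistics), so
#' repeated calls with fixed weights are bit-identical.
#'
#' @param sequence `T x step_width` matrix from [to_sequence()].
#' @param model a trained [train_classifier()] model (or one assembled by
#'   hand with fields `config`, `params`, `running`).
#' @return list `probabilities` (sums to 1) and `label` (argmax index).
#' @export
lstm_forward <- function(sequence, model) {
  if (!is.matrix(sequence)) stop("sequence must be a matrix", call. = FALSE)
  if (ncol(sequence) != model$config$step_width) {
    stop("sequence width ", ncol(sequence), " does not match step_width ",
         model$config$step_width, call. = FALSE)
  }
  X <- lapply(seq_len(nrow(sequence)), function(t) sequence[t, , drop = FALSE])
  out <- classifier_forward_batch(X, model$params, model$running, training = FALSE)
  p <- as.vector(out$probs)
  list(probabilities = p, label = which.max(p))
}

#' Train the LSTM classifier
#'
#' Mini-batch Adam on (optionally label-smoothed) cross-entropy. All
#' randomness — weight init and batch order — derives from `config$seed`, so
#' identical data + config reproduce identical weights.
#'
#' @param features `n x d` matrix of selected fused features (one row per
#'   sample); rows are chunked into `step_width`-wide timesteps internally.
#' @param labels class labels, both classes present.
#' @param config an [lstm_config()].
#' @param adam an [adam_config()].
#' @param epochs training epochs; 0 returns the freshly initialised model.
#' @param batch_size mini-batch size.
#' @param label_smoothing epsilon for the loss (default 0).
#' @param lr_decay_factor,lr_step_size optional step-decay schedule.
#' @return object of class `lstm_classifier` with fields `config`, `params`,
#'   `running` (batch-norm statistics), `classes`, `loss_history`,
#'   `input_dim`.
#' @export
train_classifier <- function(features, labels, config = lstm_config(),
                             adam = adam_config(), epochs = 30L,
                             batch_size = 32L, label_smoothing = 0,
                             lr_decay_factor = 1, lr_step_size = Inf) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("training set must contain >= 2 classes", call. = FALSE)
  if (length(classes) > config$num_classes) {
    stop("more classes than config$num_classes", call. = FALSE)
  }
  y <- match(labels, classes)
  K <- config$num_classes
  S_all <- t(vapply(y, function(z) smooth_labels(z, K, label_smoothing)$distribution,
                    numeric(K)))

  params <- init_classifier_params(config)
  running <- list(mean = rep(0, config$hidden), var = rep(1, config$hidden))
  model <- structure(list(config = config, params = params, running = running,
                          classes = classes, loss_history = numeric(0),
                          input_dim = ncol(features)),
                     class = "lstm_classifier")
  if (epochs == 0L) return(model)

  X_all <- features_to_batch(features, config$step_width)
  n <- nrow(features)
  state <- adam_init(params)
  set.seed(config$seed + 1L)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lr <- lr_schedule(adam$learning_rate, ep, lr_decay_factor, lr_step_size)
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- lapply(X_all, function(m) m[idx, , drop = FALSE])
      Sb <- S_all[idx, , drop = FALSE]
      fwd <- classifier_forward_batch(Xb, params, running, training = TRUE)
      running <- fwd$running
      ep_loss <- ep_loss - sum(Sb * log(pmax(fwd$probs, 1e-12)))
      grads <- classifier_backward_batch(fwd, Sb, params)
      upd <- adam_step(params, grads, state, adam, lr)
      params <- upd$params; state <- upd$state
    }
    losses[ep] <- ep_loss / n
  }
  model$params <- params
  model$running <- running
  model$loss_history <- losses
  model
}

#' Predict with a trained LSTM classifier
#'
#' @param model an [train_classifier()] model.
#' @param features `n x d` matrix (d = `model$input_dim`) or single vector.
#' @return list `probabilities` (`n x num_classes` matrix), `labels`
#'   (character), `scores` (probability of the last class in sorted order,
#'   i.e. of `"malignant"` for benign/malignant data).
#' @export
predict_classifier <- function(model, features) {
  if (is.vector(features)) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != model$input_dim) {
    stop("feature width ", ncol(features), " does not match the model (",
         model$input_dim, ")", call. = FALSE)
  }
  X <- features_to_batch(features, model$config$step_width)
  out <- classifier_forward_batch(X, model$params, model$running, training = FALSE)
  P <- out$probs
  k <- length(model$classes)
  list(probabilities = P,
       labels = model$classes[max.col(P[, seq_len(k), drop = FALSE],
                                      ties.method = "first")],
       scores = P[, k])
}
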