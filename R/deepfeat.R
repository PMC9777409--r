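# Deep feature branch. The backbone is a contract — (input_side, feature_dim,
# forward map) — not a mandated architecture: the production configuration
# declares an Inception-V3-like extractor (299 px in, 2048 features out),
# while the default trainable instantiation is a small CNN that runs on one
# CPU in seconds. The convolutional base is frozen (a seeded random
# initialisation standing in for externally-trained weights); training
# adjusts the feature projection and the classification head, the usual
# frozen-base transfer-learning regime.

#' Label smoothing
#'
#' Replaces a one-hot target with
#' \eqn{s'(k) = (1-\varepsilon)\,\delta_{k,z} + \varepsilon / K}: mass
#' \eqn{(1-\varepsilon) + \varepsilon/K} on the true class, \eqn{\varepsilon/K}
#' elsewhere.
#'
#' @param true_class 1-based index of the true class.
#' @param K number of classes, >= 2.
#' @param epsilon smoothing mass in `[0, 1)`.
#' @return object of class `smoothed_labels` with fields `distribution`
#'   (length-K probability vector), `epsilon`, `num_classes`, `true_class`.
#' @export
smooth_labels <- function(true_class, K, epsilon = 0.1) {
  if (epsilon < 0 || epsilon >= 1) {
    stop("epsilon must lie in [0, 1)", call. = FALSE)
  }
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (true_class < 1L || true_class > K) {
    stop("true_class out of range", call. = FALSE)
  }
  d <- rep(epsilon / K, K)
  d[true_class] <- (1 - epsilon) + epsilon / K
  structure(list(distribution = d, epsilon = epsilon, num_classes = K,
                 true_class = as.integer(true_class)),
            class = "smoothed_labels")
}

#' Cross-entropy against a smoothed target
#'
#' \eqn{\ell = -\sum_k s'(k) \log p(k)} with `p = softmax(logits)`, computed
#' via log-sum-exp. By construction it equals
#' \eqn{(1-\varepsilon) H(\mathrm{onehot}, p) + \varepsilon H(\mathrm{uniform}, p)}.
#'
#' @param logits numeric vector of K finite unnormalised scores.
#' @param target a [smooth_labels()] object or a length-K probability vector.
#' @return non-negative scalar loss.
#' @export
smoothed_cross_entropy <- function(logits, target) {
  if (!all(is.finite(logits))) stop("logits must be finite", call. = FALSE)
  s <- if (inherits(target, "smoothed_labels")) target$distribution else target
  if (length(s) != length(logits)) stop("length mismatch", call. = FALSE)
  logp <- logits - max(logits) - log(sum(exp(logits - max(logits))))
  -sum(s * logp)
}

#' Gradient of softmax cross-entropy with respect to the logits
#'
#' For predicted distribution p and target distribution s the gradient is
#' simply `p - s`, every component of which lies in `[-1, 1]`.
#'
#' @param p,s length-K probability vectors (each sums to 1).
#' @return numeric vector `p - s`.
#' @export
cross_entropy_gradient <- function(p, s) {
  if (length(p) != length(s)) stop("length mismatch", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(s) - 1) > 1e-6 || any(p < -1e-12) || any(s < -1e-12)) {
    stop("p and s must be probability distributions", call. = FALSE)
  }
  p - s
}

#' Output shape of a valid convolution, stride 1
#'
#' @param h,w input height and width.
#' @param kh,kw kernel height and width (must not exceed the input).
#' @return integer vector `c(h - kh + 1, w - kw + 1)`.
#' @export
conv_output_shape <- function(h, w, kh, kw) {
  if (kh > h || kw > w) stop("kernel larger than input", call. = FALSE)
  c(as.integer(h - kh + 1L), as.integer(w - kw + 1L))
}

#' Declare a feature-extractor backbone
#'
#' @param name identifier; `"smallcnn"` is the trainable default,
#'   `"inceptionv3-like"` declares the production contract (299 px input,
#'   2048 features).
#' @param input_side square input side in pixels, >= 32.
#' @param feature_dim length of the extracted feature vector.
#' @param pretrained whether externally-trained weights are to be loaded
#'   (informational; no weight file ships with the package).
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = "smallcnn", input_side = 64L,
                          feature_dim = 64L, pretrained = FALSE) {
  input_side <- as.integer(input_side); feature_dim <- as.integer(feature_dim)
  if (input_side < 32L) stop("input_side must be >= 32", call. = FALSE)
  if (feature_dim < 1L) stop("feature_dim must be >= 1", call. = FALSE)
  if (name == "inceptionv3-like") {
    if (input_side != 299L) stop("inceptionv3-like declares input_side 299", call. = FALSE)
    if (feature_dim != 2048L) stop("inceptionv3-like declares feature_dim 2048", call. = FALSE)
  }
  structure(list(name = name, input_side = input_side,
                 feature_dim = feature_dim, pretrained = isTRUE(pretrained)),
            class = "backbone_spec")
}

# two conv/pool blocks; global average pooling keeps the base independent of
# input_side so one code path serves every spec
.bb_filters <- c(8L, 16L)

#' Instantiate a backbone
#'
#' Builds the frozen convolutional base (two 3x3 valid-convolution + ReLU +
#' 2x2 max-pool blocks, He-initialised from `seed`) and the trainable feature
#' projection.
#'
#' @param spec a [backbone_spec()].
#' @param seed integer seed for the weight initialisation.
#' @return object of class `cnn_backbone`.
#' @export
create_backbone <- function(spec = backbone_spec(), seed = 0L) {
  stopifnot(inherits(spec, "backbone_spec"))
  set.seed(seed)
  he <- function(fan_in, nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  f1 <- .bb_filters[1]; f2 <- .bb_filters[2]
  structure(list(
    spec  = spec,
    conv1 = he(9L * 3L, 9L * 3L, f1),        # (3*3*3) x f1
    conv2 = he(9L * f1, 9L * f1, f2),        # (3*3*f1) x f2
    W1    = he(f2, f2, spec$feature_dim),    # gap -> feature projection
    b1    = rep(0, spec$feature_dim),
    gap_stats = NULL,                        # set by train_backbone
    head  = NULL,                            # set by train_backbone
    seed  = as.integer(seed)
  ), class = "cnn_backbone")
}

im2col <- function(img, k) {
  d <- dim(img)
  oh <- d[1] - k + 1L; ow <- d[2] - k + 1L
  cols <- matrix(0, oh * ow, k * k * d[3])
  col <- 1L
  for (ch in seq_len(d[3])) {
    for (j in seq_len(k)) {
      for (i in seq_len(k)) {
        cols[, col] <- as.vector(img[i:(i + oh - 1L), j:(j + ow - 1L), ch])
        col <- col + 1L
      }
    }
  }
  list(cols = cols, oh = oh, ow = ow)
}

maxpool2 <- function(x) {
  d <- dim(x)
  h <- d[1] %/% 2L * 2L; w <- d[2] %/% 2L * 2L
  x <- x[seq_len(h), seq_len(w), , drop = FALSE]
  a <- pmax(x[seq(1L, h, 2L), , , drop = FALSE], x[seq(2L, h, 2L), , , drop = FALSE])
  pmax(a[, seq(1L, w, 2L), , drop = FALSE], a[, seq(2L, w, 2L), , drop = FALSE])
}

# frozen conv base -> global-average-pooled activation vector
backbone_gap <- function(image, backbone) {
  d <- dim(image)
  if (d[1] != backbone$spec$input_side || d[2] != backbone$spec$input_side) {
    stop("image must be resized to the backbone input side (",
         backbone$spec$input_side, ")", call. = FALSE)
  }
  if (d[3] == 1L) image <- array(rep(image, 3L), dim = c(d[1:2], 3L))
  c1 <- im2col(image, 3L)
  a1 <- relu(c1$cols %*% backbone$conv1)
  a1 <- maxpool2(array(a1, dim = c(c1$oh, c1$ow, ncol(a1))))
  c2 <- im2col(a1, 3L)
  a2 <- relu(c2$cols %*% backbone$conv2)
  a2 <- maxpool2(array(a2, dim = c(c2$oh, c2$ow, ncol(a2))))
  apply(a2, 3L, mean)
}

#' Extract deep features from one image
#'
#' Runs the frozen base and the (possibly trained) feature projection:
#' `relu(W1' gap + b1)`. Deterministic given fixed weights.
#'
#' @param image `side x side x C` array, `side = backbone$spec$input_side`.
#' @param backbone a [create_backbone()] object.
#' @return numeric vector of length `feature_dim`.
#' @export
extract_features <- function(image, backbone) {
  g <- backbone_gap(image, backbone)
  if (!is.null(backbone$gap_stats)) {
    g <- (g - backbone$gap_stats$mean) / backbone$gap_stats$sd
  }
  as.vector(relu(drop(g %*% backbone$W1) + backbone$b1))
}

#' Train the backbone head
#'
#' Freezes the convolutional base, caches its pooled activations once, and
#' fits the feature projection plus a softmax classification head with
#' mini-batch Adam on the label-smoothing cross-entropy. All randomness
#' (head init, batch order) derives from `seed`.
#'
#' @param images list of `side x side x C` arrays already resized to the
#'   backbone input side.
#' @param labels character/factor vector of class names, one per image; at
#'   least two distinct classes required.
#' @param backbone a [create_backbone()] object.
#' @param adam an [adam_config()].
#' @param label_smoothing smoothing mass epsilon (default 0.1).
#' @param epochs training epochs; 0 returns the backbone unchanged.
#' @param batch_size mini-batch size.
#' @param seed integer seed.
#' @param lr_decay_factor,lr_step_size optional step-decay schedule
#'   (defaults: constant rate).
#' @return the trained backbone, with an attribute `loss_history` (mean
#'   training loss per epoch).
#' @export
train_backbone <- function(images, labels, backbone, adam = adam_config(),
                           label_smoothing = 0.1, epochs = 5L, batch_size = 32L,
                           seed = 0L, lr_decay_factor = 1, lr_step_size = Inf) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("training set must contain >= 2 classes", call. = FALSE)
  if (length(images) != length(labels)) stop("images/labels length mismatch", call. = FALSE)
  y <- match(labels, classes)
  K <- length(classes)
  if (epochs == 0L) {
    attr(backbone, "classes") <- classes
    attr(backbone, "loss_history") <- numeric(0)
    return(backbone)
  }

  G <- t(vapply(images, backbone_gap, numeric(.bb_filters[2]), backbone = backbone))
  # standardise the pooled activations (training-set statistics, persisted):
  # their large common positive mean otherwise drowns the class signal in
  # mini-batch gradient noise
  gs <- list(mean = colMeans(G), sd = apply(G, 2L, stats::sd))
  gs$sd[!is.finite(gs$sd) | gs$sd == 0] <- 1
  G <- sweep(sweep(G, 2L, gs$mean), 2L, gs$sd, `/`)
  backbone$gap_stats <- gs
  S <- t(vapply(y, function(z) smooth_labels(z, K, label_smoothing)$distribution,
                numeric(K)))

  set.seed(seed)
  fd <- backbone$spec$feature_dim
  # zero-initialised softmax head: with few Adam steps the decision is set
  # by the learned direction, not by a random initial rotation
  params <- list(
    W1 = backbone$W1, b1 = backbone$b1,
    W2 = matrix(0, fd, K),
    b2 = rep(0, K)
  )
  state <- adam_init(params)
  n <- nrow(G)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lr <- lr_schedule(adam$learning_rate, ep, lr_decay_factor, lr_step_size)
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Gb <- G[idx, , drop = FALSE]; Sb <- S[idx, , drop = FALSE]
      Hpre <- sweep(Gb %*% params$W1, 2L, params$b1, `+`)
      H <- relu(Hpre)
      logits <- sweep(H %*% params$W2, 2L, params$b2, `+`)
      P <- softmax_rows(logits)
      logP <- log(pmax(P, 1e-12))
      ep_loss <- ep_loss - sum(Sb * logP)
      dlog <- (P - Sb) / length(idx)
      dH <- dlog %*% t(params$W2)
      dpre <- dH * (Hpre > 0)
      grads <- list(W1 = t(Gb) %*% dpre, b1 = colSums(dpre),
                    W2 = t(H) %*% dlog, b2 = colSums(dlog))
      upd <- adam_step(params, grads, state, adam, lr)
      params <- upd$params; state <- upd$state
    }
    losses[ep] <- ep_loss / n
  }
  backbone$W1 <- params$W1; backbone$b1 <- params$b1
  backbone$head <- list(W2 = params$W2, b2 = params$b2)
  attr(backbone, "classes") <- classes
  attr(backbone, "loss_history") <- losses
  backbone
}

#' Classify images with the backbone's own head
#'
#' Mainly a training diagnostic; the pipeline's decision comes from the LSTM
#' classifier downstream.
#'
#' @param images list of resized image arrays.
#' @param backbone a trained backbone (head present).
#' @return character vector of predicted class names.
#' @export
predict_backbone <- function(images, backbone) {
  if (is.null(backbone$head)) stop("backbone has no trained head", call. = FALSE)
  classes <- attr(backbone, "classes")
  feats <- t(vapply(images, extract_features, numeric(backbone$spec$feature_dim),
                    backbone = backbone))
  logits <- sweep(feats %*% backbone$head$W2, 2L, backbone$head$b2, `+`)
  classes[max.col(logits, ties.method = "first")]
}
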