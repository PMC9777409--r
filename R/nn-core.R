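# Shared numerical-optimisation plumbing for the two trainable networks
# (the CNN head and the LSTM classifier): Adam with the published defaults,
# a step-decay learning-rate schedule, and helpers that map a nested list of
# weight matrices to and from a flat structure.

#' Adam optimizer configuration
#'
#' Defaults follow the published settings: learning rate 0.001, first-moment
#' decay 0.98, second-moment decay 0.999, epsilon 1e-7. (0.98 is unusual for
#' the first moment — 0.9 is conventional — but it is the stated value and is
#' kept as the default.)
#'
#' @param learning_rate step size, > 0.
#' @param beta1,beta2 exponential decay rates for the moment estimates, in (0, 1).
#' @param epsilon numerical stabiliser added to the denominator.
#' @return object of class `adam_config`.
#' @export
adam_config <- function(learning_rate = 0.001, beta1 = 0.98, beta2 = 0.999,
                        epsilon = 1e-7) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1) {
    stop("beta1 and beta2 must lie in (0, 1)", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon), class = "adam_config")
}

#' Step-decay learning-rate schedule
#'
#' Multiplies the base rate by `factor` every `step_size` epochs; with
#' `factor <= 1` the schedule never increases the rate. `step_size = Inf`
#' (the default) gives a constant rate.
#'
#' @param base_lr base learning rate.
#' @param epoch 1-based epoch index.
#' @param factor decay multiplier in (0, 1].
#' @param step_size epochs between decays.
#' @return the learning rate for `epoch`.
#' @export
lr_schedule <- function(base_lr, epoch, factor = 0.1, step_size = Inf) {
  if (factor <= 0 || factor > 1) stop("decay factor must be in (0, 1]", call. = FALSE)
  if (is.infinite(step_size)) return(base_lr)
  base_lr * factor^floor((epoch - 1) / step_size)
}

# ---- parameter trees ------------------------------------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(t1)
    out
  } else {
    do.call(f, trees)
  }
}

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg, lr = cfg$learning_rate) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) cfg$beta1 * m + (1 - cfg$beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) cfg$beta2 * v + (1 - cfg$beta2) * g^2, state$v, grads)
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + cfg$epsilon)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# ---- activations ----------------------------------------------------------

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)
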