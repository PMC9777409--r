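# Shared fixtures, all generated in code at test time.

random_image <- function(h, w, c = 3L, seed = 1L) {
  set.seed(seed)
  array(runif(h * w * c), dim = c(h, w, c))
}

checkerboard <- function(h, w) {
  outer(seq_len(h), seq_len(w), function(i, j) (i + j) %% 2)
}

# naive per-pixel LBP oracle: double loop over interior pixels, explicit
# clockwise-from-top-left neighbour walk
lbp_oracle <- function(gray) {
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  h <- nrow(gray); w <- ncol(gray)
  out <- matrix(0L, h - 2L, w - 2L)
  for (r in 2:(h - 1)) {
    for (cc in 2:(w - 1)) {
      code <- 0L
      for (i in seq_along(offs)) {
        if (gray[r + offs[[i]][1], cc + offs[[i]][2]] >= gray[r, cc]) {
          code <- code + as.integer(2^(i - 1))
        }
      }
      out[r - 1L, cc - 1L] <- code
    }
  }
  out
}

# a small shared synthetic corpus, generated once per test run
small_corpus <- local({
  root <- NULL
  function() {
    if (is.null(root)) {
      root <<- file.path(tempdir(), "lesionfuse-test-corpus")
      if (!dir.exists(root)) {
        generate_dataset(synth_config(small = TRUE, seed = 7L), root)
      }
    }
    root
  }
})

# well-separated two-class Gaussian feature clusters
separable_features <- function(n = 200L, d = 70L, seed = 0L, gap = 1.5) {
  set.seed(seed)
  y <- rep(c("benign", "malignant"), each = n / 2L)
  informative <- runif(d) > 0.5
  mu <- ifelse(y == "malignant", gap, -gap)
  X <- matrix(rnorm(n * d), n, d) +
    matrix(mu, n, d) * matrix(informative, n, d, byrow = TRUE)
  list(X = X, y = y)
}
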