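# Feature fusion and entropy-based selection — the pipeline's bespoke stage.
#
# Fusion is concatenation: the deep vector (1 x m) followed by the LBP
# histogram (1 x p) gives a fused vector of length s = m + p, with per-
# position provenance retained so the operation is invertible.
#
# Selection scores each fused position with the Shannon entropy term of its
# normalised absolute magnitude, p_i = |f_i| / sum_j |f_j| and
# score_i = -p_i log2 p_i, and keeps the keep_n highest-scoring positions
# (default 1186), ties broken towards the lower index. At training time the
# scores are averaged over the training samples only and the resulting index
# set is frozen for inference, so the classifier always sees the same
# positions.

#' Construct a named feature branch
#'
#' @param name branch identifier, `"deep"` or `"lbp"`.
#' @param values numeric feature vector (finite, non-empty).
#' @return object of class `feature_branch`.
#' @export
feature_branch <- function(name, values) {
  name <- match.arg(name, c("deep", "lbp"))
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty feature branch", call. = FALSE)
  if (!all(is.finite(values))) stop("feature branch must be finite", call. = FALSE)
  structure(list(name = name, values = values), class = "feature_branch")
}

#' Fuse the two feature branches by concatenation
#'
#' @param deep,lbp [feature_branch()] objects (or bare numeric vectors).
#' @return object of class `fused_vector` with fields `values` (length
#'   `m + p`) and `provenance` (data.frame `branch`, `index` mapping every
#'   fused position back to its source).
#' @export
fuse <- function(deep, lbp) {
  if (!inherits(deep, "feature_branch")) deep <- feature_branch("deep", deep)
  if (!inherits(lbp, "feature_branch"))  lbp  <- feature_branch("lbp", lbp)
  values <- c(deep$values, lbp$values)
  provenance <- data.frame(
    branch = c(rep("deep", length(deep$values)), rep("lbp", length(lbp$values))),
    index  = c(seq_along(deep$values), seq_along(lbp$values)),
    stringsAsFactors = FALSE
  )
  structure(list(values = values, provenance = provenance), class = "fused_vector")
}

#' Split a fused vector back into its branches
#'
#' Round-trip companion of [fuse()], used to verify that fusion loses
#' nothing.
#'
#' @param fused a `fused_vector`.
#' @return list with numeric elements `deep` and `lbp`.
#' @export
unfuse <- function(fused) {
  stopifnot(inherits(fused, "fused_vector"))
  list(deep = fused$values[fused$provenance$branch == "deep"],
       lbp  = fused$values[fused$provenance$branch == "lbp"])
}

#' Per-feature entropy scores
#'
#' Normalised absolute magnitudes are read as a probability over positions,
#' \eqn{p_i = |f_i| / \sum_j |f_j|}; the score of position i is its Shannon
#' entropy term \eqn{-p_i \log_2 p_i} (0 when \eqn{p_i = 0}), so the scores
#' sum to the Shannon entropy of p. Scores are invariant to positive
#' rescaling of the whole vector.
#'
#' @param fused a `fused_vector` or bare numeric vector with at least one
#'   non-zero entry.
#' @return numeric vector of non-negative scores, one per position.
#' @export
entropy_scores <- function(fused) {
  f <- if (inherits(fused, "fused_vector")) fused$values else as.numeric(fused)
  a <- abs(f)
  tot <- sum(a)
  if (tot == 0) stop("degenerate input: all-zero feature vector", call. = FALSE)
  p <- a / tot
  ifelse(p > 0, -p * log2(p), 0)
}

#' Select the top-entropy features of one fused vector
#'
#' Keeps the `keep_n` highest-scoring positions (all of them when the vector
#' is shorter than `keep_n`); ties broken towards the lower original index.
#' The reduced vector lists kept values in ascending original-index order.
#'
#' @param fused a `fused_vector` or numeric vector.
#' @param keep_n number of features to retain (default 1186).
#' @param scores optional externally-computed score vector (e.g. training-set
#'   averages); defaults to [entropy_scores()] of `fused` itself.
#' @return list with `values` (the reduced vector), `kept_indices` (sorted),
#'   `scores`, `keep_n`.
#' @export
select_features <- function(fused, keep_n = 1186L, scores = NULL) {
  f <- if (inherits(fused, "fused_vector")) fused$values else as.numeric(fused)
  keep_n <- as.integer(keep_n)
  if (is.na(keep_n) || keep_n < 1L) stop("keep_n must be >= 1", call. = FALSE)
  if (is.null(scores)) scores <- entropy_scores(f)
  if (length(scores) != length(f)) stop("scores length mismatch", call. = FALSE)
  k <- min(keep_n, length(f))
  kept <- sort(order(-scores, seq_along(scores))[seq_len(k)])
  list(values = f[kept], kept_indices = kept, scores = scores, keep_n = keep_n)
}

# column means/sds for branch standardisation; zero-variance columns get
# sd 1 so constant features pass through centred instead of dividing by zero
.branch_stats <- function(M) {
  mu <- colMeans(M)
  sd <- apply(M, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

.standardize <- function(M, st) sweep(sweep(M, 2L, st$mean), 2L, st$sd, `/`)

#' Fit the fusion + selection stage on training features
#'
#' Each branch is z-scored with training-set statistics (so neither branch's
#' scale dominates the entropy ranking), the branches are concatenated per
#' sample, entropy scores are averaged over the training samples, and the
#' top `keep_n` positions are frozen. The returned artifact reproduces the
#' training-time transformation exactly at inference.
#'
#' @param deep_mat `n x m` matrix of deep features (training samples only).
#' @param lbp_mat `n x p` matrix of LBP histograms (same rows).
#' @param keep_n number of fused features to retain (default 1186).
#' @return object of class `fusion_selection` with branch statistics, mean
#'   scores and the kept index set.
#' @export
fit_selection <- function(deep_mat, lbp_mat, keep_n = 1186L) {
  deep_mat <- as.matrix(deep_mat); lbp_mat <- as.matrix(lbp_mat)
  if (nrow(deep_mat) != nrow(lbp_mat)) stop("branch row mismatch", call. = FALSE)
  if (nrow(deep_mat) < 2L) stop("need >= 2 training samples", call. = FALSE)
  ds <- .branch_stats(deep_mat); ls <- .branch_stats(lbp_mat)
  Z <- cbind(.standardize(deep_mat, ds), .standardize(lbp_mat, ls))
  score_mat <- t(apply(Z, 1L, function(row) {
    if (all(row == 0)) rep(0, length(row)) else entropy_scores(row)
  }))
  mean_scores <- colMeans(score_mat)
  sel <- select_features(rep(0, ncol(Z)), keep_n = keep_n, scores = mean_scores)
  structure(list(
    keep_n = as.integer(keep_n),
    m = ncol(deep_mat), p = ncol(lbp_mat),
    kept_indices = sel$kept_indices,
    scores = mean_scores,
    deep_stats = ds, lbp_stats = ls
  ), class = "fusion_selection")
}

#' Apply a fitted selection to feature branches
#'
#' @param selection a [fit_selection()] artifact.
#' @param deep_mat,lbp_mat matrices (or single vectors) of raw branch
#'   features.
#' @return `n x keep_n` matrix of standardized, fused, selected features.
#' @export
apply_selection <- function(selection, deep_mat, lbp_mat) {
  stopifnot(inherits(selection, "fusion_selection"))
  if (is.vector(deep_mat)) deep_mat <- matrix(deep_mat, nrow = 1L)
  if (is.vector(lbp_mat))  lbp_mat  <- matrix(lbp_mat, nrow = 1L)
  if (ncol(deep_mat) != selection$m || ncol(lbp_mat) != selection$p) {
    stop("branch widths do not match the fitted selection", call. = FALSE)
  }
  Z <- cbind(.standardize(as.matrix(deep_mat), selection$deep_stats),
             .standardize(as.matrix(lbp_mat), selection$lbp_stats))
  Z[, selection$kept_indices, drop = FALSE]
}

#' Serialize / restore a selection artifact as JSON
#'
#' @param selection a `fusion_selection`.
#' @param path JSON file path.
#' @return `read_selection_json` returns the restored `fusion_selection`.
#' @export
write_selection_json <- function(selection, path) {
  stopifnot(inherits(selection, "fusion_selection"))
  jsonlite::write_json(unclass(selection), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_selection_json
#' @export
read_selection_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$keep_n <- as.integer(x$keep_n)
  x$kept_indices <- as.integer(x$kept_indices)
  structure(x, class = "fusion_selection")
}
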