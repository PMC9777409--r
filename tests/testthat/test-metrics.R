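test_that("confusion counts follow the contingency definitions", {
  truth <- c(rep("malignant", 6), rep("benign", 4))
  perfect <- confusion(truth, truth)
  expect_equal(unclass(perfect)[c("TP", "TN", "FP", "FN")],
               list(TP = 6L, TN = 4L, FP = 0L, FN = 0L))

  all_pos <- confusion(truth, rep("malignant", 10))
  expect_equal(all_pos$FN, 0L)
  expect_equal(all_pos$TN, 0L)

  set.seed(50)
  t50 <- sample(c("benign", "malignant"), 50, TRUE)
  p50 <- sample(c("benign", "malignant"), 50, TRUE)
  cc <- confusion(t50, p50)
  # brute-force pairwise tally
  tally <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (i in 1:50) {
    key <- if (t50[i] == "malignant" && p50[i] == "malignant") "TP"
      else if (t50[i] != "malignant" && p50[i] == "malignant") "FP"
      else if (t50[i] != "malignant" && p50[i] != "malignant") "TN"
      else "FN"
    tally[key] <- tally[key] + 1L
  }
  expect_equal(unlist(unclass(cc)), tally)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 50L)

  expect_error(confusion(t50, p50[-1]), "equal length")
})

test_that("scalar metrics reproduce the cross-validation worked example", {
  # 500 + 500 held-out images: 493 and 491 correct per class
  m <- compute_metrics(list(TP = 493L, FP = 9L, TN = 491L, FN = 7L))
  expect_equal(m$accuracy, 0.984, tolerance = 1e-12)
  expect_equal(m$precision, 493 / 502, tolerance = 1e-12)
  expect_equal(m$recall, 493 / 500, tolerance = 1e-12)

  sym <- compute_metrics(list(TP = 25L, FP = 25L, TN = 25L, FN = 25L))
  expect_equal(sym$precision, 0.5)
  expect_equal(sym$recall, 0.5)
  expect_equal(sym$accuracy, 0.5)
  expect_equal(sym$f1, 0.5)
})

test_that("F1 is the harmonic mean and lies between precision and recall", {
  set.seed(60)
  for (rep in 1:25) {
    counts <- as.list(setNames(sample(1:40, 4L, TRUE), c("TP", "FP", "TN", "FN")))
    m <- compute_metrics(counts)
    expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall), tolerance = 1e-12)
    expect_gte(m$f1, min(m$precision, m$recall))
    expect_lte(m$f1, max(m$precision, m$recall))
  }
})

test_that("zero denominators warn and report 0 instead of failing", {
  expect_warning(m <- compute_metrics(list(TP = 0L, FP = 0L, TN = 10L, FN = 5L)),
                 "zero denominator")
  expect_equal(m$precision, 0)
  expect_true(m$degenerate)
  expect_error(compute_metrics(list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)),
               "all-zero")
})

test_that("ROC endpoints, degenerate cases and the pair-counting AUC oracle", {
  y <- c(rep("malignant", 5), rep("benign", 5))
  sep <- roc_curve(y, c(6:10, 1:5) / 10)
  expect_equal(sep$auc, 1)

  tied <- roc_curve(y, rep(0.5, 10))
  expect_equal(tied$auc, 0.5)

  set.seed(70)
  for (rep in 1:20) {
    yy <- sample(c("benign", "malignant"), 20, TRUE)
    if (length(unique(yy)) < 2L) next
    s <- round(runif(20), 1)                    # coarse scores force ties
    r <- roc_curve(yy, s)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(r$points$fpr[1], 0)
    expect_equal(tail(r$points$fpr, 1), 1)
    # O(n^2) oracle: fraction of correctly ordered (pos, neg) pairs, ties 1/2
    pos <- s[yy == "malignant"]; neg <- s[yy != "malignant"]
    oracle <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, oracle, tolerance = 1e-12)
  }

  expect_error(roc_curve(rep("benign", 5), runif(5)), "both classes")
})

test_that("metrics artifacts are written as json and csv", {
  m <- compute_metrics(list(TP = 8L, FP = 2L, TN = 7L, FN = 3L))
  r <- roc_curve(c(rep("malignant", 4), rep("benign", 4)), c(0.9, 0.8, 0.4, 0.7, 0.3, 0.6, 0.2, 0.1))
  dir <- tempfile()
  write_metrics(m, r, dir)
  js <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(js$accuracy, m$accuracy)
  expect_equal(js$auc, r$auc)
  roc_back <- utils::read.csv(file.path(dir, "roc.csv"))
  expect_equal(roc_back$fpr, r$points$fpr)
})
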