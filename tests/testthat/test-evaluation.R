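# Overlap metrics, ROC/AUC, bootstrap, operating points.

test_that("dice and jaccard match pixel enumeration and conventions", {
  a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
  expect_equal(dice(a, b), 1)        # empty-empty convention
  expect_equal(jaccard(a, b), 1)
  a[1, 1:2] <- 1                     # |A| = 2
  b[1, 1:2] <- 1; b[2, 1:2] <- 1     # |B| = 4, intersection 2
  expect_equal(dice(a, b), 2 * 2 / 6)
  expect_equal(jaccard(a, b), 2 / 4)
  expect_equal(dice(a, a), 1)
  d <- matrix(0, 4, 4); d[4, 4] <- 1
  expect_equal(dice(a, d), 0)
  expect_equal(jaccard(a, d), 0)
  expect_error(dice(a, matrix(0, 3, 3)), "shape")
})

test_that("dice/jaccard conversion is exact and self-inverse", {
  expect_equal(dice_to_jaccard(1), 1)
  expect_equal(jaccard_to_dice(dice_to_jaccard(0.42)), 0.42)
  for (d in seq(0, 1, by = 0.05))
    expect_equal(jaccard_to_dice(dice_to_jaccard(d)), d, tolerance = 1e-12)
  # every mask pair satisfies J <= D and D = 2J/(1+J)
  set.seed(7)
  for (i in 1:20) {
    a <- matrix(rbinom(36, 1, 0.4), 6, 6)
    b <- matrix(rbinom(36, 1, 0.4), 6, 6)
    D <- dice(a, b); J <- jaccard(a, b)
    expect_lte(J, D + 1e-12)
    expect_equal(D, 2 * J / (1 + J), tolerance = 1e-12)
  }
})

# Brute-force AUC oracle: enumerate all cancer/normal pairs.
auc_pairs <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("trapezoidal AUC equals Mann-Whitney pair enumeration", {
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  set.seed(3)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(s, y)$auc, auc_pairs(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  y <- rbinom(30, 1, 0.4); y[1:2] <- c(0, 1)
  s <- rnorm(30)
  a0 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a0)
  expect_equal(roc_auc(2 * s + 7, y)$auc, a0)
  expect_equal(roc_auc(rank(s), y)$auc, a0)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:10) {
    y <- c(0, 1, rbinom(28, 1, 0.3))
    s <- round(rnorm(30), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-10)
  }
})

test_that("bootstrap CI is deterministic, ordered, and degenerate when data are", {
  set.seed(5)
  y <- rep(c(0, 1), each = 10)
  s <- c(rnorm(10, 0), rnorm(10, 2))
  ci1 <- bootstrap_ci(s, y, n_boot = 300, seed = 42)
  ci2 <- bootstrap_ci(s, y, n_boot = 300, seed = 42)
  expect_identical(ci1, ci2)
  expect_lte(ci1$ci_low, ci1$ci_high)
  # perfectly separated far apart: every resample keeps AUC 1
  s2 <- c(rep(0, 10), rep(1, 10))
  ci <- bootstrap_ci(s2, y, n_boot = 100, seed = 1)
  expect_equal(c(ci$ci_low, ci$ci_high), c(1, 1))
  expect_error(bootstrap_ci(s, y, n_boot = 0), "n_boot")
})

test_that("bootstrap CI narrows with sample size", {
  width_at <- function(n) {
    set.seed(100 + n)
    y <- rep(c(0, 1), each = n / 2)
    s <- c(rnorm(n / 2), rnorm(n / 2, 1))
    ci <- bootstrap_ci(s, y, n_boot = 400, seed = 9)
    ci$ci_high - ci$ci_low
  }
  w <- vapply(c(50, 500, 5000), width_at, 0)
  expect_true(w[2] < w[1])
  expect_true(w[3] < w[2])
})

test_that("operating points match an exhaustive threshold sweep", {
  y <- c(0, 0, 0, 1, 1, 1)
  s <- c(0.1, 0.4, 0.6, 0.5, 0.7, 0.9)
  roc <- roc_auc(s, y)
  op <- operating_points(roc)
  # brute force over candidate thresholds
  cand <- sort(unique(c(s, -Inf, Inf)))
  stats_at <- t(vapply(cand, function(t) {
    pred <- as.integer(s >= t)
    c(se = mean(pred[y == 1]), sp = mean(1 - pred[y == 0]),
      acc = mean(pred == y))
  }, c(se = 0, sp = 0, acc = 0)))
  expect_equal(op$P1$se, max(stats_at[stats_at[, "sp"] == 1, "se"]))
  expect_equal(op$P2$sp, max(stats_at[stats_at[, "se"] == 1, "sp"]))
  expect_equal(op$P3$acc, max(stats_at[, "acc"]))
  expect_equal(op$P1$sp, 1)
  expect_equal(op$P2$se, 1)
  # perfect classifier: all three points are (1, 1, 1)
  op2 <- operating_points(roc_auc(c(1, 2, 8, 9), c(0, 0, 1, 1)))
  for (p in op2) expect_equal(c(p$se, p$sp, p$acc), c(1, 1, 1))
})

test_that("P3 accuracy ties resolve toward higher sensitivity", {
  # thresholds 0.5 and 0.9 both give accuracy 0.75; the lower one has SE 1
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.9, 0.5, 0.8)
  op <- operating_points(roc_auc(s, y))
  expect_equal(op$P3$se, 1)
})

test_that("precision-recall and confusion matrix match hand enumeration", {
  y <- c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1)
  s <- seq(0.05, 0.95, length.out = 10)
  pr <- pr_curve(s, y)
  for (i in seq_len(nrow(pr))) {
    pred <- s >= pr$threshold[i]
    expect_equal(pr$precision[i], sum(pred & y == 1) / sum(pred))
    expect_equal(pr$recall[i], sum(pred & y == 1) / sum(y == 1))
  }
  # everything called cancer: recall 1, precision = prevalence
  expect_equal(pr$recall[nrow(pr)], 1)
  expect_equal(pr$precision[nrow(pr)], mean(y))
  cm <- confusion_matrix(ifelse(s >= 0.5, "cancer", "normal"),
                         ifelse(y == 1, "cancer", "normal"))
  expect_equal(sum(cm), 10)
  cm_perfect <- confusion_matrix(y, y)
  expect_equal(cm_perfect["normal", "cancer"] + cm_perfect["cancer", "normal"],
               0L)
})
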