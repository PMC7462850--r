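# T07, slide features, MRMR ranking, thresholding.

test_that("t07 and slide features match hand counts", {
  tpm <- matrix(c(0.9, 0.8, 0.6, 0.5), 2, 2)
  ta <- matrix(1, 2, 2)
  tm <- tumor_map(tpm, ta)
  expect_equal(t07(tm), 0.5)               # 2 of 4 pixels >= 0.7
  f <- extract_slide_features(tm)
  expect_equal(unname(f["cumhist_07"]), 0.5)
  expect_equal(unname(f["mean"]), 0.7)
  expect_equal(unname(f["tumor_area"]), 4)
  expect_equal(unname(f["variance"]), unname(f["std"])^2)
  # all pixels at 1: cumulative histogram all ones, zero spread
  tm1 <- tumor_map(matrix(1, 3, 3), matrix(1, 3, 3))
  f1 <- extract_slide_features(tm1)
  expect_equal(unname(f1[sprintf("cumhist_%02d", 0:9)]), rep(1, 10))
  expect_equal(unname(f1["std"]), 0)
  expect_equal(t07(tm1), 1)
})

test_that("empty tumor area yields the zero convention", {
  tm <- tumor_map(matrix(0.9, 3, 3), matrix(0, 3, 3))
  expect_equal(t07(tm), 0)
  f <- extract_slide_features(tm)
  expect_equal(unname(f["tumor_area"]), 0)
  expect_true(all(f == 0))
})

test_that("t07 equals brute-force counting and the cumhist 0.7 bin", {
  for (seed in 1:25) {
    tm <- random_tumor_map(8, seed)
    brute <- if (sum(tm$ta) == 0) 0 else
      sum(tm$tpm[tm$ta == 1] >= 0.7) / sum(tm$ta)
    expect_identical(t07(tm), brute)
    expect_identical(t07(tm),
                     unname(extract_slide_features(tm)["cumhist_07"]))
  }
})

test_that("raising TPM on TA never decreases T07, and T07 is size-invariant", {
  tm <- random_tumor_map(8, 3)
  up <- tm
  up$tpm <- clamp(tm$tpm + 0.1, 0, 1)
  expect_gte(t07(up), t07(tm))
  # duplicating every pixel leaves the fraction unchanged
  dup <- tumor_map(rbind(tm$tpm, tm$tpm), rbind(tm$ta, tm$ta))
  expect_equal(t07(dup), t07(tm))
})

test_that("tumor-map invariants hold on random maps", {
  for (seed in 1:10) {
    set.seed(seed)
    probs <- array(runif(6 * 6 * 5), dim = c(6, 6, 5))
    probs <- probs / array(rep(apply(probs, c(1, 2), sum), 5),
                           dim = dim(probs))
    tm <- derive_tumor_map(likelihood_map(probs, mpp = 2))
    # brute-force argmax loop
    for (i in 1:6) for (j in 1:6) {
      expect_equal(tm$ta[i, j],
                   as.integer(which.max(probs[i, j, ]) == 1 &&
                                max(probs[i, j, -1]) < probs[i, j, 1]))
    }
    # TA subset of {TPM > 1/5}
    expect_true(all(tm$tpm[tm$ta == 1] > 1 / 5))
  }
})

test_that("exact probability ties are excluded from TA", {
  probs <- array(0.1, dim = c(1, 1, 5))
  probs[1, 1, 1] <- 0.5; probs[1, 1, 2] <- 0.5; probs[1, 1, 3:5] <- 0
  tm <- derive_tumor_map(likelihood_map(probs, mpp = 2))
  expect_equal(sum(tm$ta), 0)
  expect_equal(tm$tpm[1, 1], 0.5)
})

# Exhaustive MRMR oracle: recompute the greedy MID objective directly.
mrmr_oracle <- function(features, y, k, bins = 3L) {
  disc <- apply(features, 2, function(x) {
    r <- rank(x, ties.method = "first")
    as.integer(ceiling(r * bins / length(x)))
  })
  mi <- function(a, b) {
    tab <- table(a, b); p <- tab / sum(tab)
    pa <- rowSums(p); pb <- colSums(p); idx <- p > 0
    sum(p[idx] * log(p[idx] / outer(pa, pb)[idx]))
  }
  sel <- integer(0); rem <- seq_len(ncol(features))
  for (s in seq_len(k)) {
    obj <- sapply(rem, function(j) {
      rel <- mi(disc[, j], y)
      if (length(sel) == 0) rel
      else rel - mean(sapply(sel, function(q) mi(disc[, j], disc[, q])))
    })
    sel <- c(sel, rem[which.max(obj)])
    rem <- setdiff(rem, sel)
  }
  sel
}

test_that("MRMR ranks the label-matching feature first", {
  set.seed(2)
  y <- rep(c(0, 1), each = 10)
  f <- cbind(noise1 = rnorm(20), signal = y + rnorm(20, sd = 0.01),
             noise2 = rnorm(20))
  expect_equal(mrmr_select(f, y)[1], 2)
})

test_that("MRMR matches the exhaustive greedy oracle on random data", {
  set.seed(14)
  for (rep in 1:40) {
    n <- sample(12:30, 1)
    nf <- sample(3:5, 1)
    y <- c(0, 0, 1, 1, rbinom(n - 4, 1, 0.5))
    f <- matrix(rnorm(n * nf), n, nf)
    f[, 1] <- f[, 1] + y                      # one informative feature
    k <- sample(seq_len(nf), 1)
    expect_equal(mrmr_select(f, y, k = k), mrmr_oracle(f, y, k))
  }
})

test_that("MRMR demotes a duplicated informative feature", {
  set.seed(8)
  y <- rep(c(0, 1), each = 12)
  strong <- y + rnorm(24, sd = 0.05)
  weak <- y + rnorm(24, sd = 0.9)
  f <- cbind(strong, strong_copy = strong, weak)
  r <- mrmr_select(f, y, k = 3)
  expect_equal(r[1], 1)
  # the redundant copy (MI with selected = self-information) ranks below
  # the independent weaker feature
  expect_equal(r[2], 3)
})

test_that("MRMR with k = n_features returns a permutation; errors are raised", {
  set.seed(4)
  f <- matrix(rnorm(40), 10, 4)
  y <- rep(c(0, 1), each = 5)
  expect_setequal(mrmr_select(f, y, k = 4), 1:4)
  expect_error(mrmr_select(f, rep(1, 10)), "constant")
  expect_error(mrmr_select(f, y, k = 5), "exceeds")
})

test_that("slide thresholding uses the inclusive rule", {
  expect_equal(classify_slide(0.5, 0.5), "cancer")
  expect_equal(classify_slide(0.499, 0.5), "normal")
  expect_equal(classify_slide(0, 0.01), "normal")
})

test_that("threshold sweep over scores reproduces every confusion matrix", {
  set.seed(6)
  y <- c(0, 1, rbinom(10, 1, 0.5))
  s <- round(runif(12), 2)
  cand <- sort(unique(s))
  seen <- unique(lapply(c(cand[1] - 1, cand), function(t)
    confusion_matrix(as.integer(s >= t), y)))
  # each achievable matrix corresponds to a distinct positive-count split
  npos <- vapply(seen, function(m) sum(m[, "cancer"]), 0L)
  expect_equal(sort(npos, decreasing = TRUE), npos[order(-npos)])
  expect_equal(length(seen), length(unique(npos)))
})

test_that("tune_threshold matches exhaustive search and handles separation", {
  # perfectly separated: midpoint of the gap
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.2, 0.6, 0.8)
  expect_equal(tune_threshold(s, y), 0.4)
  thr <- tune_threshold(s, y, criterion = "sensitivity1")
  expect_lte(thr, 0.6)
  expect_true(all(s[y == 1] >= thr))
  # 6-slide toy: accuracy at returned threshold equals brute-force optimum
  y2 <- c(0, 0, 0, 1, 1, 1)
  s2 <- c(0.2, 0.55, 0.3, 0.5, 0.8, 0.9)
  t_acc <- tune_threshold(s2, y2)
  brute <- max(sapply(c(-Inf, sort(unique(s2))),
                      function(t) mean((s2 >= t) == y2)))
  expect_equal(mean((s2 >= t_acc) == y2), brute)
})
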