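# Patch- and slide-level evaluation: overlap metrics, ROC analysis with
# bootstrap confidence intervals, operating points, precision-recall.

#' Dice coefficient between two binary masks
#'
#' Dice = 2|A n B| / (|A| + |B|). Two empty masks score 1 by convention, so
#' that all-negative validation patches do not poison averages.
#'
#' @param pred,ref Binary masks (logical or 0/1 numeric) of identical shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)) || length(pred) != length(ref))
    stop("mask shapes differ")
  a <- as.logical(pred); b <- as.logical(ref)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Jaccard index between two binary masks
#'
#' Jaccard = |A n B| / |A u B|; 1 when both masks are empty.
#'
#' @inheritParams dice
#' @return Jaccard index in [0, 1].
#' @export
jaccard <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)) || length(pred) != length(ref))
    stop("mask shapes differ")
  a <- as.logical(pred); b <- as.logical(ref)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Convert between Dice and Jaccard
#'
#' The two overlap measures are deterministic transforms of each other:
#' J = D / (2 - D) and D = 2J / (1 + J).
#'
#' @param d,j Dice coefficient / Jaccard index in [0, 1].
#' @return The converted coefficient.
#' @export
dice_to_jaccard <- function(d) {
  stopifnot(all(d >= 0 & d <= 1))
  d / (2 - d)
}

#' @rdname dice_to_jaccard
#' @export
jaccard_to_dice <- function(j) {
  stopifnot(all(j >= 0 & j <= 1))
  2 * j / (1 + j)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "cancer")
  } else {
    as.integer(labels != 0)
  }
}

# Rank-based AUC (equals the Mann-Whitney statistic; midranks handle ties).
auc_rank <- function(scores, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC for slide scores
#'
#' Builds the ROC curve over all unique score thresholds (decision rule:
#' predict cancer when score >= threshold) plus infinite endpoints, and
#' integrates it by the trapezoidal rule, which equals the Mann-Whitney pair
#' statistic P(score_cancer > score_normal) + P(tie)/2 exactly, ties included.
#'
#' @param scores Numeric slide scores (higher = more cancer-like).
#' @param labels Slide labels: "cancer"/"normal", factor, or 0/1 numeric.
#' @return An object of class `roc_result` with `thresholds`, `se`
#'   (sensitivity), `sp` (specificity) and `auc`; confidence-interval fields
#'   are unset until [bootstrap_ci()] fills them.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(y) != length(scores)) stop("scores/labels length mismatch")
  if (length(unique(y)) < 2) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  se <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n1, 0)
  sp <- vapply(thr, function(t) sum(scores < t & y == 0L) / n0, 0)
  fpr <- 1 - sp
  auc <- sum(diff(fpr) * (se[-1] + se[-length(se)]) / 2)
  structure(
    list(thresholds = thr, se = se, sp = sp, auc = auc,
         ci_low = NA_real_, ci_high = NA_real_, n_boot = NA_integer_,
         seed = NA_integer_, scores = scores, labels = y),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d slides (%d cancer / %d normal)\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0)))
  if (!is.na(x$ci_low)) {
    cat(sprintf("AUC = %.3f  [%.3f, %.3f] (%d bootstrap resamples, +/- %.3f)\n",
                x$auc, x$ci_low, x$ci_high, x$n_boot,
                (x$ci_high - x$ci_low) / 2))
  } else {
    cat(sprintf("AUC = %.3f\n", x$auc))
  }
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$sp, x$se, type = "s", xlab = "1 - specificity",
                 ylab = "sensitivity", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Resamples prediction indices with replacement (default 2000 resamples) and
#' takes the percentile interval of the resampled AUCs. Resamples that contain
#' only one class are discarded and redrawn. Fully deterministic given `seed`.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap resamples.
#' @param alpha Two-sided miscoverage; 0.05 gives the 95% interval.
#' @param seed RNG seed for the resampling.
#' @return List with `ci_low`, `ci_high`, `aucs` (the resampled values).
#' @export
bootstrap_ci <- function(scores, labels, n_boot = 2000, alpha = 0.05,
                         seed = 1L) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- length(scores)
  aucs <- with_seed(seed, {
    out <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2) break
      }
      out[b] <- auc_rank(scores[idx], y[idx])
    }
    out
  })
  q <- stats::quantile(aucs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  list(ci_low = q[1], ci_high = q[2], aucs = aucs)
}

#' ROC analysis with bootstrap CI in one call
#'
#' @inheritParams bootstrap_ci
#' @return A `roc_result` with CI fields populated.
#' @export
roc_with_ci <- function(scores, labels, n_boot = 2000, alpha = 0.05,
                        seed = 1L) {
  r <- roc_auc(scores, labels)
  ci <- bootstrap_ci(scores, labels, n_boot = n_boot, alpha = alpha,
                     seed = seed)
  r$ci_low <- ci$ci_low; r$ci_high <- ci$ci_high
  r$n_boot <- as.integer(n_boot); r$seed <- as.integer(seed)
  r
}

#' Fixed operating points of a ROC curve
#'
#' P1: the maximal-sensitivity threshold among those with specificity 1
#' (no false alarms). P2: the maximal-specificity threshold among those with
#' sensitivity 1 (no missed cancers; the screening point). P3: the threshold
#' maximizing plain accuracy at the observed prevalence; accuracy ties are
#' broken toward the lower threshold (higher sensitivity).
#'
#' @param roc A `roc_result` from [roc_auc()].
#' @return Object of class `operating_points`: a list of P1/P2/P3, each with
#'   `threshold`, `se`, `sp`, `acc`.
#' @export
operating_points <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  y <- roc$labels; n <- length(y)
  n1 <- sum(y == 1); n0 <- n - n1
  acc <- (roc$se * n1 + roc$sp * n0) / n
  pick <- function(i) list(threshold = roc$thresholds[i], se = roc$se[i],
                           sp = roc$sp[i], acc = acc[i])
  i1 <- which(roc$sp == 1)
  p1 <- pick(i1[which.max(roc$se[i1])])
  i2 <- which(roc$se == 1)
  p2 <- pick(i2[which.max(roc$sp[i2])])
  best <- max(acc)
  # thresholds are stored in decreasing order; the last maximal-accuracy
  # index is the lowest threshold, i.e. the higher-sensitivity side of a tie
  i3 <- max(which(acc == best))
  p3 <- pick(i3)
  structure(list(P1 = p1, P2 = p2, P3 = p3), class = "operating_points")
}

#' @export
print.operating_points <- function(x, ...) {
  for (nm in c("P1", "P2", "P3")) {
    p <- x[[nm]]
    cat(sprintf("%s: SE %.2f  SP %.2f  ACC %.2f  (threshold %.4g)\n",
                nm, p$se, p$sp, p$acc, p$threshold))
  }
  invisible(x)
}

#' Precision-recall curve
#'
#' Precision = TP/(TP+FP) and recall = sensitivity, at every unique score
#' threshold (rule: predict cancer when score >= threshold).
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `precision`, `recall`.
#' @export
pr_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y == 1L)
  out <- lapply(thr, function(t) {
    pred <- scores >= t
    tp <- sum(pred & y == 1L); fp <- sum(pred & y == 0L)
    data.frame(threshold = t,
               precision = if (tp + fp > 0) tp / (tp + fp) else 1,
               recall = tp / n1)
  })
  do.call(rbind, out)
}

#' Slide-level confusion matrix
#'
#' @param pred_labels Predicted labels ("cancer"/"normal" or 0/1).
#' @param labels Reference labels in the same encoding.
#' @return 2x2 integer matrix, rows = reference, columns = prediction.
#' @export
confusion_matrix <- function(pred_labels, labels) {
  p <- as_binary_labels(pred_labels); y <- as_binary_labels(labels)
  if (length(p) != length(y)) stop("length mismatch")
  m <- matrix(0L, 2, 2,
              dimnames = list(reference = c("normal", "cancer"),
                              predicted = c("normal", "cancer")))
  for (i in seq_along(y)) m[y[i] + 1L, p[i] + 1L] <- m[y[i] + 1L, p[i] + 1L] + 1L
  m
}
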