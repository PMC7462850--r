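# Slide-level scoring: features of the tumor likelihood map, MRMR feature
# ranking, the T07 statistic and score thresholding.

#' Slide-level features of a tumor map
#'
#' Computes, over the tumor-area (TA) pixels of a tumor map: a 10-bin
#' cumulative histogram of the tumor probability map (fraction of TA pixels
#' with TPM >= t for t = 0.0, 0.1, ..., 0.9), the TA pixel count, and
#' first-order statistics (mean, standard deviation, variance) of the TPM.
#' With `stats_domain = "tissue"` the histogram and statistics are taken over
#' all tissue pixels instead (TA remains the histogram's normalizer domain
#' only in "ta" mode). An empty TA yields the all-zero vector with area 0.
#'
#' @param tumor_map A `tumor_map` from [derive_tumor_map()].
#' @param stats_domain `"ta"` (default) or `"tissue"`.
#' @return Named numeric vector: `cumhist_00` ... `cumhist_09`, `tumor_area`,
#'   `mean`, `std`, `variance`.
#' @export
extract_slide_features <- function(tumor_map, stats_domain = c("ta", "tissue")) {
  stats_domain <- match.arg(stats_domain)
  stopifnot(inherits(tumor_map, "tumor_map"))
  tpm <- tumor_map$tpm; ta <- tumor_map$ta
  if (!identical(dim(tpm), dim(ta))) stop("TPM/TA shape mismatch")
  thresholds <- seq(0, 0.9, by = 0.1)
  hnames <- sprintf("cumhist_%02.0f", thresholds * 10)
  vals <- if (stats_domain == "ta") tpm[ta == 1] else {
    if (is.null(tumor_map$tissue)) as.vector(tpm) else tpm[tumor_map$tissue == 1]
  }
  area <- sum(ta == 1)
  if (length(vals) == 0) {
    out <- c(rep(0, 10), area, 0, 0, 0)
  } else {
    ch <- vapply(thresholds, function(t) mean(vals >= t), 0)
    s <- stats::sd(vals); if (is.na(s)) s <- 0
    out <- c(ch, area, mean(vals), s, s^2)
  }
  names(out) <- c(hnames, "tumor_area", "mean", "std", "variance")
  out
}

#' The T07 slide statistic
#'
#' T07 = (number of tumor-area pixels with tumor probability >= 0.7) divided
#' by the tumor-area pixel count. It is the 0.7 bin of the cumulative TPM
#' histogram, and the single most expressive slide-level feature. Returns 0
#' for an empty tumor area: no tumor-argmax pixel means no evidence of cancer.
#'
#' @inheritParams extract_slide_features
#' @return Fraction in [0, 1].
#' @export
t07 <- function(tumor_map) {
  stopifnot(inherits(tumor_map, "tumor_map"))
  tpm <- tumor_map$tpm; ta <- tumor_map$ta
  if (!identical(dim(tpm), dim(ta))) stop("TPM/TA shape mismatch")
  n_ta <- sum(ta == 1)
  if (n_ta == 0) return(0)
  sum(tpm[ta == 1] >= 0.7) / n_ta
}

# -- minimum-redundancy maximum-relevance feature ranking ---------------------

# Equal-frequency discretization into `bins` levels; rank-based so it is
# deterministic under ties.
discretize_ef <- function(x, bins = 3L) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / length(x)))
}

# Plug-in mutual information (nats) from two discrete vectors.
mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(pa, pb)[idx]))
}

#' MRMR feature ranking (greedy MID scheme)
#'
#' Ranks features by minimum-redundancy maximum-relevance with the mutual
#' information difference criterion: the first feature maximizes the relevance
#' I(f; y); each subsequent feature maximizes
#' I(f; y) - mean over already-selected s of I(f; f_s).
#' Features are discretized into equal-frequency bins (default 3) before the
#' plug-in MI estimate, which keeps the estimate stable at small sample sizes.
#' Ties are broken toward the lower feature index.
#'
#' @param features Numeric matrix, slides x features.
#' @param labels Slide labels (two classes, each with >= 2 slides).
#' @param k Number of features to rank (default: all).
#' @param bins Discretization bins.
#' @return Integer vector of feature column indices, best first.
#' @export
mrmr_select <- function(features, labels, k = ncol(features), bins = 3L) {
  features <- as.matrix(features)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("labels are constant")
  if (min(table(y)) < 2) stop("need >= 2 slides per class")
  if (k > ncol(features)) stop("k exceeds the number of features")
  d <- apply(features, 2, discretize_ef, bins = bins)
  nf <- ncol(features)
  rel <- vapply(seq_len(nf), function(j) mutual_information(d[, j], y), 0)
  red <- matrix(NA_real_, nf, nf)
  selected <- integer(0)
  remaining <- seq_len(nf)
  for (step in seq_len(k)) {
    obj <- vapply(remaining, function(j) {
      if (length(selected) == 0) return(rel[j])
      for (s in selected) {
        if (is.na(red[j, s])) {
          red[j, s] <<- red[s, j] <<- mutual_information(d[, j], d[, s])
        }
      }
      rel[j] - mean(red[j, selected])
    }, 0)
    pick <- remaining[which.max(obj)]   # which.max: first index wins ties
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Threshold a slide score into a label
#'
#' @param score T07 (or any slide score) in [0, 1].
#' @param threshold Decision threshold; a slide is called cancer when
#'   `score >= threshold` (inclusive rule).
#' @return `"cancer"` or `"normal"` (vectorised).
#' @export
classify_slide <- function(score, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  ifelse(score >= threshold, "cancer", "normal")
}

#' Tune the slide-score threshold on a held-out tuning set
#'
#' Searches candidate thresholds (midpoints between adjacent sorted unique
#' scores, plus the extremes) for the one maximizing the chosen criterion:
#' `"accuracy"` for the best-accuracy operating point, or `"sensitivity1"`
#' for the screening point (smallest threshold set that keeps sensitivity at
#' 1, maximizing specificity). Accuracy ties are broken toward the lower
#' threshold; with perfectly separated classes the gap midpoint is returned.
#'
#' @param scores Numeric slide scores on the tuning set.
#' @param labels Tuning-set labels (both classes required).
#' @param criterion `"accuracy"` or `"sensitivity1"`.
#' @return Numeric threshold.
#' @export
tune_threshold <- function(scores, labels,
                           criterion = c("accuracy", "sensitivity1")) {
  criterion <- match.arg(criterion)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  # the decision rule score >= t is piecewise constant in t, changing only at
  # the unique scores: evaluating there (plus a below-everything sentinel)
  # covers every achievable confusion matrix
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, u)
  stat <- vapply(cand, function(t) {
    pred <- as.integer(scores >= t)
    if (criterion == "accuracy") mean(pred == y)
    else if (all(pred[y == 1] == 1)) mean(pred[y == 0] == 0) else -1
  }, 0)
  best <- which(stat == max(stat))
  # lowest contiguous optimal run (ties broken toward higher sensitivity);
  # the optimal t-interval is (previous candidate, run end]: return its
  # midpoint so perfectly separated classes get the centre of the gap
  run_end <- if (length(best) == 1) best else {
    gaps <- which(diff(best) != 1)
    best[if (length(gaps)) gaps[1] else length(best)]
  }
  lo <- cand[max(run_end - 1, 1)]
  (lo + cand[run_end]) / 2
}
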