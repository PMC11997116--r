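# Evaluation statistics. Mid-ranks are used throughout (ROC AUC,
# Mann-Whitney, DeLong placement values), so tied scores count half.

check_binary <- function(scores, labels, both = TRUE) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (both && (sum(labels) == 0L || sum(labels) == length(labels)))
    stop("both classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' The Mann-Whitney U statistic scaled to `[0, 1]`: the probability that a
#' random positive outscores a random negative, ties counted half
#' (mid-rank convention).
#'
#' @param scores Numeric scores (higher = more modified).
#' @param labels Binary labels (1 = positive class).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary(scores, labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores)              # mid-ranks
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated ("average precision") convention: the sum over unique
#' score thresholds of the recall increment times the precision at that
#' threshold.
#'
#' @inheritParams roc_auc
#' @return Average precision in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- check_binary(scores, labels, both = FALSE)
  if (sum(labels) == 0L) stop("pr_auc requires at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- c(s[-1L] != s[-length(s)], TRUE)  # block ends of tied scores
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(labels)
  sum(diff(c(0, rec)) * prec)
}

#' Confusion-matrix metrics at a score cutoff
#'
#' Predictions are `score > cutoff`. Ratios whose denominator class is
#' empty are reported as `NA`.
#'
#' @inheritParams roc_auc
#' @param cutoff Score cutoff in `(0, 1)`.
#' @return List with `sensitivity`, `specificity`, `precision`, `fpr`.
#' @export
operating_point <- function(scores, labels, cutoff = 0.5) {
  labels <- check_binary(scores, labels, both = FALSE)
  pred <- scores > cutoff
  tp <- sum(pred & labels == 1L); fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L); fp <- sum(pred & labels == 0L)
  safe <- function(num, den) if (den == 0L) NA_real_ else num / den
  list(sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp),
       precision = safe(tp, tp + fp), fpr = safe(fp, fp + tn))
}

# placement values: for each positive, the fraction of negatives it beats
# (ties half), and vice versa
placements <- function(scores, labels) {
  x <- scores[labels == 1L]; y <- scores[labels == 0L]
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  rx <- rank(x); ry <- rank(y)
  v10 <- (r[seq_len(m)] - rx) / n          # per-positive
  v01 <- 1 - (r[m + seq_len(n)] - ry) / m  # per-negative
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors over the same labelled examples
#' using DeLong's placement-value covariance estimate and a two-sided
#' normal reference. Identical score vectors give `z = 0`, `p = 1`.
#'
#' @param scores1,scores2 Paired score vectors.
#' @param labels Shared binary labels.
#' @return List with `auc1`, `auc2`, `z`, `p`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  labels <- check_binary(scores1, labels)
  if (length(scores2) != length(labels)) stop("scores2 and labels differ in length")
  p1 <- placements(scores1, labels)
  p2 <- placements(scores2, labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- p1$auc - p2$auc
  z <- if (v <= 0) {
    if (abs(d) < .Machine$double.eps^0.5) 0 else sign(d) * Inf
  } else d / sqrt(v)
  list(auc1 = p1$auc, auc2 = p2$auc, z = z, p = 2 * pnorm(-abs(z)))
}

parse_bins <- function(bins) {
  out <- lapply(bins, function(b) {
    if (is.character(b)) {
      p <- strsplit(sub("\\+$", "-Inf", b), "-", fixed = FALSE)[[1L]]
      b <- as.numeric(p)
    }
    if (length(b) != 2L || b[1L] > b[2L]) stop("malformed depth bin")
    b
  })
  if (length(out) > 1L) {
    m <- do.call(rbind, out)
    o <- order(m[, 1L])
    if (any(m[o, 1L][-1L] <= m[o, 2L][-nrow(m)]))
      stop("depth bins overlap")
  }
  out
}

#' ROC AUC stratified by subread depth
#'
#' @inheritParams roc_auc
#' @param depth Integer subread depth per example.
#' @param bins List of inclusive depth intervals, each `c(lo, hi)` or a
#'   string like `"1-5"` or `"21+"`; bins must not overlap.
#' @return Data frame with `bin`, `n` and `auc` (`NA` where a bin holds
#'   fewer than two classes or no examples).
#' @export
depth_stratified_auc <- function(scores, labels, depth, bins) {
  labels <- check_binary(scores, labels)
  if (length(depth) != length(labels)) stop("depth and labels differ in length")
  iv <- parse_bins(bins)
  res <- lapply(seq_along(iv), function(i) {
    sel <- depth >= iv[[i]][1L] & depth <= iv[[i]][2L]
    auc <- if (sum(sel) == 0L || length(unique(labels[sel])) < 2L) NA_real_
    else roc_auc(scores[sel], labels[sel])
    nm <- if (is.character(bins[[i]])) bins[[i]] else
      paste0(iv[[i]][1L], "-", iv[[i]][2L])
    data.frame(bin = nm, n = sum(sel), auc = auc, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution when both groups have at most 8 untied
#' observations; otherwise the normal approximation with tie correction
#' (no continuity correction).
#'
#' @param a,b Numeric samples.
#' @return List with the U statistic (`u`, for group `a`) and two-sided `p`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("mann_whitney: empty input")
  exact <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = FALSE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Pearson correlation with a two-sided test
#'
#' @param x,y Numeric vectors of equal length; both need positive variance.
#' @return List with `r` and two-sided `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("pearson_cor needs two equal-length vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("pearson_cor: zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
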