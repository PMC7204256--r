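# ROC / precision-recall machinery for the two benchmark tasks:
# misclassified-sample detection (scores = average misclassification
# probabilities over cases) and disease-associated-SNP detection (scores =
# association p-values).

#' ROC and PR curves for score-based detection
#'
#' Sweeps a decreasing threshold over the scores (higher score = more likely
#' positive); equal scores collapse into a single operating point.
#'
#' @param scores Numeric scores, higher meaning more suspect.
#' @param truth Logical (or 0/1) ground-truth positives.
#' @return Object of class \code{detection_curves}: \code{roc} (data.frame
#'   fpr, tpr, threshold), \code{pr} (recall, precision, threshold),
#'   \code{auc_roc}, \code{auc_pr}, \code{n_pos}, \code{n_neg}.
#' @export
detection_metrics <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0) stop("no positives in truth: PR curve undefined")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  tp <- cumsum(t); fp <- cumsum(!t)
  last <- !duplicated(s, fromLast = TRUE)  # group tied scores
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, if (n_neg > 0) fp / n_neg else rep(0, length(fp)))
  precision <- c(1, tp / (tp + fp))
  roc <- data.frame(fpr = fpr, tpr = tpr, threshold = c(Inf, thr))
  pr <- data.frame(recall = tpr, precision = precision,
                   threshold = c(Inf, thr))
  structure(list(roc = roc, pr = pr,
                 auc_roc = auc_trapezoid(fpr, tpr),
                 auc_pr = auc_trapezoid(tpr, precision),
                 n_pos = n_pos, n_neg = n_neg),
            class = "detection_curves")
}

#' @export
print.detection_curves <- function(x, ...) {
  cat(sprintf("detection_curves: AUC ROC %.3f, AUC PR %.3f (%d pos / %d neg)\n",
              x$auc_roc, x$auc_pr, x$n_pos, x$n_neg))
  invisible(x)
}

#' ROC/PR for SNP detection from association p-values
#'
#' Threshold sweep over p-values (smaller p = called positive): recall is
#' the recovered causal fraction, the false positive rate is over non-causal
#' SNPs, precision is among sub-threshold SNPs.
#'
#' @param p Association p-values over the full SNP universe.
#' @param causal_indices Integer indices of truly causal SNPs.
#' @return A \code{detection_curves} object.
#' @export
snp_detection_metrics <- function(p, causal_indices) {
  if (length(causal_indices) == 0) stop("empty causal set")
  truth <- seq_along(p) %in% causal_indices
  detection_metrics(-p, truth)
}

#' Trapezoidal area under a curve
#'
#' Points are sorted by x first; the result is clamped to the unit interval.
#'
#' @param x,y Curve coordinates (at least two points).
#' @return Scalar area.
#' @export
auc_trapezoid <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least two curve points")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  a <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  min(max(a, 0), 1)
}

#' Pointwise mean curve across replicates
#'
#' Each curve is linearly interpolated onto a common x-grid and the y-values
#' averaged pointwise.
#'
#' @param curves List of data.frames with columns x and y (or two-column
#'   objects; the first column is x).
#' @param grid Common x-grid (default 201 evenly spaced points in the unit interval).
#' @return data.frame with \code{x} and mean \code{y}.
#' @export
mean_curve_across_replicates <- function(curves,
                                         grid = seq(0, 1, length.out = 201)) {
  if (length(curves) == 0) stop("no curves to average")
  ys <- vapply(curves, function(cv) {
    cv <- as.data.frame(cv)
    stats::approx(cv[[1]], cv[[2]], xout = grid, rule = 2,
                  ties = "ordered")$y
  }, numeric(length(grid)))
  data.frame(x = grid, y = rowMeans(ys))
}

#' Count significant SNPs against ground truth
#'
#' True positives are causal SNPs called significant; novel true positives
#' are causal SNPs significant in the corrected-phenotype scan but in
#' neither the true-phenotype nor the misclassified-phenotype scans; false
#' positives are significant non-causal SNPs.
#'
#' @param p Corrected-phenotype p-values.
#' @param causal_indices Indices of causal SNPs.
#' @param threshold_rule \code{"bonferroni"} (on unadjusted p) or
#'   \code{"bh"} (adjusted p < 0.1).
#' @param p_true,p_misclassified Reference scans for the novelty rule
#'   (optional; novel counts are NA without them).
#' @param family_alpha Family-wise rate for Bonferroni (default 0.05).
#' @param bh_alpha BH significance level (default 0.1).
#' @return List with \code{true_positive}, \code{novel_true_positive},
#'   \code{false_positive}, \code{threshold}.
#' @export
count_significant_snps <- function(p, causal_indices,
                                   threshold_rule = c("bonferroni", "bh"),
                                   p_true = NULL, p_misclassified = NULL,
                                   family_alpha = 0.05, bh_alpha = 0.1) {
  threshold_rule <- match.arg(threshold_rule)
  if (!is.null(p_true)) stopifnot(length(p_true) == length(p))
  if (!is.null(p_misclassified)) {
    stopifnot(length(p_misclassified) == length(p))
  }
  sig_at <- function(pv) {
    if (threshold_rule == "bonferroni") {
      pv < bonferroni_threshold(length(pv), family_alpha)
    } else {
      benjamini_hochberg(pv) < bh_alpha
    }
  }
  sig <- sig_at(p)
  causal <- seq_along(p) %in% causal_indices
  novel <- NA_integer_
  if (!is.null(p_true) && !is.null(p_misclassified)) {
    novel <- sum(sig & causal & !sig_at(p_true) & !sig_at(p_misclassified))
  }
  list(true_positive = sum(sig & causal),
       novel_true_positive = novel,
       false_positive = sum(sig & !causal),
       threshold = if (threshold_rule == "bonferroni") {
         bonferroni_threshold(length(p), family_alpha)
       } else {
         bh_alpha
       })
}
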