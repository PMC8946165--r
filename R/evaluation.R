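# Group comparison and classifier evaluation: Welch t-tests, Matthews
# correlation, rank-based AUC-ROC, average-precision AUC-PR, stratified
# percentile bootstrap intervals, and sensitivity/specificity at a
# Youden-J operating point.

#' Two-sided Welch t-test between two groups
#'
#' Unequal-variance (Welch) test; the convention `p = 1` is used when both
#' groups are constant with equal means.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values.
#' @return List with `t`, `p` and `df`.
#' @export
two_sided_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_tcf("each group needs at least 2 values", class = "tcf_spec_error")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, p = 0, df = NA_real_))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the usual
#' convention of 0 whenever a factor of the denominator vanishes.
#'
#' @param tp,fp,tn,fn Nonnegative confusion-matrix counts.
#' @return Value in \[-1, 1\].
#' @export
mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  # products can overflow integer range; go through double
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(as.numeric(den))
}

as_binary_labels <- function(labels, positive = NULL) {
  y <- factor(labels)
  if (nlevels(y) > 2L) stop_tcf("labels must be binary", class = "tcf_class_error")
  positive <- positive %||% levels(y)[nlevels(y)]
  y == positive
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, with ties counted one half.
#'
#' @param scores Numeric decision scores, larger favoring the positive class.
#' @param labels Binary labels.
#' @param positive Positive-class label (default: last factor level).
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels, positive = NULL) {
  pos <- as_binary_labels(labels, positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop_tcf("both classes must be present", class = "tcf_class_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step integration `sum (R_i - R_{i-1}) P_i` over descending score
#' thresholds, with tied scores grouped into a single threshold. Constant
#' scores therefore give the positive-class prevalence.
#'
#' @inheritParams auc_roc
#' @return Average precision in \[0, 1\].
#' @export
auc_pr <- function(scores, labels, positive = NULL) {
  pos <- as_binary_labels(labels, positive)
  n1 <- sum(pos)
  if (n1 == 0L) stop_tcf("no positives in labels", class = "tcf_class_error")
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; r_prev <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(sel & pos)
    prec <- tp / sum(sel)
    rec <- tp / n1
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

#' Sensitivity and specificity of hard predictions
#'
#' @param predictions Predicted labels.
#' @param labels True labels.
#' @param positive Positive-class label (default: last level of `labels`).
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(predictions, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  positive <- positive %||% levels(factor(labels))[nlevels(factor(labels))]
  p <- as.character(predictions) == as.character(positive)
  ok <- !is.na(p)
  tp <- sum(p & y & ok); fn <- sum(!p & y & ok)
  tn <- sum(!p & !y & ok); fp <- sum(p & !y & ok)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Youden-J-maximizing decision threshold
#'
#' Scans the observed scores for the threshold (predict positive when
#' `score >= threshold`) that maximizes sensitivity + specificity - 1; ties
#' resolve toward the smaller threshold.
#'
#' @inheritParams auc_roc
#' @return The chosen threshold.
#' @export
youden_threshold <- function(scores, labels, positive = NULL) {
  pos <- as_binary_labels(labels, positive)
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    sel <- scores >= t
    sum(sel & pos) / sum(pos) + sum(!sel & !pos) / sum(!pos) - 1
  }, numeric(1))
  thr[which.max(j)]
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples within each class (so both classes survive every draw), applies
#' `statistic(scores, labels)` to each resample, and reports the 2.5 / 97.5
#' percentiles. Resamples on which the statistic fails are dropped; failure
#' on more than half of them is an error.
#'
#' @param statistic Function of `(scores, labels)` returning one number.
#' @param scores,labels The observed sample.
#' @param n_boot Number of resamples (at least 100; default 2000).
#' @param seed RNG seed making the interval reproducible.
#' @return Named vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(statistic, scores, labels, n_boot = 2000L, seed = NULL) {
  if (n_boot < 100L) stop_tcf("n_boot must be >= 100", class = "tcf_spec_error")
  y <- factor(labels)
  strata <- split(seq_along(scores), y)
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(strata, function(s) sample(s, length(s), replace = TRUE)),
                    use.names = FALSE)
      tryCatch(statistic(scores[idx], y[idx]), error = function(e) NA_real_)
    }, numeric(1))
  })
  if (mean(is.na(vals)) > 0.5) {
    stop_tcf("statistic undefined on more than half of the resamples",
             class = "tcf_instability_error")
  }
  q <- stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Full evaluation report for one score set
#'
#' Computes MCC, sensitivity and specificity at the Youden-J operating point
#' (or from supplied hard predictions), plus AUC-ROC and AUC-PR with
#' stratified percentile-bootstrap 95% intervals.
#'
#' @inheritParams auc_roc
#' @param predictions Optional hard predictions; derived from the Youden
#'   threshold when absent.
#' @param n_boot Bootstrap resamples for the AUC intervals.
#' @param seed Bootstrap seed.
#' @return An `eval_report` list.
#' @export
eval_report <- function(scores, labels, predictions = NULL, positive = NULL,
                        n_boot = 2000L, seed = NULL) {
  y <- factor(labels)
  positive <- positive %||% levels(y)[nlevels(y)]
  pos <- as_binary_labels(y, positive)
  if (is.null(predictions)) {
    thr <- youden_threshold(scores, y, positive)
    predictions <- ifelse(scores >= thr, as.character(positive),
                          setdiff(levels(y), positive))
  } else {
    thr <- NA_real_
  }
  p <- as.character(predictions) == as.character(positive)
  tp <- sum(p & pos); fp <- sum(p & !pos)
  tn <- sum(!p & !pos); fn <- sum(!p & pos)
  structure(list(
    mcc = mcc(tp, fp, tn, fn),
    auc_roc = auc_roc(scores, y, positive),
    auc_roc_ci = bootstrap_ci(function(s, l) auc_roc(s, l, positive),
                              scores, y, n_boot, seed),
    auc_pr = auc_pr(scores, y, positive),
    auc_pr_ci = bootstrap_ci(function(s, l) auc_pr(s, l, positive),
                             scores, y, n_boot,
                             if (is.null(seed)) NULL else derive_seed(seed, 1)),
    sensitivity = unname(sens_spec(predictions, y, positive)["sensitivity"]),
    specificity = unname(sens_spec(predictions, y, positive)["specificity"]),
    threshold = thr,
    n_positive = sum(pos), n_negative = sum(!pos),
    positive = positive
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> positive = %s (n = %d vs %d)\n",
              x$positive, x$n_positive, x$n_negative))
  cat(sprintf("  MCC     %.3f\n", x$mcc))
  cat(sprintf("  AUC-ROC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc_roc, x$auc_roc_ci[1], x$auc_roc_ci[2]))
  cat(sprintf("  AUC-PR  %.3f (95%% CI %.3f-%.3f)\n",
              x$auc_pr, x$auc_pr_ci[1], x$auc_pr_ci[2]))
  cat(sprintf("  sens/spec at threshold: %.3f / %.3f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Metric-by-metric group comparison table
#'
#' Welch t-test, per-metric AUCs and MCC for each column of a two-group
#' feature matrix, mirroring the usual summary-table layout (group means with
#' SD, p-value, MCC, AUC-ROC, AUC-PR).
#'
#' @param features Numeric matrix, one row per lesion.
#' @param labels Binary group labels.
#' @param positive Group treated as positive for the AUCs.
#' @param n_boot,seed Bootstrap settings (CIs omitted when `n_boot = 0`).
#' @return Data frame, one row per feature column.
#' @export
compare_groups <- function(features, labels, positive = NULL,
                           n_boot = 0L, seed = NULL) {
  x <- as.matrix(features)
  y <- factor(labels)
  positive <- positive %||% levels(y)[nlevels(y)]
  pos <- as_binary_labels(y, positive)
  rows <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    ht <- two_sided_t_test(v[pos], v[!pos])
    # orient scores so the class with the larger mean ranks higher
    s <- if (mean(v[pos]) >= mean(v[!pos])) v else -v
    thr <- youden_threshold(s, y, positive)
    pr <- ifelse(s >= thr, as.character(positive), setdiff(levels(y), positive))
    ss <- sens_spec(pr, y, positive)
    tp <- sum(pr == positive & pos); fp <- sum(pr == positive & !pos)
    tn <- sum(pr != positive & !pos); fn <- sum(pr != positive & pos)
    data.frame(metric = colnames(x)[j] %||% paste0("V", j),
               mean_positive = mean(v[pos]), sd_positive = stats::sd(v[pos]),
               mean_negative = mean(v[!pos]), sd_negative = stats::sd(v[!pos]),
               p_value = ht$p, mcc = mcc(tp, fp, tn, fn),
               auc_roc = auc_roc(s, y, positive),
               auc_pr = auc_pr(s, y, positive),
               significant = ht$p < 0.05)
  })
  do.call(rbind, rows)
}
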