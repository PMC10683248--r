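#' Confusion matrix at a score threshold
#'
#' Predicted-positive means `score > t` (strictly), the same convention
#' used by the three-way stratification cutoffs. Rows with a missing
#' score are excluded from the counts and reported in the `missing`
#' attribute.
#'
#' @param scores numeric scores (may contain `NA` = unscored).
#' @param labels 0/1 labels aligned with `scores`.
#' @param t threshold.
#' @return Object of class `confusion_matrix`: list with `tp`, `tn`,
#'   `fp`, `fn` and attribute `missing`.
#' @export
confusion_at_threshold <- function(scores, labels, t = 0.5) {
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(labels)) stop("scores and labels must align")
  if (any(is.na(labels)) || !all(labels %in% c(0, 1))) stop("labels must be 0/1")
  scored <- !is.na(scores)
  s <- scores[scored]; y <- labels[scored]
  pred <- s > t
  cm <- confusion_matrix(tp = sum(pred & y == 1), tn = sum(!pred & y == 0),
                         fp = sum(pred & y == 0), fn = sum(!pred & y == 1))
  attr(cm, "missing") <- sum(!scored)
  cm
}

#' Construct a confusion matrix from counts
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("            predicted+  predicted-\n")
  cat(sprintf("pathogenic  %9d  %9d\n", x$tp, x$fn))
  cat(sprintf("benign      %9d  %9d\n", x$fp, x$tn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Standard definitions: precision (PPV) = TP/(TP+FP), NPV = TN/(TN+FN),
#' specificity = TN/(TN+FP), FPR = FP/(TN+FP), recall = TP/(TP+FN),
#' FNR = FN/(TP+FN), accuracy = (TP+TN)/total, F1 = 2PR/(P+R),
#' MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Rate metrics are returned as percentages; MCC and F1 on their natural
#' scales. Ratios with a zero denominator are `NA` (an explicit
#' undefined marker), never silently 0. Full precision is retained; the
#' print method rounds percentages to 2 decimals and MCC/F1 to 3.
#'
#' @param cm a `confusion_matrix`.
#' @return Object of class `metric_report` (fields `precision`, `npv`,
#'   `specificity`, `fpr`, `recall`, `fnr`, `accuracy` as percentages;
#'   `mcc`, `f1`).
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  total <- tp + tn + fp + fn
  if (total == 0) stop("all-zero confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(denom)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  structure(list(precision = 100 * precision,
                 npv = 100 * ratio(tn, tn + fn),
                 specificity = 100 * ratio(tn, tn + fp),
                 fpr = 100 * ratio(fp, tn + fp),
                 recall = 100 * recall,
                 fnr = 100 * ratio(fn, tp + fn),
                 accuracy = 100 * (tp + tn) / total,
                 mcc = mcc, f1 = f1),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v, d) ifelse(is.na(v), ".", formatC(v, format = "f", digits = d))
  for (f in c("precision", "npv", "specificity", "fpr", "recall", "fnr", "accuracy")) {
    cat(sprintf("  %-18s %s\n", paste0(f, " (%)"), fmt(x[[f]], 2)))
  }
  for (f in intersect(c("mcc", "auc", "f1", "average_precision"), names(x))) {
    cat(sprintf("  %-18s %s\n", f, fmt(x[[f]], 3)))
  }
  if (!is.null(x$missing)) cat(sprintf("  %-18s %d\n", "missing", x$missing))
  invisible(x)
}

# Threshold sweep shared by ROC and PR: distinct scores descending, with
# equal scores grouped into one step; a trailing -Inf step classifies
# everything positive.
sweep_counts <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  distinct <- !duplicated(s)
  cum_tp <- cumsum(y == 1)
  cum_fp <- cumsum(y == 0)
  last_of_group <- c(which(distinct)[-1] - 1L, length(s))
  list(thresholds = c(s[distinct], -Inf),
       cum_tp = cum_tp[last_of_group], cum_fp = cum_fp[last_of_group],
       n_pos = sum(y == 1), n_neg = sum(y == 0))
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps thresholds over the distinct scores (descending; ties grouped),
#' using the strict `score > t` rule, so the curve starts at (0,0) with
#' threshold `max(score)` and ends at (1,1) with threshold `-Inf`. AUC is
#' the trapezoidal area, equal to the normalised Mann-Whitney U
#' statistic with tied pairs counted half.
#'
#' @param scores numeric scores (`NA` rows are dropped).
#' @param labels 0/1 labels.
#' @return List with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(scores)
  s <- scores[keep]; y <- labels[keep]
  if (length(unique(y)) < 2L) stop("both classes must be present among scored rows")
  sw <- sweep_counts(s, y)
  # threshold = max(score) classifies nothing positive under the strict
  # rule -> (0,0); the trailing -Inf step classifies everything -> (1,1)
  tpr <- c(0, sw$cum_tp / sw$n_pos)
  fpr <- c(0, sw$cum_fp / sw$n_neg)
  curve <- data.frame(threshold = sw$thresholds, fpr = fpr, tpr = tpr)
  auc <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  list(curve = curve, auc = auc)
}

#' Precision-recall curve and average precision
#'
#' Average precision is the step-wise sum over the descending-score sweep
#' of `(R_k - R_{k-1}) * P_k`.
#'
#' @param scores numeric scores (`NA` rows dropped).
#' @param labels 0/1 labels.
#' @return List with `curve` (data.frame `threshold`, `recall`,
#'   `precision`) and `average_precision`.
#' @export
pr_average_precision <- function(scores, labels) {
  keep <- !is.na(scores)
  s <- scores[keep]; y <- labels[keep]
  if (sum(y == 1) == 0L) stop("at least one positive is required")
  sw <- sweep_counts(s, y)
  recall <- sw$cum_tp / sw$n_pos
  precision <- sw$cum_tp / (sw$cum_tp + sw$cum_fp)
  ap <- sum(diff(c(0, recall)) * precision)
  curve <- data.frame(threshold = sw$thresholds[seq_along(recall)],
                      recall = recall, precision = precision)
  list(curve = curve, average_precision = ap)
}

#' Optimal threshold by Youden's J
#'
#' Returns the sweep threshold maximising J = TPR - FPR; among ties the
#' smallest finite threshold is returned.
#'
#' @param roc output of [roc_auc()] (or an equivalent list with `curve`).
#' @return A single threshold.
#' @export
optimal_threshold <- function(roc) {
  curve <- roc$curve
  if (is.null(curve) || nrow(curve) < 2L) stop("degenerate ROC curve")
  j <- curve$tpr - curve$fpr
  best <- which(j > max(j) - 1e-12)
  cand <- curve$threshold[best]
  finite <- cand[is.finite(cand)]
  if (length(finite) > 0L) min(finite) else min(cand)
}

#' Full evaluation report: the twelve-metric panel
#'
#' Combines the confusion-derived metrics at a threshold with AUC,
#' average precision and the count of unscored rows. Metrics are
#' computed over scored rows only; unscored rows appear solely in
#' `missing` (the per-tool coverage convention).
#'
#' @param scores numeric scores (`NA` = unscored).
#' @param labels 0/1 labels.
#' @param threshold classification cutoff (default 0.5).
#' @return A `metric_report` with the additional fields `auc`,
#'   `average_precision` and `missing`.
#' @export
full_report <- function(scores, labels, threshold = 0.5) {
  cm <- confusion_at_threshold(scores, labels, threshold)
  rep <- metrics_from_confusion(cm)
  keep <- !is.na(scores)
  rep$auc <- roc_auc(scores[keep], labels[keep])$auc
  rep$average_precision <-
    pr_average_precision(scores[keep], labels[keep])$average_precision
  rep$missing <- attr(cm, "missing")
  rep
}

#' Three-way threshold stratification report
#'
#' Applies the recommended-cutoff policy: `Pr > pathogenic_cutoff` is
#' called pathogenic, `Pr < benign_cutoff` benign, everything in between
#' is indeterminate (VUS). Overall accuracy counts indeterminate calls
#' as incorrect; precision/recall/specificity/NPV are computed among the
#' classified rows only.
#'
#' @param scores numeric scores (scored rows only).
#' @param labels 0/1 labels.
#' @param pathogenic_cutoff lower probability bound for a pathogenic
#'   call (default 0.75).
#' @param benign_cutoff upper probability bound for a benign call
#'   (default 0.15).
#' @return Object of class `stratified_report` with percentage fields
#'   `overall_accuracy`, `proportion_classified`,
#'   `accuracy_of_recommended`, `proportion_indeterminate`, `recall`,
#'   `precision`, `specificity`, `npv`.
#' @export
stratified_report <- function(scores, labels, pathogenic_cutoff = 0.75,
                              benign_cutoff = 0.15) {
  if (length(scores) == 0L) stop("empty input")
  if (!(benign_cutoff >= 0 && benign_cutoff < pathogenic_cutoff &&
        pathogenic_cutoff <= 1)) {
    stop("cutoffs must satisfy 0 <= benign < pathogenic <= 1")
  }
  if (any(is.na(scores))) stop("stratification expects scored rows only")
  call <- ifelse(scores > pathogenic_cutoff, "pathogenic",
                 ifelse(scores < benign_cutoff, "benign", "vus"))
  n <- length(scores)
  classified <- call != "vus"
  correct <- (call == "pathogenic" & labels == 1) | (call == "benign" & labels == 0)
  tp <- sum(call == "pathogenic" & labels == 1)
  fp <- sum(call == "pathogenic" & labels == 0)
  tn <- sum(call == "benign" & labels == 0)
  fn <- sum(call == "benign" & labels == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(
    overall_accuracy = 100 * sum(correct) / n,
    proportion_classified = 100 * sum(classified) / n,
    accuracy_of_recommended = ratio(sum(correct), sum(classified)),
    proportion_indeterminate = 100 * sum(!classified) / n,
    recall = ratio(tp, tp + fn),
    precision = ratio(tp, tp + fp),
    specificity = ratio(tn, tn + fp),
    npv = ratio(tn, tn + fn),
    pathogenic_cutoff = pathogenic_cutoff,
    benign_cutoff = benign_cutoff),
    class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), ".", formatC(v, format = "f", digits = 2))
  cat("Stratified classification (pathogenic: Pr >", x$pathogenic_cutoff,
      "; benign: Pr <", x$benign_cutoff, ")\n")
  fields <- c(overall_accuracy = "Overall accuracy (%)",
              proportion_classified = "Classified with recommended (%)",
              accuracy_of_recommended = "Accuracy of recommended (%)",
              proportion_indeterminate = "Indeterminate (VUS) (%)",
              recall = "Recall (%)", precision = "Precision (%)",
              specificity = "Specificity (%)", npv = "NPV (%)")
  for (f in names(fields)) {
    cat(sprintf("  %-34s %s\n", fields[[f]], fmt(x[[f]])))
  }
  invisible(x)
}

#' Long-format score distribution with per-class error rates
#'
#' Produces the table behind a violin/strip plot of score distributions
#' per label class, plus per-class misclassification rates at the given
#' threshold (benign misclassified when score > t, pathogenic when
#' score <= t).
#'
#' @param scores numeric scores (scored rows).
#' @param labels 0/1 labels.
#' @param threshold cutoff (default 0.5).
#' @return List with `table` (data.frame `class`, `score`) and `rates`
#'   (named vector `benign`, `pathogenic`, percentages).
#' @export
score_distribution_export <- function(scores, labels, threshold = 0.5) {
  keep <- !is.na(scores)
  s <- scores[keep]; y <- labels[keep]
  tab <- data.frame(class = ifelse(y == 1, "pathogenic", "benign"),
                    score = s, stringsAsFactors = FALSE)
  benign_rate <- if (any(y == 0)) 100 * mean(s[y == 0] > threshold) else NA_real_
  path_rate <- if (any(y == 1)) 100 * mean(s[y == 1] <= threshold) else NA_real_
  list(table = tab,
       rates = c(benign = benign_rate, pathogenic = path_rate))
}
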