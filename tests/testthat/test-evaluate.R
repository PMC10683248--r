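test_that("confusion counting uses the strict score > t rule and tracks missing", {
  cm <- confusion_at_threshold(c(0.9, 0.4), c(1, 0), 0.5)
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]), c(tp = 1, tn = 1, fp = 0, fn = 0))
  # score exactly at the threshold is predicted negative
  cm <- confusion_at_threshold(c(0.5, 0.5), c(1, 0), 0.5)
  expect_equal(cm$fn, 1); expect_equal(cm$tn, 1)
  # brute-force oracle over random scored rows
  set.seed(5)
  for (i in 1:5) {
    s <- runif(20); y <- rbinom(20, 1, 0.5); t <- runif(1)
    cm <- confusion_at_threshold(s, y, t)
    expect_equal(cm$tp, sum(s > t & y == 1))
    expect_equal(cm$tn, sum(s <= t & y == 0))
    expect_equal(cm$fp, sum(s > t & y == 0))
    expect_equal(cm$fn, sum(s <= t & y == 1))
  }
  s <- c(0.9, NA, 0.1); y <- c(1, 1, 0)
  cm <- confusion_at_threshold(s, y, 0.5)
  expect_equal(attr(cm, "missing"), 1)
  expect_error(confusion_at_threshold(numeric(0), numeric(0)), "empty")
  expect_error(confusion_at_threshold(0.5, 2), "0/1")
})

test_that("metric formulas agree with an independently coded implementation", {
  alt_metrics <- function(tp, tn, fp, fn) {
    # deliberately different formulation via prevalence/rates
    n <- tp + tn + fp + fn
    list(precision = 100 * tp / (tp + fp), npv = 100 * tn / (tn + fn),
         specificity = 100 * (1 - fp / (tn + fp)), fpr = 100 * fp / (tn + fp),
         recall = 100 * (1 - fn / (tp + fn)), fnr = 100 * fn / (tp + fn),
         accuracy = 100 * (1 - (fp + fn) / n),
         mcc = (tp / n * tn / n - fp / n * fn / n) /
           sqrt((tp + fp) / n * (tp + fn) / n * (tn + fp) / n * (tn + fn) / n) / n * n,
         f1 = tp / (tp + (fp + fn) / 2))
  }
  set.seed(11)
  for (i in 1:20) {
    counts <- rpois(4, 50) + 1
    got <- metrics_from_confusion(confusion_matrix(counts[1], counts[2], counts[3], counts[4]))
    want <- alt_metrics(counts[1], counts[2], counts[3], counts[4])
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12, info = f)
    }
  }
})

test_that("degenerate confusion matrices give perfect scores or undefined markers", {
  perfect <- metrics_from_confusion(confusion_matrix(10, 10, 0, 0))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$recall, 100)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)
  # no predicted positives: precision undefined, not 0
  none_pos <- metrics_from_confusion(confusion_matrix(0, 5, 0, 5))
  expect_true(is.na(none_pos$precision))
  expect_true(is.na(none_pos$mcc))
  expect_error(metrics_from_confusion(confusion_matrix(0, 0, 0, 0)), "all-zero")
})

test_that("complement identities hold exactly", {
  set.seed(3)
  for (i in 1:10) {
    counts <- rpois(4, 30) + 1
    m <- metrics_from_confusion(confusion_matrix(counts[1], counts[2], counts[3], counts[4]))
    expect_equal(m$fpr + m$specificity, 100)
    expect_equal(m$fnr + m$recall, 100)
  }
})

test_that("trapezoidal AUC equals the normalised Mann-Whitney statistic", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  set.seed(21)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y)$auc, brute_auc(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("ROC curves span (0,0) to (1,1) with strictly decreasing thresholds", {
  set.seed(8)
  s <- runif(25); y <- rbinom(25, 1, 0.5)
  curve <- roc_auc(s, y)$curve
  expect_equal(c(curve$fpr[1], curve$tpr[1]), c(0, 0))
  expect_equal(c(curve$fpr[nrow(curve)], curve$tpr[nrow(curve)]), c(1, 1))
  expect_true(all(diff(curve$threshold) < 0))
})

test_that("average precision matches a brute-force descending sweep", {
  brute_ap <- function(s, y) {
    ord <- order(s, decreasing = TRUE)
    s <- s[ord]; y <- y[ord]
    ap <- 0; last_r <- 0
    for (t in unique(s)) {
      sel <- s >= t
      p <- sum(y[sel]) / sum(sel)
      r <- sum(y[sel]) / sum(y)
      ap <- ap + (r - last_r) * p
      last_r <- r
    }
    ap
  }
  expect_equal(pr_average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$average_precision, 1)
  # all-identical scores collapse to the prevalence
  expect_equal(pr_average_precision(rep(0.3, 10), c(rep(1, 3), rep(0, 7)))$average_precision, 0.3)
  set.seed(13)
  for (i in 1:10) {
    s <- round(runif(20), 2); y <- rbinom(20, 1, 0.4)
    if (sum(y) == 0) next
    expect_equal(pr_average_precision(s, y)$average_precision, brute_ap(s, y),
                 tolerance = 1e-12)
  }
  expect_error(pr_average_precision(runif(4), rep(0, 4)), "positive")
})

test_that("Youden threshold selection matches exhaustive search", {
  # separable: smallest score-derived threshold achieving J = 1
  roc <- roc_auc(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(optimal_threshold(roc), 0.2)
  # identical scores: J = 0 everywhere, smallest finite threshold returned
  roc_flat <- roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(optimal_threshold(roc_flat), 0.4)
  set.seed(17)
  for (i in 1:10) {
    s <- round(runif(12), 1); y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) next
    t_star <- optimal_threshold(roc_auc(s, y))
    j_of <- function(t) {
      mean(s[y == 1] > t) - mean(s[y == 0] > t)
    }
    j_all <- vapply(sort(unique(s)), j_of, numeric(1))
    expect_equal(j_of(t_star), max(j_all), tolerance = 1e-12)
  }
})

test_that("the full report composes its component operations and counts missing", {
  set.seed(31)
  s <- runif(10); y <- rbinom(10, 1, 0.5); y[1:2] <- c(1, 0)
  s[c(3, 7)] <- NA
  rep <- full_report(s, y, 0.5)
  expect_equal(rep$missing, 2)
  keep <- !is.na(s)
  cm <- confusion_at_threshold(s[keep], y[keep], 0.5)
  part <- metrics_from_confusion(cm)
  expect_equal(rep$accuracy, part$accuracy)
  expect_equal(rep$auc, roc_auc(s[keep], y[keep])$auc)
  expect_equal(rep$average_precision,
               pr_average_precision(s[keep], y[keep])$average_precision)
  expect_equal(full_report(runif(10), c(1, 0, rbinom(8, 1, 0.5)))$missing, 0)
})

test_that("three-way stratification obeys its accounting identities", {
  sr <- stratified_report(c(0.9, 0.05, 0.5), c(1, 0, 1))
  expect_equal(sr$proportion_classified, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(sr$accuracy_of_recommended, 100)
  expect_equal(sr$overall_accuracy, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(sr$proportion_indeterminate, 100 / 3, tolerance = 1e-9)
  # proportions always sum to 100 over random seeded score sets
  set.seed(41)
  for (i in 1:100) {
    s <- runif(sample(5:50, 1)); y <- rbinom(length(s), 1, 0.5)
    sr <- stratified_report(s, y)
    expect_equal(sr$proportion_classified + sr$proportion_indeterminate, 100,
                 tolerance = 1e-9)
  }
  # everything inside the VUS band: nothing classified, accuracy undefined
  sr <- stratified_report(c(0.2, 0.5, 0.7), c(1, 0, 1))
  expect_equal(sr$proportion_classified, 0)
  expect_true(is.na(sr$accuracy_of_recommended))
  expect_error(stratified_report(numeric(0), numeric(0)), "empty")
  expect_error(stratified_report(0.5, 1, pathogenic_cutoff = 0.1, benign_cutoff = 0.2),
               "cutoffs")
})

test_that("a degenerate policy collapses stratification to the binary report", {
  set.seed(43)
  s <- runif(40); y <- rbinom(40, 1, 0.5)
  eps <- 1e-9
  sr <- stratified_report(s, y, pathogenic_cutoff = 0.5, benign_cutoff = 0.5 - eps)
  cm <- confusion_at_threshold(s, y, 0.5)
  acc <- metrics_from_confusion(cm)$accuracy
  expect_equal(sr$overall_accuracy, acc, tolerance = 1e-6)
  expect_equal(sr$proportion_classified, 100)
})

test_that("score distribution export matches the confusion matrix identities", {
  s <- c(0.1, 0.6, 0.9, 0.4); y <- c(0, 0, 1, 1)
  out <- score_distribution_export(s, y, 0.5)
  expect_equal(nrow(out$table), 4)
  expect_equal(out$rates[["benign"]], 50)      # one of two benign above t
  expect_equal(out$rates[["pathogenic"]], 50)  # one of two pathogenic at/below t
  cm <- confusion_at_threshold(s, y, 0.5)
  expect_equal(out$rates[["benign"]], 100 * cm$fp / (cm$fp + cm$tn))
  expect_equal(out$rates[["pathogenic"]], 100 * cm$fn / (cm$fn + cm$tp))
  all_right <- score_distribution_export(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(unname(all_right$rates), c(0, 0))
})

test_that("metrics are invariant under row permutation", {
  set.seed(47)
  s <- runif(30); y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  perm <- sample(30)
  expect_equal(full_report(s, y, 0.4), full_report(s[perm], y[perm], 0.4))
  expect_equal(unclass(stratified_report(s, y)),
               unclass(stratified_report(s[perm], y[perm])))
})
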