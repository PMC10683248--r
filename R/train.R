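#' Fit the final pathogenicity scorer
#'
#' Fits the full scoring pipeline on a labelled feature matrix: KNN
#' imputation and min-max normalisation are fitted on the entire provided
#' matrix, then the classifier is trained on the transformed values. For
#' logistic regression (the default and the family behind the shipped
#' scorer) the per-feature coefficients are exposed; their absolute
#' values serve as feature importances.
#'
#' @param fm labelled `feature_matrix` (1 = pathogenic, 0 = benign).
#' @param algorithm classifier family (default `"logistic_regression"`).
#' @param hyperparameters named list of family hyperparameters (e.g.
#'   `lambda` for logistic regression).
#' @param k_impute neighbour count for imputation (default 5).
#' @param threshold default binary classification cutoff (default 0.5).
#' @param seed RNG seed used by stochastic families.
#' @return Object of class `variant_scorer`.
#' @export
fit_scorer <- function(fm, algorithm = "logistic_regression",
                       hyperparameters = list(), k_impute = 5,
                       threshold = 0.5, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("labels are required to fit a scorer")
  if (length(unique(fm$labels)) < 2L) {
    stop("degenerate labels: both classes must be present")
  }
  if (!algorithm %in% ALGORITHM_FAMILIES) stop("unknown algorithm family: ", algorithm)
  imp <- fit_impute(fm, k = min(k_impute, nrow(fm$x) - 1))
  nrm <- fit_normalize(imp$completed)
  model <- train_candidate(algorithm, nrm$normalized$x, fm$labels,
                           hyperparameters, seed = seed)
  structure(list(algorithm = algorithm,
                 model = model,
                 coefficients = if (algorithm == "logistic_regression")
                   model$fit$coefficients else NULL,
                 intercept = if (algorithm == "logistic_regression")
                   model$fit$intercept else NULL,
                 feature_names = colnames(fm$x),
                 imputer = imp$imputer,
                 normalizer = nrm$normalizer,
                 hyperparameters = hyperparameters,
                 threshold = threshold,
                 seed = seed),
            class = "variant_scorer")
}

#' Predict pathogenicity probabilities
#'
#' Applies the fitted imputation and normalisation state, then the
#' classifier; returns the pathogenicity probability Pr in `[0, 1]` per
#' row, in input order.
#'
#' @param object a `variant_scorer`.
#' @param newdata a `feature_matrix` or numeric matrix whose columns match
#'   the model's `feature_names`.
#' @param ... unused.
#' @return Numeric vector of probabilities.
#' @export
predict.variant_scorer <- function(object, newdata, ...) {
  if (!inherits(newdata, "feature_matrix")) newdata <- feature_matrix(newdata)
  have <- colnames(newdata$x)
  want <- object$feature_names
  if (!identical(have, want)) {
    if (setequal(have, want)) {
      newdata <- feature_matrix(newdata$x[, want, drop = FALSE], newdata$labels)
    } else {
      stop("feature mismatch; missing: ",
           paste(setdiff(want, have), collapse = ", "),
           "; unexpected: ", paste(setdiff(have, want), collapse = ", "))
    }
  }
  x <- normalize_transform(object$normalizer,
                           impute_transform(object$imputer, newdata))$x
  unname(score_candidate(object$model, x))
}

#' Coefficients of a fitted logistic scorer
#'
#' `scale = "normalized"` returns the coefficients on the min-max-scaled
#' feature scale (as fitted); `scale = "raw"` rescales them back to the
#' original feature units, so they are comparable with a generative model
#' on raw features.
#'
#' @param object a `variant_scorer` fitted with logistic regression.
#' @param scale `"normalized"` or `"raw"`.
#' @param ... unused.
#' @return Named vector of slopes with attribute `intercept`.
#' @export
coef.variant_scorer <- function(object, scale = c("normalized", "raw"), ...) {
  if (object$algorithm != "logistic_regression") {
    stop("coefficients are only defined for logistic_regression scorers")
  }
  scale <- match.arg(scale)
  w <- object$coefficients
  b <- object$intercept
  if (scale == "raw") {
    s <- object$normalizer$scale
    m <- object$normalizer$min
    b <- b - sum(w * m / s)
    w <- w / s
  }
  attr(w, "intercept") <- b
  w
}

#' Rank features by coefficient magnitude
#'
#' Features are ordered by decreasing absolute logistic coefficient;
#' magnitude ties are broken alphabetically by feature name.
#'
#' @param model a logistic-regression `variant_scorer`.
#' @return data.frame with columns `feature`, `weight`, `importance`
#'   (the absolute weight), sorted by decreasing importance.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "variant_scorer"))
  if (model$algorithm != "logistic_regression") {
    stop("feature importance via |coefficient| requires a logistic_regression scorer")
  }
  w <- model$coefficients
  out <- data.frame(feature = names(w), weight = unname(w),
                    importance = abs(unname(w)), stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.variant_scorer <- function(x, ...) {
  cat("Pathogenicity scorer (", x$algorithm, "), ",
      length(x$feature_names), " features, threshold ", x$threshold, "\n", sep = "")
  if (!is.null(x$coefficients)) {
    top <- utils::head(feature_importance(x), 5)
    cat("Top features by |coefficient|:\n")
    cat(sprintf("  %-24s %8.3f\n", top$feature, top$weight), sep = "")
  }
  invisible(x)
}

#' @export
summary.variant_scorer <- function(object, ...) {
  cat("Pathogenicity scorer\n")
  cat("  algorithm:      ", object$algorithm, "\n")
  cat("  features:       ", length(object$feature_names), "\n")
  cat("  imputation:     k =", object$imputer$k, "(nan-Euclidean KNN)\n")
  cat("  normalisation:   min-max to [0,1];",
      sum(object$normalizer$constant), "constant feature(s)\n")
  cat("  threshold:      ", object$threshold, "\n")
  if (!is.null(object$coefficients)) {
    cat("  intercept:      ", round(object$intercept, 4), "\n")
    print(utils::head(feature_importance(object), 10))
  }
  invisible(object)
}

#' @export
plot.variant_scorer <- function(x, n = 20, ...) {
  imp <- utils::head(feature_importance(x), n)
  graphics::barplot(rev(imp$importance), names.arg = rev(imp$feature),
                    horiz = TRUE, las = 1, xlab = "|coefficient|",
                    main = "Feature importance", ...)
  invisible(x)
}

inner_grid_search <- function(cand, x, y, inner_k, k_impute, seed) {
  grid_points <- expand_grid_list(cand$grid)
  if (length(grid_points) == 1L) return(grid_points[[1]])
  fold <- stratified_folds(y, inner_k, seed)
  acc <- vapply(grid_points, function(params) {
    fold_acc <- vapply(seq_len(inner_k), function(f) {
      tr <- fold != f; te <- fold == f
      pp <- fit_pipeline_xy(x[tr, , drop = FALSE], x[te, , drop = FALSE], k_impute)
      model <- train_candidate(cand$name, pp$train, y[tr], params, seed = seed)
      mean((score_candidate(model, pp$test) > 0.5) == (y[te] == 1))
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  grid_points[[which.max(acc)]]
}

#' Select a classifier family by nested cross-validation
#'
#' For each candidate family, hyperparameters are tuned by an inner
#' stratified cross-validation (default fivefold) on each outer-training
#' fold, the tuned model is refitted on the outer-training fold and
#' scored on the outer held-out fold (default tenfold). Imputation and
#' normalisation are refitted inside every fold on its training rows
#' only, so no held-out information leaks into preprocessing.
#'
#' @param fm labelled `feature_matrix`.
#' @param candidates named list of `candidate_algorithm` objects
#'   (default [default_candidates()]).
#' @param inner_k inner folds (default 5).
#' @param outer_k outer folds (default 10).
#' @param k_impute imputation neighbour count (default 5).
#' @param seed fold-assignment and model seed.
#' @return Object of class `cv_report`: per-candidate best
#'   hyperparameters, outer-fold accuracies with mean and standard
#'   deviation, pooled outer-fold Accuracy/Precision/AUC/F1/Recall/MCC,
#'   and per-fold preprocessing state for audit.
#' @export
nested_cv_select <- function(fm, candidates = default_candidates(),
                             inner_k = 5, outer_k = 10, k_impute = 5,
                             seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("labels are required for cross-validation")
  for (cand in candidates) stopifnot(inherits(cand, "candidate_algorithm"))
  y <- fm$labels
  x <- fm$x
  fold <- stratified_folds(y, outer_k, seed)
  results <- list()
  for (cand in candidates) {
    fold_acc <- numeric(outer_k)
    chosen <- vector("list", outer_k)
    details <- vector("list", outer_k)
    pooled_scores <- numeric(0)
    pooled_labels <- integer(0)
    for (f in seq_len(outer_k)) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) {
        stop("stratification error: a class is absent from outer fold ", f)
      }
      params <- inner_grid_search(cand, x[tr, , drop = FALSE], y[tr],
                                  inner_k, k_impute, seed + f)
      pp <- fit_pipeline_xy(x[tr, , drop = FALSE], x[te, , drop = FALSE], k_impute)
      model <- train_candidate(cand$name, pp$train, y[tr], params, seed = seed + f)
      scores <- score_candidate(model, pp$test)
      fold_acc[[f]] <- mean((scores > 0.5) == (y[te] == 1))
      chosen[[f]] <- params
      details[[f]] <- list(test_idx = which(te),
                           normalizer = pp$normalizer,
                           imputer_k = pp$imputer$k)
      pooled_scores <- c(pooled_scores, scores)
      pooled_labels <- c(pooled_labels, y[te])
    }
    cm <- confusion_at_threshold(pooled_scores, pooled_labels, 0.5)
    met <- metrics_from_confusion(cm)
    auc <- roc_auc(pooled_scores, pooled_labels)$auc
    param_keys <- vapply(chosen, function(p) paste(deparse(p), collapse = ""), character(1))
    best <- chosen[[match(names(sort(table(param_keys), decreasing = TRUE))[1], param_keys)]]
    results[[cand$name]] <- list(
      best_hyperparameters = best,
      outer_fold_accuracies = fold_acc,
      mean_accuracy = mean(fold_acc),
      sd_accuracy = stats::sd(fold_acc),
      metrics = list(accuracy = met$accuracy, precision = met$precision,
                     auc = auc, f1 = met$f1, recall = met$recall, mcc = met$mcc),
      per_fold_hyperparameters = chosen,
      outer_details = details)
  }
  structure(list(candidates = results, outer_k = outer_k, inner_k = inner_k,
                 seed = seed, n = nrow(x)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Nested cross-validation (outer ", x$outer_k, ", inner ", x$inner_k,
      ", n = ", x$n, ")\n", sep = "")
  cat(sprintf("%-20s %9s %10s %6s %7s %8s %6s\n",
              "family", "acc(%)", "prec(%)", "AUC", "F1", "recall(%)", "MCC"))
  for (name in names(x$candidates)) {
    m <- x$candidates[[name]]$metrics
    cat(sprintf("%-20s %9.2f %10.2f %6.3f %7.3f %8.2f %6.3f\n",
                name, m$accuracy, m$precision, m$auc, m$f1, m$recall, m$mcc))
  }
  for (name in names(x$candidates)) {
    r <- x$candidates[[name]]
    cat(sprintf("%-20s outer mean accuracy: %.3f +/- %.3f\n",
                name, r$mean_accuracy, r$sd_accuracy))
  }
  invisible(x)
}

#' Learning-curve diagnostics
#'
#' For each requested training-set size, a stratified subsample of each
#' cross-validation training split is fitted (full pipeline) and scored
#' on its own subsample and on the held-out fold; means and standard
#' deviations across folds are reported. Used to check that the scorer
#' neither underfits nor would benefit materially from more data.
#'
#' @param fm labelled `feature_matrix`.
#' @param algorithm classifier family.
#' @param hyperparameters named list for the family.
#' @param sizes strictly increasing training sizes.
#' @param cv_k folds (default 5).
#' @param k_impute imputation neighbours.
#' @param seed RNG seed.
#' @return Object of class `learning_curve_result` with `training_sizes`,
#'   `train_mean`, `train_sd`, `validation_mean`, `validation_sd`.
#' @export
learning_curve <- function(fm, algorithm = "logistic_regression",
                           hyperparameters = list(), sizes, cv_k = 5,
                           k_impute = 5, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("labels required")
  if (anyDuplicated(sizes) || is.unsorted(sizes, strictly = TRUE)) {
    stop("sizes must be strictly increasing with no duplicates")
  }
  y <- fm$labels
  if (min(sizes) < 2 * length(unique(y))) stop("smallest size is too small to stratify")
  if (max(sizes) > nrow(fm$x) - ceiling(nrow(fm$x) / cv_k)) {
    stop("largest size exceeds available training rows after the CV split")
  }
  fold <- stratified_folds(y, cv_k, seed)
  train_scores <- matrix(NA_real_, length(sizes), cv_k)
  val_scores <- matrix(NA_real_, length(sizes), cv_k)
  for (f in seq_len(cv_k)) {
    tr_idx <- which(fold != f); te_idx <- which(fold == f)
    for (s in seq_along(sizes)) {
      size <- sizes[[s]]
      set.seed(seed + 1000 * f + s)
      # stratified subsample of the training split
      sub <- unlist(lapply(unique(y), function(cls) {
        cls_idx <- tr_idx[y[tr_idx] == cls]
        n_cls <- max(1L, round(size * length(cls_idx) / length(tr_idx)))
        sample(cls_idx, min(n_cls, length(cls_idx)))
      }))
      pp <- fit_pipeline_xy(fm$x[sub, , drop = FALSE],
                            fm$x[te_idx, , drop = FALSE], k_impute)
      model <- train_candidate(algorithm, pp$train, y[sub], hyperparameters,
                               seed = seed + f)
      train_scores[s, f] <- mean((score_candidate(model, pp$train) > 0.5) == (y[sub] == 1))
      val_scores[s, f] <- mean((score_candidate(model, pp$test) > 0.5) == (y[te_idx] == 1))
    }
  }
  structure(list(training_sizes = sizes,
                 train_mean = rowMeans(train_scores),
                 train_sd = apply(train_scores, 1, stats::sd),
                 validation_mean = rowMeans(val_scores),
                 validation_sd = apply(val_scores, 1, stats::sd)),
            class = "learning_curve_result")
}

#' @export
print.learning_curve_result <- function(x, ...) {
  cat("Learning curve\n")
  cat(sprintf("%8s %14s %18s\n", "size", "train acc", "validation acc"))
  for (i in seq_along(x$training_sizes)) {
    cat(sprintf("%8d %8.3f +/- %.3f %10.3f +/- %.3f\n", x$training_sizes[[i]],
                x$train_mean[[i]], x$train_sd[[i]],
                x$validation_mean[[i]], x$validation_sd[[i]]))
  }
  invisible(x)
}

#' Persist a logistic scorer as JSON
#'
#' Stores the coefficients, intercept, feature list, fitted imputation
#' reference and normalisation parameters, threshold and seed; the file
#' is library-agnostic and sufficient to reproduce predictions exactly.
#'
#' @param model a logistic-regression `variant_scorer`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_scorer <- function(model, path) {
  stopifnot(inherits(model, "variant_scorer"))
  if (model$algorithm != "logistic_regression") {
    stop("only logistic_regression scorers are persisted as JSON")
  }
  payload <- list(
    format = "mitomiss_scorer_v1",
    algorithm = model$algorithm,
    feature_names = model$feature_names,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    imputer = list(k = model$imputer$k, distance = model$imputer$distance,
                   reference = apply(model$imputer$reference, 1, as.list)),
    normalizer = list(min = as.list(model$normalizer$min),
                      scale = as.list(model$normalizer$scale),
                      constant = as.list(model$normalizer$constant)),
    threshold = model$threshold,
    seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a scorer persisted with [write_scorer()]
#'
#' @param path JSON path.
#' @return A `variant_scorer`.
#' @export
read_scorer <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "mitomiss_scorer_v1")) stop("unrecognised scorer file")
  fn <- p$feature_names
  ref <- t(vapply(seq_len(nrow(p$imputer$reference)),
                  function(i) as.numeric(p$imputer$reference[i, fn]),
                  numeric(length(fn))))
  colnames(ref) <- fn
  coefs <- stats::setNames(as.numeric(p$coefficients[fn]), fn)
  imputer <- structure(list(k = p$imputer$k, reference = ref,
                            distance = p$imputer$distance), class = "knn_imputer")
  normalizer <- structure(list(min = stats::setNames(as.numeric(p$normalizer$min[fn]), fn),
                               scale = stats::setNames(as.numeric(p$normalizer$scale[fn]), fn),
                               constant = stats::setNames(as.logical(p$normalizer$constant[fn]), fn)),
                          class = "minmax_normalizer")
  structure(list(algorithm = p$algorithm,
                 model = list(kind = "logistic_regression",
                              fit = list(coefficients = coefs, intercept = p$intercept)),
                 coefficients = coefs, intercept = p$intercept,
                 feature_names = fn, imputer = imputer, normalizer = normalizer,
                 hyperparameters = list(), threshold = p$threshold, seed = p$seed),
            class = "variant_scorer")
}
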