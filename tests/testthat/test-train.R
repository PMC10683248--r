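test_that("prediction is the sigmoid of the linear score on preprocessed inputs", {
  # hand-built scorer: w = 0, b = 0 -> every score 0.5; w = 1, x = 1 -> sigmoid(1)
  x <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, "f1"))
  fm <- feature_matrix(x, labels = c(0, 1))
  m <- fit_scorer(fm, hyperparameters = list(lambda = 1))
  m$coefficients <- c(f1 = 0); m$intercept <- 0
  m$model$fit$coefficients <- m$coefficients; m$model$fit$intercept <- 0
  expect_equal(predict(m, fm), c(0.5, 0.5))
  m$coefficients <- c(f1 = 1)
  m$model$fit$coefficients <- m$coefficients
  # normalized x is (0, 1) here, so the second score is sigmoid(1)
  expect_equal(predict(m, fm)[2], 1 / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("logistic fit agrees with the glm oracle at vanishing penalty", {
  set.seed(2)
  x <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rbinom(200, 1, plogis(x %*% c(1, -0.5, 0)))
  fit <- mitomiss:::logistic_irls(x, y, lambda = 1e-10)
  g <- glm(y ~ x, family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(g)[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(coef(g)[1]), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("coefficients recover the generative truth as n grows", {
  truth <- synthetic_truth(c(f1 = 2, f2 = -1, f3 = 0), seed = 20)
  fm_small <- gen_labeled_dataset(500, truth)
  m_small <- fit_scorer(fm_small, hyperparameters = list(lambda = 1e-4))
  err_small <- abs(coef(m_small, scale = "raw") - truth$coefficients)
  expect_true(all(err_small < 0.6))  # wide bound at n = 500

  truth_big <- synthetic_truth(c(f1 = 2, f2 = -1, f3 = 0), seed = 21)
  fm_big <- gen_labeled_dataset(5000, truth_big)
  m_big <- fit_scorer(fm_big, hyperparameters = list(lambda = 1e-4))
  err_big <- abs(coef(m_big, scale = "raw") - truth_big$coefficients)
  expect_true(all(err_big < 0.15))  # tight bound attainable only at the larger n
})

test_that("refitting on identical data is deterministic and degenerate inputs error", {
  fm <- separable_dataset(60, seed = 5)
  m1 <- fit_scorer(fm, seed = 3)
  m2 <- fit_scorer(fm, seed = 3)
  expect_identical(coef(m1), coef(m2))
  # all-constant features collapse to an intercept-only fit at the prevalence
  x0 <- matrix(0, 40, 2, dimnames = list(NULL, c("a", "b")))
  y0 <- rep(c(1, 0), c(10, 30))
  m0 <- fit_scorer(feature_matrix(x0, labels = y0))
  expect_equal(unname(coef(m0)), c(0, 0), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(predict(m0, feature_matrix(x0))[1], 0.25, tolerance = 1e-3)
  expect_error(fit_scorer(feature_matrix(x0, labels = rep(1, 40))), "degenerate")
  expect_error(fit_scorer(feature_matrix(x0)), "labels")
})

test_that("prediction validates and aligns columns by name", {
  fm <- separable_dataset(60, seed = 6)
  m <- fit_scorer(fm)
  p <- predict(m, fm)
  # column permutation with names is realigned, not misread
  swapped <- feature_matrix(fm$x[, c("f2", "f1")], fm$labels)
  expect_equal(predict(m, swapped), p)
  # row order is respected
  expect_equal(predict(m, feature_matrix(fm$x[10:1, ])), p[10:1])
  bad <- feature_matrix(matrix(0, 2, 2, dimnames = list(NULL, c("f1", "zz"))))
  expect_error(predict(m, bad), "zz")
})

test_that("positively weighted features move scores monotonically", {
  fm <- separable_dataset(100, seed = 8)
  m <- fit_scorer(fm)
  w <- coef(m)
  set.seed(9)
  for (i in 1:20) {
    row <- matrix(rnorm(2), 1, dimnames = list(NULL, c("f1", "f2")))
    up <- row
    j <- sample(1:2, 1)
    up[1, j] <- up[1, j] + abs(rnorm(1))
    delta <- predict(m, feature_matrix(up)) - predict(m, feature_matrix(row))
    expect_true(sign(delta) == sign(w[[j]]) || delta == 0)
  }
})

test_that("feature importance ranks by |coefficient| with alphabetical tie-break", {
  fm <- separable_dataset(60, seed = 10)
  m <- fit_scorer(fm)
  m$coefficients <- c(f1 = 0.89, f2 = -0.63, f3 = 0.01)
  imp <- feature_importance(m)
  expect_equal(imp$feature, c("f1", "f2", "f3"))
  expect_equal(imp$importance, c(0.89, 0.63, 0.01))
  m$coefficients <- c(zeta = 0.5, alpha = -0.5, mid = 0.5)
  expect_equal(feature_importance(m)$feature, c("alpha", "mid", "zeta"))
  m$coefficients <- c(only = 2)
  expect_equal(nrow(feature_importance(m)), 1)
  m_rf <- fit_scorer(separable_dataset(40, seed = 2), algorithm = "random_forest",
                     hyperparameters = list(ntree = 20))
  expect_error(feature_importance(m_rf), "logistic_regression")
  expect_error(coef(m_rf), "logistic_regression")
})

test_that("nested CV reports per-candidate outer-fold aggregates with sane structure", {
  fm <- separable_dataset(90, seed = 12)
  cands <- list(logistic_regression =
                  candidate_algorithm("logistic_regression", list(lambda = 0.001)))
  cv <- nested_cv_select(fm, cands, inner_k = 3, outer_k = 4, seed = 2)
  r <- cv$candidates$logistic_regression
  expect_length(r$outer_fold_accuracies, 4)
  expect_equal(r$mean_accuracy, mean(r$outer_fold_accuracies))
  expect_equal(r$sd_accuracy, sd(r$outer_fold_accuracies))
  # outer folds partition the rows
  idx <- sort(unlist(lapply(r$outer_details, `[[`, "test_idx")))
  expect_equal(idx, 1:90)
  expect_true(r$metrics$auc >= 0 && r$metrics$auc <= 1)
  expect_true(r$metrics$mcc >= -1 && r$metrics$mcc <= 1)
  expect_true(r$metrics$accuracy >= 0 && r$metrics$accuracy <= 100)
  expect_error(candidate_algorithm("logistic_regression", list()), "empty")
  expect_error(nested_cv_select(feature_matrix(fm$x), cands), "labels")
})

test_that("every candidate family separates two well-separated clouds", {
  fm <- separable_dataset(200, seed = 14)
  cands <- default_candidates()
  # trim the grids so each family fits once per fold
  for (nm in names(cands)) cands[[nm]]$grid <- lapply(cands[[nm]]$grid, `[`, 1)
  cv <- nested_cv_select(fm, cands, inner_k = 3, outer_k = 3, seed = 4)
  for (nm in names(cands)) {
    expect_gte(cv$candidates[[nm]]$mean_accuracy, 0.95)
  }
})

test_that("permuted labels bring logistic accuracy to chance", {
  fm <- separable_dataset(200, seed = 16)
  set.seed(17)
  fm_null <- feature_matrix(fm$x, labels = sample(fm$labels))
  cands <- list(logistic_regression =
                  candidate_algorithm("logistic_regression", list(lambda = 0.001)))
  cv <- nested_cv_select(fm_null, cands, inner_k = 3, outer_k = 5, seed = 18)
  expect_lt(abs(cv$candidates$logistic_regression$mean_accuracy - 0.5), 0.10)
})

test_that("preprocessing inside nested CV never sees held-out rows", {
  set.seed(19)
  n <- 300
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("f1", "f2", "sentinel")))
  y <- rbinom(n, 1, plogis(x[, 1]))
  y[1:2] <- c(0, 1)
  fm <- feature_matrix(x, labels = y)
  cands <- list(logistic_regression =
                  candidate_algorithm("logistic_regression", list(lambda = 0.001)))
  cv <- nested_cv_select(fm, cands, inner_k = 3, outer_k = 3, seed = 20)
  for (fold in cv$candidates$logistic_regression$outer_details) {
    train_idx <- setdiff(seq_len(n), fold$test_idx)
    # normaliser parameters are exactly the training-fold extrema, so the
    # held-out rows (whatever their values) cannot have influenced them
    expect_equal(fold$normalizer$min[["sentinel"]], min(x[train_idx, "sentinel"]))
    expect_equal(fold$normalizer$scale[["sentinel"]],
                 max(x[train_idx, "sentinel"]) - min(x[train_idx, "sentinel"]))
  }
})

test_that("learning curves improve on separable data and validate sizes", {
  fm <- separable_dataset(150, seed = 22)
  lc <- learning_curve(fm, sizes = c(10, 40, 100), cv_k = 3, seed = 23)
  expect_length(lc$train_mean, 3)
  expect_gte(lc$validation_mean[3] + 0.05, lc$validation_mean[1])  # non-decreasing within noise
  gap_first <- abs(lc$train_mean[1] - lc$validation_mean[1])
  gap_last <- abs(lc$train_mean[3] - lc$validation_mean[3])
  expect_lte(gap_last, gap_first + 0.05)
  single <- learning_curve(fm, sizes = 50, cv_k = 3, seed = 24)
  expect_length(single$validation_mean, 1)
  expect_error(learning_curve(fm, sizes = c(20, 20), cv_k = 3), "strictly increasing")
  expect_error(learning_curve(fm, sizes = 3, cv_k = 3), "too small")
  expect_error(learning_curve(fm, sizes = c(10, 149), cv_k = 3), "exceeds")
})

test_that("a persisted scorer reproduces predictions exactly", {
  truth <- synthetic_truth(c(f1 = 1.5, f2 = -0.7), missingness_rate = 0.1, seed = 26)
  fm <- gen_labeled_dataset(80, truth)
  m <- fit_scorer(fm)
  path <- tempfile(fileext = ".json")
  write_scorer(m, path)
  m2 <- read_scorer(path)
  expect_equal(predict(m2, fm), predict(m, fm), tolerance = 1e-12)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  m_rf <- fit_scorer(separable_dataset(40, seed = 1), algorithm = "random_forest",
                     hyperparameters = list(ntree = 10))
  expect_error(write_scorer(m_rf, path), "logistic_regression")
})
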