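ALGORITHM_FAMILIES <- c("adaboost", "decision_tree", "random_forest",
                        "logistic_regression", "kneighbors", "svm")

#' Penalised logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with an L2 (ridge) penalty on the
#' slopes; the intercept is unpenalised. Newton/IRLS with convergence
#' tolerance `tol` on the step size.
#'
#' @param x numeric design matrix (no intercept column).
#' @param y 0/1 response.
#' @param lambda L2 penalty weight (default 1e-3; near-MLE).
#' @param tol convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @return List with `coefficients` (named), `intercept`, `converged`,
#'   `iterations`.
#' @keywords internal
logistic_irls <- function(x, y, lambda = 1e-3, tol = 1e-6, max_iter = 1000) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  X1 <- cbind(`(Intercept)` = 1, x)
  beta <- numeric(p + 1)
  pen <- c(0, rep(lambda, p))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X1, y - mu)) - pen * beta
    H <- crossprod(X1, X1 * w) + diag(pen + 1e-12, p + 1)
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-6, p + 1), grad)
    })
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  list(coefficients = stats::setNames(beta[-1], colnames(x)),
       intercept = beta[[1]], converged = converged, iterations = iter)
}

# ---- discrete AdaBoost over decision stumps (two-class SAMME) ----
# No boosting package ships the classic stump AdaBoost, so it is
# implemented directly; rpart supplies the weighted weak learner.
adaboost_fit <- function(x, y, n_trees = 50, maxdepth = 1) {
  dat <- data.frame(.y = factor(y, levels = c(0, 1)), x, check.names = FALSE)
  n <- nrow(dat)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_trees)
  alphas <- numeric(n_trees)
  ysign <- ifelse(y == 1, 1, -1)
  m_used <- 0L
  for (m in seq_len(n_trees)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- ifelse(stats::predict(fit, dat, type = "class") == "1", 1, -1)
    err <- sum(w[pred != ysign])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * ysign * pred)
    w <- w / sum(w)
    m_used <- m
    stumps[[m]] <- fit
    alphas[[m]] <- alpha
    if (err < 1e-9) break
  }
  structure(list(stumps = stumps[seq_len(m_used)], alphas = alphas[seq_len(m_used)],
                 feature_names = colnames(x)),
            class = "adaboost_model")
}

adaboost_score <- function(model, x) {
  dat <- data.frame(x, check.names = FALSE)
  f <- numeric(nrow(dat))
  for (m in seq_along(model$stumps)) {
    pred <- ifelse(stats::predict(model$stumps[[m]], dat, type = "class") == "1", 1, -1)
    f <- f + model$alphas[[m]] * pred
  }
  # Friedman's link between the boosted margin and class probability
  stats::plogis(2 * f)
}

# ---- unified candidate interface ----
train_candidate <- function(name, x, y, params, seed = 1) {
  set.seed(seed)
  yf <- factor(y, levels = c(0, 1))
  switch(name,
    logistic_regression = {
      fit <- logistic_irls(x, y, lambda = params$lambda %||% 1e-3)
      list(kind = name, fit = fit)
    },
    decision_tree = {
      dat <- data.frame(.y = yf, x, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = dat, method = "class",
                          control = rpart::rpart.control(
                            cp = params$cp %||% 0.01,
                            maxdepth = params$maxdepth %||% 30, xval = 0))
      list(kind = name, fit = fit)
    },
    random_forest = {
      fit <- randomForest::randomForest(x, yf, ntree = params$ntree %||% 200)
      list(kind = name, fit = fit)
    },
    kneighbors = {
      list(kind = name, train_x = x, train_y = y, k = params$k %||% 5)
    },
    svm = {
      fit <- e1071::svm(x, yf, kernel = params$kernel %||% "radial",
                        cost = params$cost %||% 1, probability = TRUE)
      list(kind = name, fit = fit)
    },
    adaboost = {
      fit <- adaboost_fit(x, y, n_trees = params$n_trees %||% 50)
      list(kind = name, fit = fit)
    },
    stop("unknown algorithm family: ", name)
  )
}

score_candidate <- function(model, x) {
  switch(model$kind,
    logistic_regression = {
      stats::plogis(model$fit$intercept + drop(x %*% model$fit$coefficients))
    },
    decision_tree = {
      stats::predict(model$fit, data.frame(x, check.names = FALSE), type = "prob")[, "1"]
    },
    random_forest = {
      stats::predict(model$fit, x, type = "prob")[, "1"]
    },
    kneighbors = {
      pred <- class::knn(model$train_x, x, factor(model$train_y, levels = c(0, 1)),
                         k = model$k, prob = TRUE, use.all = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    svm = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    adaboost = adaboost_score(model$fit, x),
    stop("unknown model kind")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Candidate algorithm with a hyperparameter grid
#'
#' @param name one of `adaboost`, `decision_tree`, `random_forest`,
#'   `logistic_regression`, `kneighbors`, `svm`.
#' @param grid named list: parameter name -> vector of values to try.
#' @return Object of class `candidate_algorithm`.
#' @export
candidate_algorithm <- function(name, grid) {
  if (!name %in% ALGORITHM_FAMILIES) stop("unknown algorithm family: ", name)
  if (length(grid) == 0L || any(lengths(grid) == 0L)) stop("hyperparameter grid is empty")
  structure(list(name = name, grid = grid), class = "candidate_algorithm")
}

#' Default candidate set: the six classifier families
#'
#' Small documented grids; all are config-replaceable.
#'
#' @return Named list of `candidate_algorithm` objects.
#' @export
default_candidates <- function() {
  list(
    adaboost = candidate_algorithm("adaboost", list(n_trees = c(30, 60))),
    decision_tree = candidate_algorithm("decision_tree", list(cp = c(0.001, 0.01))),
    random_forest = candidate_algorithm("random_forest", list(ntree = c(100, 200))),
    logistic_regression = candidate_algorithm("logistic_regression",
                                              list(lambda = 10^c(-3, -1, 1))),
    kneighbors = candidate_algorithm("kneighbors", list(k = c(5, 11))),
    svm = candidate_algorithm("svm", list(cost = c(0.1, 1)))
  )
}

expand_grid_list <- function(grid) {
  df <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    if (length(idx) < k) {
      stop("stratification error: class ", cls, " has ", length(idx),
           " rows, fewer than ", k, " folds")
    }
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Fit imputer + normaliser on training rows only, returning transformed
# train/test matrices and the fitted preprocessing state.
fit_pipeline_xy <- function(x_train, x_test, k_impute) {
  imp <- fit_impute(feature_matrix(x_train), k = min(k_impute, nrow(x_train) - 1))
  nrm <- fit_normalize(imp$completed)
  test_fm <- normalize_transform(nrm$normalizer,
                                 impute_transform(imp$imputer, feature_matrix(x_test)))
  list(train = nrm$normalized$x, test = test_fm$x,
       imputer = imp$imputer, normalizer = nrm$normalizer)
}
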