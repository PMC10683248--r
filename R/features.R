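#' Construct a feature matrix
#'
#' A feature matrix is the model-ready view of a variant set: rows are
#' variants, columns are numeric features (booleans encoded 0/1), `NA`
#' marks missing values, and an optional binary label vector
#' (1 = pathogenic, 0 = benign) aligns with the rows.
#'
#' @param x numeric matrix (may contain `NA`); column names required.
#' @param labels optional 0/1 vector, one per row.
#' @return Object of class `feature_matrix` with elements `x` and `labels`.
#' @export
feature_matrix <- function(x, labels = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) stop("feature matrix needs column names")
  if (!is.null(labels)) {
    if (length(labels) != nrow(x)) stop("labels must align with rows")
    if (any(is.na(labels)) || !all(labels %in% c(0, 1))) {
      stop("labels must be 0/1 with no missing values")
    }
    labels <- as.integer(labels)
  }
  structure(list(x = x, labels = labels), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$x), "variants x", ncol(x$x), "features;",
      sum(is.na(x$x)), "missing cells")
  if (!is.null(x$labels)) {
    cat(";", sum(x$labels == 1), "pathogenic /", sum(x$labels == 0), "benign")
  }
  cat("\n")
  invisible(x)
}

#' Build a feature matrix from annotated variants
#'
#' Selects the requested features, in the given order, from an annotated
#' variant table and encodes them numerically: booleans as 0/1, integers
#' and continuous values as doubles, missing annotations as `NA`.
#'
#' @param annotated an `annotated_variants` table.
#' @param feature_names ordered character vector of schema field names.
#' @param labels optional 0/1 vector per row.
#' @return A `feature_matrix`.
#' @export
build_feature_matrix <- function(annotated, feature_names, labels = NULL) {
  schema <- attr(annotated, "schema")
  stopifnot(!is.null(schema))
  absent <- setdiff(feature_names, schema$fields$name)
  if (length(absent) > 0L) {
    stop("feature(s) absent from schema: ", paste(absent, collapse = ", "))
  }
  if (anyDuplicated(feature_names)) stop("duplicate feature names")
  x <- vapply(feature_names, function(f) as.numeric(annotated[[f]]),
              numeric(nrow(annotated)))
  if (nrow(annotated) == 1L) x <- matrix(x, nrow = 1, dimnames = list(NULL, feature_names))
  rownames(x) <- variant_id(annotated)
  feature_matrix(x, labels = labels)
}

#' Drop every feature in one schema category
#'
#' Used to build the reduced feature set that excludes
#' mitochondria-specific annotations; remaining column order is preserved.
#'
#' @param fm a `feature_matrix`.
#' @param schema the `annotation_schema` the features came from.
#' @param drop_category category token whose fields are removed.
#' @return A `feature_matrix` with the remaining columns.
#' @export
subset_features <- function(fm, schema, drop_category) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(schema, "annotation_schema"))
  if (!drop_category %in% ANNOTATION_CATEGORIES) {
    stop("unknown category: ", drop_category)
  }
  dropped <- schema$fields$name[schema$fields$category == drop_category]
  keep <- setdiff(colnames(fm$x), dropped)
  feature_matrix(fm$x[, keep, drop = FALSE], labels = fm$labels)
}

# Pairwise distance between one (possibly incomplete) row and reference rows:
# Euclidean over mutually observed features, rescaled by
# sqrt(p_total / p_observed) — the standard incomplete-data KNN convention.
nan_euclidean <- function(row, ref) {
  p <- length(row)
  obs_row <- !is.na(row)
  apply(ref, 1, function(r) {
    both <- obs_row & !is.na(r)
    n_obs <- sum(both)
    if (n_obs == 0L) return(Inf)
    d2 <- sum((row[both] - r[both])^2)
    sqrt(d2 * p / n_obs)
  })
}

# Mean of `values` over the k nearest rows by `dists`, restricted to rows
# where the value is observed; distance ties at the k-th neighbour enlarge
# the averaging set (deterministic, row-order independent).
knn_cell_mean <- function(dists, values, k) {
  usable <- which(!is.na(values) & is.finite(dists))
  if (length(usable) == 0L) return(NA_real_)
  d <- dists[usable]
  if (length(usable) <= k) return(mean(values[usable]))
  kth <- sort(d, partial = k)[k]
  sel <- usable[d <= kth + 1e-12]
  mean(values[sel])
}

#' Fit a K-nearest-neighbour imputer
#'
#' Replaces each missing cell by the unweighted mean of that feature over
#' the k nearest rows. Distances are Euclidean over mutually observed
#' features, rescaled by the proportion of observed features; neighbour
#' candidates are rows where the target feature is observed, and distance
#' ties at the k-th neighbour are all included. The completed training
#' matrix is stored as the reference for transforming new rows.
#'
#' @param fm a `feature_matrix` (training data).
#' @param k neighbour count (default 5).
#' @return List with `imputer` (class `knn_imputer`) and `completed`
#'   (the training `feature_matrix` with no missing cells).
#' @export
fit_impute <- function(fm, k = 5) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$x
  if (k < 1) stop("k must be >= 1")
  if (nrow(x) < k + 1) stop("need at least k+1 = ", k + 1, " rows, have ", nrow(x))
  all_missing <- colnames(x)[colSums(!is.na(x)) == 0L]
  if (length(all_missing) > 0L) {
    stop("column(s) entirely missing: ", paste(all_missing, collapse = ", "))
  }
  completed <- x
  miss_idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(miss_idx) > 0L) {
    for (i in unique(miss_idx[, 1])) {
      dists <- nan_euclidean(x[i, ], x[-i, , drop = FALSE])
      cols <- miss_idx[miss_idx[, 1] == i, 2]
      for (j in cols) {
        completed[i, j] <- knn_cell_mean(dists, x[-i, j], k)
      }
    }
  }
  imputer <- structure(list(k = k, reference = completed, distance = "nan_euclidean"),
                       class = "knn_imputer")
  list(imputer = imputer, completed = feature_matrix(completed, labels = fm$labels))
}

#' Impute new rows with a fitted imputer
#'
#' Missing cells in new rows are filled from the stored (complete)
#' training reference; fully observed rows pass through unchanged.
#'
#' @param imputer a `knn_imputer` from [fit_impute()].
#' @param fm a `feature_matrix` with the same columns.
#' @return A `feature_matrix` with no missing cells.
#' @export
impute_transform <- function(imputer, fm) {
  stopifnot(inherits(imputer, "knn_imputer"), inherits(fm, "feature_matrix"))
  if (!identical(colnames(fm$x), colnames(imputer$reference))) {
    stop("column mismatch between imputer and new data")
  }
  x <- fm$x
  ref <- imputer$reference
  for (i in which(rowSums(is.na(x)) > 0L)) {
    dists <- nan_euclidean(x[i, ], ref)
    for (j in which(is.na(x[i, ]))) {
      x[i, j] <- knn_cell_mean(dists, ref[, j], imputer$k)
    }
  }
  feature_matrix(x, labels = fm$labels)
}

#' Fit a min-max normaliser
#'
#' Scales each feature to `[0, 1]` using the training minimum and range.
#' Constant features get scale 1 (so they map to 0) and are flagged.
#' Transforming new data reuses the stored training parameters, so values
#' outside the training range fall outside `[0, 1]`.
#'
#' @param fm a complete (no missing) `feature_matrix`.
#' @return List with `normalizer` (class `minmax_normalizer`) and
#'   `normalized` (the scaled training `feature_matrix`).
#' @export
fit_normalize <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$x
  if (anyNA(x)) stop("normalisation requires a complete matrix; impute first")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  scale <- maxs - mins
  constant <- scale == 0
  scale[constant] <- 1
  normalizer <- structure(list(min = mins, scale = scale, constant = constant),
                          class = "minmax_normalizer")
  list(normalizer = normalizer, normalized = normalize_transform(normalizer, fm))
}

#' Apply a fitted min-max normaliser
#'
#' @param normalizer a `minmax_normalizer`.
#' @param fm a complete `feature_matrix` with matching columns.
#' @return The scaled `feature_matrix`.
#' @export
normalize_transform <- function(normalizer, fm) {
  stopifnot(inherits(normalizer, "minmax_normalizer"), inherits(fm, "feature_matrix"))
  if (!identical(colnames(fm$x), names(normalizer$min))) {
    stop("column mismatch between normalizer and data")
  }
  if (anyNA(fm$x)) stop("normalisation requires a complete matrix; impute first")
  x <- sweep(sweep(fm$x, 2, normalizer$min, "-"), 2, normalizer$scale, "/")
  feature_matrix(x, labels = fm$labels)
}
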