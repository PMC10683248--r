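# Shared fixture builders for the suite. Everything is generated in code;
# no data files are read from disk except those the tests themselves write
# to tempdir().

toy_schema <- function() {
  annotation_schema(data.frame(
    name = c("sift", "af_gnomad", "mito_flag", "tx_length", "expr_heart"),
    category = c("predictor_score", "allele_frequency", "mito_specific",
                 "basic", "tissue_expression"),
    dtype = c("continuous", "continuous", "boolean", "integer", "continuous"),
    level = c("variant", "variant", "gene", "transcript", "gene"),
    source = "synthetic", stringsAsFactors = FALSE))
}

toy_registry <- function(seed = 42) gen_registry(c(1, 1, 1), seed = seed)

# Schema with a configurable number of fields per category; used to build
# the 115/85-feature panel shape.
sized_schema <- function(counts) {
  stopifnot(identical(sort(names(counts)), sort(mitomiss:::ANNOTATION_CATEGORIES)) ||
              all(names(counts) %in% mitomiss:::ANNOTATION_CATEGORIES))
  rows <- do.call(rbind, lapply(names(counts), function(cat) {
    n <- counts[[cat]]
    if (n == 0) return(NULL)
    data.frame(name = sprintf("%s_%02d", cat, seq_len(n)), category = cat,
               dtype = "continuous", level = "variant", source = "synthetic",
               stringsAsFactors = FALSE)
  }))
  annotation_schema(rows)
}

# Brute-force interval scan: the oracle for filter_to_panel.
brute_panel_filter <- function(variants, registry) {
  rec <- registry$records
  out <- NULL
  for (i in seq_len(nrow(variants))) {
    for (g in seq_len(nrow(rec))) {
      if (variants$chromosome[[i]] == rec$chromosome[[g]] &&
          variants$position[[i]] >= rec$start[[g]] &&
          variants$position[[i]] <= rec$end[[g]]) {
        out <- rbind(out, cbind(variants[i, , drop = FALSE], gene = rec$symbol[[g]]))
      }
    }
  }
  if (is.null(out)) return(cbind(variants[0, , drop = FALSE], gene = character(0)))
  rownames(out) <- NULL
  out
}

# Brute-force incomplete-data KNN imputation with the same tie-inclusive
# convention, written as plain loops over all rows.
brute_knn_impute <- function(x, k) {
  filled <- x
  p <- ncol(x)
  for (i in seq_len(nrow(x))) {
    miss <- which(is.na(x[i, ]))
    if (length(miss) == 0) next
    d <- rep(Inf, nrow(x))
    for (r in seq_len(nrow(x))) {
      if (r == i) next
      both <- which(!is.na(x[i, ]) & !is.na(x[r, ]))
      if (length(both) == 0) next
      d[r] <- sqrt(sum((x[i, both] - x[r, both])^2) * p / length(both))
    }
    for (j in miss) {
      cand <- which(!is.na(x[, j]) & is.finite(d))
      if (length(cand) == 0) { filled[i, j] <- NA; next }
      if (length(cand) <= k) { filled[i, j] <- mean(x[cand, j]); next }
      dd <- sort(d[cand])
      kth <- dd[k]
      sel <- cand[d[cand] <= kth + 1e-12]
      filled[i, j] <- mean(x[sel, j])
    }
  }
  filled
}

# Pair-counting AUC oracle (normalised Mann-Whitney with ties half-counted).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

separable_dataset <- function(n = 200, seed = 1) {
  set.seed(seed)
  n1 <- n %/% 2
  x <- rbind(matrix(rnorm(n1 * 2, mean = 4), ncol = 2),
             matrix(rnorm((n - n1) * 2, mean = -4), ncol = 2))
  colnames(x) <- c("f1", "f2")
  feature_matrix(x, labels = c(rep(1, n1), rep(0, n - n1)))
}
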