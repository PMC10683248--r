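#' Remove common variants by allele frequency
#'
#' The standard exome-triage filter: variants with minor allele frequency
#' above the cutoff are removed as common/benign; a missing frequency is
#' treated as rare and the variant is kept.
#'
#' @param variants data.frame with a `maf` column (`NA` = unknown).
#' @param maf_cutoff frequency cutoff (default 0.01).
#' @return The filtered data.frame.
#' @export
frequency_filter <- function(variants, maf_cutoff = 0.01) {
  if (maf_cutoff < 0) stop("maf_cutoff must be non-negative")
  keep <- is.na(variants$maf) | variants$maf <= maf_cutoff
  out <- variants[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("all variants removed by the frequency filter")
  rownames(out) <- NULL
  out
}

#' Spike one causative variant into a background exome
#'
#' @param background data.frame of background variants with a
#'   `variant_id` column (none flagged causative).
#' @param causative one-row data.frame for the causative variant.
#' @return data.frame of size `nrow(background) + 1` with a logical
#'   `causative` column that is `TRUE` for exactly one row.
#' @export
spike <- function(background, causative) {
  if (nrow(causative) != 1L) stop("exactly one causative variant must be supplied")
  if (causative$variant_id %in% background$variant_id) {
    stop("causative variant id already present in the background exome: ",
         causative$variant_id)
  }
  cols <- union(names(background), names(causative))
  pad <- function(df) {
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
    df[, cols, drop = FALSE]
  }
  out <- rbind(pad(background), pad(causative))
  out$causative <- c(rep(FALSE, nrow(background)), TRUE)
  rownames(out) <- NULL
  out
}

#' Percentage of an exome called pathogenic
#'
#' `100 * #(score > threshold) / #scored`; variants with a missing score
#' are excluded from the denominator and counted in the `n_missing`
#' attribute.
#'
#' @param scores per-variant scores for one exome (`NA` = unscored).
#' @param threshold the tool's recommended cutoff.
#' @return Percentage in `[0, 100]` with attribute `n_missing`.
#' @export
percent_pathogenic <- function(scores, threshold) {
  scored <- !is.na(scores)
  if (!any(scored)) stop("no scored variants in the exome")
  out <- 100 * sum(scores[scored] > threshold) / sum(scored)
  attr(out, "n_missing") <- sum(!scored)
  out
}

#' Rank of the causative variant in an exome
#'
#' Variants are ranked by descending score; ties are handled
#' pessimistically: the causative variant is placed after every
#' non-causative variant sharing its score, so the reported rank is
#' conservative.
#'
#' @param scores per-variant scores.
#' @param causative logical flag, `TRUE` for exactly one variant.
#' @return Integer rank (1 = top of the candidate list).
#' @export
causative_rank <- function(scores, causative) {
  if (sum(causative) != 1L) stop("exactly one variant must be flagged causative")
  cs <- scores[causative]
  if (is.na(cs)) stop("causative variant is unscored and cannot be ranked")
  others <- scores[!causative]
  others <- others[!is.na(others)]
  1L + sum(others > cs) + sum(others == cs)
}

#' Summarise causative-variant ranks across exomes
#'
#' @param ranks integer ranks, one per simulated exome.
#' @return Object of class `rank_summary`: `ranks`, `mean`, `sd` (sample,
#'   n-1 denominator; `NA` for a single exome), `median` (mean of middle
#'   two for even counts).
#' @export
summarize_ranks <- function(ranks) {
  if (length(ranks) == 0L) stop("no ranks to summarise")
  structure(list(ranks = ranks,
                 mean = mean(ranks),
                 sd = if (length(ranks) > 1L) stats::sd(ranks) else NA_real_,
                 median = stats::median(ranks)),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  sd_txt <- if (is.na(x$sd)) "." else formatC(x$sd, format = "f", digits = 3)
  cat(sprintf("Causative-variant rank over %d exomes: %.3f +/- %s (median: %s)\n",
              length(x$ranks), x$mean, sd_txt, format(x$median)))
  invisible(x)
}

#' Mann-Whitney rank-sum comparison of two rank lists
#'
#' U for group a counts pairs where a's value exceeds b's, with ties
#' counted half. The two-sided p-value is computed by exhaustive
#' enumeration of all group assignments when `n_a * n_b <= 200`
#' (exact even under ties), and otherwise by the tie-corrected normal
#' approximation (no continuity correction).
#'
#' @param ranks_a,ranks_b numeric vectors (any values; typically ranks).
#' @return List with `u_a`, `u_b`, `p_value`, `method`.
#' @export
rank_sum_test <- function(ranks_a, ranks_b) {
  if (length(ranks_a) == 0L || length(ranks_b) == 0L) stop("both groups must be non-empty")
  na <- length(ranks_a); nb <- length(ranks_b)
  u_of <- function(a, b) {
    sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b), numeric(1)))
  }
  u_a <- u_of(ranks_a, ranks_b)
  u_b <- na * nb - u_a
  if (na * nb <= 200) {
    pooled <- c(ranks_a, ranks_b)
    combos <- utils::combn(na + nb, na)
    mu <- na * nb / 2
    us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
    p <- mean(abs(us - mu) >= abs(u_a - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    pooled <- c(ranks_a, ranks_b)
    n <- na + nb
    ties <- table(pooled)
    mu <- na * nb / 2
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_a - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation (tie-corrected)"
  }
  list(u_a = u_a, u_b = u_b, p_value = min(p, 1), method = method)
}

#' Benchmark scoring tools on spiked exomes
#'
#' Runs the simulated-Mendelian-exome protocol: each background exome is
#' frequency-filtered, one causative variant is spiked in, and for every
#' tool the candidate-list size (percent of scored variants called
#' pathogenic at the tool's recommended threshold) and the causative
#' variant's rank are recorded.
#'
#' @param exomes data.frame of background variants with columns
#'   `exome_id`, `variant_id`, `maf`, plus one score column per tool.
#' @param causatives data.frame with `exome_id`, `variant_id` and the
#'   same score columns; one row per exome.
#' @param thresholds named numeric vector: tool -> recommended cutoff.
#' @param maf_cutoff frequency cutoff applied to backgrounds (default 0.01).
#' @return data.frame with one row per exome x tool: `exome_id`, `tool`,
#'   `percent_pathogenic`, `causative_rank`, `n_variants`.
#' @export
benchmark_exomes <- function(exomes, causatives, thresholds, maf_cutoff = 0.01) {
  tools <- names(thresholds)
  missing_cols <- setdiff(tools, names(exomes))
  if (length(missing_cols) > 0L) {
    stop("score column(s) absent from exome table: ",
         paste(missing_cols, collapse = ", "))
  }
  rows <- list()
  for (eid in unique(exomes$exome_id)) {
    bg <- frequency_filter(exomes[exomes$exome_id == eid, , drop = FALSE], maf_cutoff)
    hit <- causatives[causatives$exome_id == eid, , drop = FALSE]
    if (nrow(hit) != 1L) stop("need exactly one causative variant for exome ", eid)
    ex <- spike(bg, hit)
    for (tool in tools) {
      scores <- ex[[tool]]
      rows[[length(rows) + 1L]] <- data.frame(
        exome_id = eid, tool = tool,
        percent_pathogenic = as.numeric(percent_pathogenic(scores, thresholds[[tool]])),
        causative_rank = causative_rank(scores, ex$causative),
        n_variants = nrow(ex), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
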