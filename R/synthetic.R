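#' Ground truth for the synthetic labelled generator
#'
#' Describes the logistic generative model the labelled fixtures are
#' drawn from: labels are Bernoulli(sigmoid(intercept + w . x)), with
#' completely-at-random missingness applied afterwards.
#'
#' @param coefficients named numeric vector of true per-feature weights.
#' @param intercept true intercept (default 0).
#' @param missingness_rate per-cell missing probability in `[0, 1)`.
#' @param seed RNG seed recorded alongside every generated output.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(coefficients, intercept = 0,
                            missingness_rate = 0, seed = 1) {
  if (missingness_rate < 0 || missingness_rate >= 1) {
    stop("missingness_rate must be in [0, 1)")
  }
  if (is.null(names(coefficients))) {
    names(coefficients) <- paste0("f", seq_along(coefficients))
  }
  structure(list(coefficients = coefficients, intercept = intercept,
                 missingness_rate = missingness_rate, seed = seed),
            class = "synthetic_truth")
}

#' Generate a synthetic gene registry
#'
#' Builds a panel-shaped registry: the requested number of genes per
#' category, non-overlapping intervals on synthetic contigs
#' (mt-protein-coding genes on `chrM`, nuclear genes spread over
#' `chr1`..`chr22`), 1-5 transcripts per gene with one marked MANE.
#' Optional exact per-category transcript totals let tests reproduce a
#' published registry shape.
#'
#' @param n_per_category integer triple: genes in `mt_protein_coding`,
#'   `disease_nuclear`, `mito_localized_nuclear`.
#' @param seed RNG seed.
#' @param transcripts_per_category optional integer triple of exact
#'   transcript totals (each >= its gene count).
#' @return A `gene_registry`.
#' @export
gen_registry <- function(n_per_category, seed = 1,
                         transcripts_per_category = NULL) {
  stopifnot(length(n_per_category) == 3L, all(n_per_category >= 0))
  set.seed(seed)
  total <- sum(n_per_category)
  if (total == 0L) {
    return(gene_registry(data.frame(symbol = character(), chromosome = character(),
                                    start = integer(), end = integer(),
                                    strand = character(), category = character(),
                                    mane_transcript = character(),
                                    all_transcripts = I(list()))))
  }
  category <- rep(GENE_CATEGORIES, times = n_per_category)
  chromosome <- character(total)
  chromosome[category == "mt_protein_coding"] <- "chrM"
  n_nuc <- sum(category != "mt_protein_coding")
  if (n_nuc > 0L) {
    chromosome[category != "mt_protein_coding"] <-
      paste0("chr", sample(1:22, n_nuc, replace = TRUE))
  }
  # sequential placement per contig keeps intervals non-overlapping
  start <- integer(total); end <- integer(total)
  for (contig in unique(chromosome)) {
    idx <- which(chromosome == contig)
    widths <- sample(500:5000, length(idx), replace = TRUE)
    gaps <- sample(100:1000, length(idx), replace = TRUE)
    s <- cumsum(gaps + c(0, utils::head(widths, -1)))
    start[idx] <- s
    end[idx] <- s + widths - 1L
  }
  n_tx <- integer(total)
  for (ci in seq_along(GENE_CATEGORIES)) {
    idx <- which(category == GENE_CATEGORIES[[ci]])
    if (length(idx) == 0L) next
    if (is.null(transcripts_per_category)) {
      n_tx[idx] <- sample(1:5, length(idx), replace = TRUE)
    } else {
      tot_tx <- transcripts_per_category[[ci]]
      if (tot_tx < length(idx)) stop("transcript total below gene count")
      extra <- tot_tx - length(idx)
      add <- if (extra > 0)
        tabulate(sample(length(idx), extra, replace = TRUE), nbins = length(idx))
      else rep(0L, length(idx))
      n_tx[idx] <- 1L + add
    }
  }
  symbol <- sprintf("GENE%04d", seq_len(total))
  all_transcripts <- lapply(seq_len(total), function(i) {
    sprintf("%s-tx%d", symbol[[i]], seq_len(n_tx[[i]]))
  })
  mane <- vapply(seq_len(total), function(i) {
    sample(all_transcripts[[i]], 1)
  }, character(1))
  gene_registry(data.frame(symbol = symbol, chromosome = chromosome,
                           start = start, end = end,
                           strand = sample(c("+", "-"), total, replace = TRUE),
                           category = category, mane_transcript = mane,
                           all_transcripts = I(all_transcripts),
                           stringsAsFactors = FALSE))
}

#' Generate a labelled feature matrix from a known logistic model
#'
#' Feature marginals by dtype: continuous ~ N(0,1), boolean ~
#' Bernoulli(0.5) encoded 0/1, integer ~ uniform over 0..5. Labels are
#' drawn Bernoulli(sigmoid(intercept + w . x)) from the complete
#' features, then missingness is applied completely at random.
#'
#' @param n number of rows (>= 10).
#' @param truth a `synthetic_truth`; the coefficient names define the
#'   feature set.
#' @param dtypes optional character vector (per feature) from
#'   `c("continuous", "boolean", "integer")`; default all continuous.
#' @return A labelled `feature_matrix` with attribute `truth`.
#' @export
gen_labeled_dataset <- function(n, truth, dtypes = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n < 10) stop("n must be at least 10")
  w <- truth$coefficients
  p <- length(w)
  if (is.null(dtypes)) dtypes <- rep("continuous", p)
  stopifnot(length(dtypes) == p)
  set.seed(truth$seed)
  x <- matrix(NA_real_, n, p, dimnames = list(NULL, names(w)))
  for (j in seq_len(p)) {
    x[, j] <- switch(dtypes[[j]],
                     continuous = stats::rnorm(n),
                     boolean = stats::rbinom(n, 1, 0.5),
                     integer = sample(0:5, n, replace = TRUE),
                     stop("unknown dtype: ", dtypes[[j]]))
  }
  pr <- stats::plogis(truth$intercept + drop(x %*% w))
  labels <- stats::rbinom(n, 1, pr)
  if (truth$missingness_rate > 0) {
    mask <- matrix(stats::runif(n * p) < truth$missingness_rate, n, p)
    # keep at least one observed value per column
    for (j in which(colSums(!mask) == 0L)) mask[1, j] <- FALSE
    x[mask] <- NA_real_
  }
  fm <- feature_matrix(x, labels = labels)
  attr(fm, "truth") <- truth
  fm
}

#' Generate a synthetic VCF over a registry panel
#'
#' Writes a valid VCF 4.2 file with `n_variants` SNVs, the stated
#' fraction of which (rounded) lie inside panel gene intervals; the rest
#' are placed on the same contigs outside every interval. All records
#' carry a `CONSEQ=missense_variant` INFO tag unless `missense_fraction`
#' lowers it.
#'
#' @param n_variants number of records.
#' @param registry a non-empty `gene_registry`.
#' @param fraction_in_panel fraction of variants inside panel intervals.
#' @param path output VCF path.
#' @param seed RNG seed.
#' @param missense_fraction fraction tagged `missense_variant`; others
#'   get `synonymous_variant` (default 1).
#' @return `path`, invisibly.
#' @export
gen_vcf <- function(n_variants, registry, fraction_in_panel, path, seed = 1,
                    missense_fraction = 1) {
  stopifnot(inherits(registry, "gene_registry"),
            fraction_in_panel >= 0, fraction_in_panel <= 1)
  rec <- registry$records
  if (nrow(rec) == 0L) stop("registry is empty")
  set.seed(seed)
  n_in <- round(n_variants * fraction_in_panel)
  rows <- vector("list", n_variants)
  bases <- c("A", "C", "G", "T")
  inside <- c(rep(TRUE, n_in), rep(FALSE, n_variants - n_in))
  for (i in seq_len(n_variants)) {
    if (inside[[i]]) {
      g <- sample(nrow(rec), 1)
      pos <- sample(rec$start[[g]]:rec$end[[g]], 1)
      chrom <- rec$chromosome[[g]]
    } else {
      chrom <- sample(unique(rec$chromosome), 1)
      on_chr <- rec[rec$chromosome == chrom, , drop = FALSE]
      repeat {
        pos <- max(on_chr$end) + sample(1000:100000, 1)
        hit <- any(on_chr$start <= pos & on_chr$end >= pos)
        if (!hit) break
      }
    }
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    rows[[i]] <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  conseq <- ifelse(stats::runif(n_variants) < missense_fraction,
                   "missense_variant", "synonymous_variant")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"Consequence term\">",
               paste0("##contig=<ID=", unique(tab$chrom), ">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tCONSEQ=%s",
                     tab$chrom, tab$pos, tab$ref, tab$alt, conseq), con)
  invisible(path)
}

#' Generate per-level annotation source tables for a variant set
#'
#' Builds one source table per annotation level covering the given panel
#' variants, with controlled completely-at-random missingness: a
#' variant-level table keyed by chromosome/position/ref/alt, a
#' gene-level table keyed by gene, and a transcript-level table keyed by
#' transcript (covering every registry transcript of the panel genes).
#'
#' @param panel_variants data.frame from [filter_to_panel()].
#' @param schema an `annotation_schema`.
#' @param registry the `gene_registry`.
#' @param missingness_rate per-cell probability of an `NA` token.
#' @param seed RNG seed.
#' @return Named list of data.frames (`variant`, `gene`, `transcript`),
#'   suitable for [annotate_variants()].
#' @export
gen_annotation_sources <- function(panel_variants, schema, registry,
                                   missingness_rate = 0.1, seed = 1) {
  stopifnot(inherits(schema, "annotation_schema"))
  set.seed(seed)
  fields <- schema$fields
  draw <- function(dtype, n) {
    switch(dtype,
           continuous = round(stats::rnorm(n), 6),
           boolean = stats::rbinom(n, 1, 0.5),
           integer = sample(0:5, n, replace = TRUE))
  }
  sprinkle <- function(x) {
    x <- as.character(x)
    x[stats::runif(length(x)) < missingness_rate] <- "NA"
    x
  }
  genes <- unique(panel_variants$gene)
  tx <- unlist(lapply(genes, function(g) gene_record(registry, g)$all_transcripts[[1]]))
  out <- list(
    variant = data.frame(chromosome = panel_variants$chromosome,
                         position = panel_variants$position,
                         ref = panel_variants$ref, alt = panel_variants$alt,
                         stringsAsFactors = FALSE),
    gene = data.frame(gene = genes, stringsAsFactors = FALSE),
    transcript = data.frame(transcript = tx, stringsAsFactors = FALSE))
  key_n <- c(variant = nrow(out$variant), gene = length(genes),
             transcript = length(tx))
  for (j in seq_len(nrow(fields))) {
    lvl <- fields$level[[j]]
    out[[lvl]][[fields$name[[j]]]] <-
      sprinkle(draw(fields$dtype[[j]], key_n[[lvl]]))
  }
  out
}

#' Generate background exome tables
#'
#' Emulates frequency-filtered exomes from healthy individuals: each
#' exome holds roughly `variants_per_exome` variants (Poisson jitter),
#' MAFs drawn mostly rare with a common tail, and one score column per
#' tool drawn from a benign-like Beta distribution.
#'
#' @param n_exomes number of exomes.
#' @param variants_per_exome target exome size (default 400).
#' @param tools character vector of score column names.
#' @param seed RNG seed.
#' @param benign_beta shape parameters of the per-tool score
#'   distribution (default `c(2, 8)`, concentrated near 0).
#' @return data.frame with columns `exome_id`, `variant_id`, `maf` and
#'   one column per tool.
#' @export
gen_background_exomes <- function(n_exomes, variants_per_exome = 400,
                                  tools = "scoreA", seed = 1,
                                  benign_beta = c(2, 8)) {
  stopifnot(n_exomes >= 1, variants_per_exome >= 1)
  set.seed(seed)
  rows <- lapply(seq_len(n_exomes), function(e) {
    n <- if (variants_per_exome > 1)
      max(1L, stats::rpois(1, variants_per_exome)) else 1L
    df <- data.frame(exome_id = sprintf("exome%03d", e),
                     variant_id = sprintf("exome%03d:v%04d", e, seq_len(n)),
                     maf = ifelse(stats::runif(n) < 0.9,
                                  stats::runif(n, 0, 0.01),
                                  stats::runif(n, 0.01, 0.5)),
                     stringsAsFactors = FALSE)
    for (tool in tools) {
      df[[tool]] <- stats::rbeta(n, benign_beta[[1]], benign_beta[[2]])
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
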