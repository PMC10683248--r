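#' Read variants from a VCF file
#'
#' Reads a VCF 4.x file (plain or bgzipped) and returns one row per
#' REF/ALT allele pair: multi-allelic records are decomposed into one row
#' per ALT, since downstream scoring is per-allele. Input order is
#' preserved (decomposed alleles stay adjacent, in ALT order).
#'
#' @param path VCF path.
#' @param consequence_key INFO key carrying a consequence term (e.g.
#'   `missense_variant`); optional — rows without it get `NA`.
#' @return data.frame with columns `chromosome`, `position`, `ref`, `alt`,
#'   `consequence`.
#' @export
read_vcf_variants <- function(path, consequence_key = "CONSEQ") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    return(data.frame(chromosome = character(), position = integer(),
                      ref = character(), alt = character(),
                      consequence = character(), stringsAsFactors = FALSE))
  }
  conseq <- tryCatch(vcfR::extract.info(vcf, element = consequence_key),
                     error = function(e) rep(NA_character_, n))
  if (is.null(conseq)) conseq <- rep(NA_character_, n)
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  idx <- rep(seq_len(n), lengths(alts))
  out <- data.frame(chromosome = fix[idx, "CHROM"],
                    position = as.integer(fix[idx, "POS"]),
                    ref = toupper(fix[idx, "REF"]),
                    alt = toupper(unlist(alts)),
                    consequence = conseq[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  validate_variant_keys(out)
  out
}

validate_variant_keys <- function(variants) {
  if (nrow(variants) == 0L) return(invisible(variants))
  if (any(is.na(variants$position)) || any(variants$position < 1L)) {
    stop("VCF positions must be 1-based positive integers")
  }
  ok_allele <- function(a) nzchar(a) & grepl("^[ACGT]+$", a)
  bad <- !ok_allele(variants$ref) | !ok_allele(variants$alt) |
    variants$ref == variants$alt
  if (any(bad)) {
    stop("invalid allele pair at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  invisible(variants)
}

variant_id <- function(variants) {
  paste(variants$chromosome, variants$position, variants$ref, variants$alt, sep = ":")
}

#' Restrict variants to a gene panel
#'
#' Keeps variants whose position falls inside a registry gene interval
#' (1-based, inclusive at both ends) on the same contig. A variant inside
#' two overlapping panel genes is emitted once per gene. Variants on
#' contigs absent from the registry are silently dropped. Input order is
#' preserved.
#'
#' @param variants data.frame as returned by [read_vcf_variants()].
#' @param registry a `gene_registry`.
#' @param missense_only if `TRUE`, keep only rows whose `consequence`
#'   contains `missense_variant`.
#' @return data.frame of the retained variants with an added `gene` column.
#' @export
filter_to_panel <- function(variants, registry, missense_only = FALSE) {
  stopifnot(inherits(registry, "gene_registry"))
  rec <- registry$records
  empty <- cbind(variants[0, , drop = FALSE], gene = character(0))
  if (nrow(variants) == 0L || nrow(rec) == 0L) return(empty)
  if (isTRUE(missense_only)) {
    keep <- !is.na(variants$consequence) &
      grepl("missense_variant", variants$consequence, fixed = TRUE)
    variants <- variants[keep, , drop = FALSE]
    if (nrow(variants) == 0L) return(empty)
  }
  pieces <- lapply(seq_len(nrow(variants)), function(i) {
    hit <- rec$chromosome == variants$chromosome[[i]] &
      rec$start <= variants$position[[i]] &
      rec$end >= variants$position[[i]]
    if (!any(hit)) return(NULL)
    cbind(variants[rep(i, sum(hit)), , drop = FALSE], gene = rec$symbol[hit])
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) return(empty)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

missing_tokens <- c("", ".", "NA", "na", "NaN", "nan", "none", "None")

coerce_column <- function(x, dtype) {
  x <- as.character(x)
  is_missing <- is.na(x) | x %in% missing_tokens
  failed <- rep(FALSE, length(x))
  if (dtype == "boolean") {
    lx <- tolower(x)
    val <- rep(NA, length(x))
    val[lx %in% c("1", "true", "t", "yes")] <- TRUE
    val[lx %in% c("0", "false", "f", "no")] <- FALSE
    failed <- !is_missing & is.na(val)
    val[failed] <- NA
  } else {
    num <- suppressWarnings(as.numeric(x))
    failed <- !is_missing & is.na(num)
    if (dtype == "integer") {
      whole <- !is.na(num) & abs(num - round(num)) < 1e-9
      failed <- failed | (!is_missing & !is.na(num) & !whole)
      val <- ifelse(whole, as.integer(round(num)), NA_integer_)
      val <- as.integer(val)
    } else {
      val <- num
    }
    val[is_missing | failed] <- NA
  }
  list(values = val, failed = failed)
}

#' Attach schema annotations to panel variants
#'
#' Joins per-level annotation source tables onto a stream of panel
#' variants. Variant-level tables are keyed by
#' `chromosome`/`position`/`ref`/`alt`, gene-level tables by `gene`, and
#' transcript-level tables by `transcript`. Each variant gets one
#' representative transcript: the gene's MANE transcript, or — when the
#' MANE id is absent from the transcripts observed for that gene in
#' transcript-level sources — the lexicographically smallest observed id.
#' Every schema field is present in the output; values failing dtype
#' coercion are recorded as missing and counted in the coercion-failure
#' report rather than aborting.
#'
#' @param variants data.frame from [filter_to_panel()] (must carry `gene`).
#' @param schema an `annotation_schema`.
#' @param sources named list of data.frames holding annotation columns.
#' @param registry the `gene_registry` used for transcript resolution.
#' @return data.frame of class `annotated_variants`: key columns, `gene`,
#'   `transcript`, `consequence`, then one column per schema field in
#'   schema order. Attributes `schema`, `missingness` (per-field missing
#'   counts) and `coercion_failures` (per-field failed-parse counts).
#' @export
annotate_variants <- function(variants, schema, sources, registry) {
  stopifnot(inherits(schema, "annotation_schema"), inherits(registry, "gene_registry"))
  n <- nrow(variants)
  fields <- schema$fields
  # resolve a representative transcript per variant
  observed_by_gene <- list()
  for (src in sources) {
    if ("transcript" %in% names(src)) {
      for (g in unique(variants$gene)) {
        all_tx <- gene_record(registry, g)$all_transcripts[[1]]
        seen <- intersect(unique(src$transcript), all_tx)
        observed_by_gene[[g]] <- union(observed_by_gene[[g]], seen)
      }
    }
  }
  transcript <- vapply(variants$gene, function(g) {
    obs <- observed_by_gene[[g]]
    if (is.null(obs)) obs <- character()
    select_mane_transcript(gene_record(registry, g), obs)
  }, character(1), USE.NAMES = FALSE)

  out <- data.frame(chromosome = variants$chromosome,
                    position = variants$position,
                    ref = variants$ref, alt = variants$alt,
                    gene = variants$gene, transcript = transcript,
                    consequence = if (is.null(variants$consequence))
                      NA_character_ else variants$consequence,
                    stringsAsFactors = FALSE)
  vid <- variant_id(out)
  coercion_failures <- stats::setNames(integer(nrow(fields)), fields$name)

  for (j in seq_len(nrow(fields))) {
    fname <- fields$name[[j]]
    level <- fields$level[[j]]
    raw <- rep(NA_character_, n)
    for (src in sources) {
      if (!fname %in% names(src)) next
      if (level == "variant") {
        if (!all(c("chromosome", "position", "ref", "alt") %in% names(src))) next
        m <- match(vid, variant_id(src))
      } else if (level == "gene") {
        if (!"gene" %in% names(src)) next
        m <- match(out$gene, src$gene)
      } else {
        if (!"transcript" %in% names(src)) next
        m <- match(out$transcript, src$transcript)
      }
      hit <- !is.na(m)
      raw[hit] <- as.character(src[[fname]][m[hit]])
      if (any(hit)) break
    }
    cc <- coerce_column(raw, fields$dtype[[j]])
    out[[fname]] <- cc$values
    coercion_failures[[fname]] <- sum(cc$failed)
  }
  missingness <- vapply(fields$name, function(f) sum(is.na(out[[f]])), integer(1))
  structure(out, schema = schema, missingness = missingness,
            coercion_failures = coercion_failures,
            class = c("annotated_variants", "data.frame"))
}

#' Write an annotated variant table
#'
#' Tab-separated, one row per variant; columns are the four key fields,
#' `gene`, `transcript`, `consequence`, then the schema fields in schema
#' order. Missing values are rendered as `"."` (VCF convention); booleans
#' as `1`/`0`.
#'
#' @param annotated an `annotated_variants` object.
#' @param path output path.
#' @return Number of data rows written.
#' @export
write_annotated_table <- function(annotated, path) {
  schema <- attr(annotated, "schema")
  stopifnot(!is.null(schema))
  cols <- c("chromosome", "position", "ref", "alt", "gene", "transcript",
            "consequence", schema$fields$name)
  tab <- as.data.frame(annotated)[, cols, drop = FALSE]
  render <- function(x) {
    if (is.logical(x)) x <- as.integer(x)
    out <- as.character(x)
    out[is.na(out)] <- "."
    out
  }
  chr_tab <- as.data.frame(lapply(tab, render), stringsAsFactors = FALSE,
                           check.names = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(chr_tab) > 0L) {
    writeLines(do.call(paste, c(chr_tab, sep = "\t")), con)
  }
  nrow(chr_tab)
}

#' Read back an annotated variant table
#'
#' Inverse of [write_annotated_table()]: reproduces typed columns and the
#' explicit missing marker.
#'
#' @param path TSV path written by [write_annotated_table()].
#' @param schema the `annotation_schema` the table was written with.
#' @return An `annotated_variants` data.frame.
#' @export
read_annotated_table <- function(path, schema) {
  stopifnot(inherits(schema, "annotation_schema"))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  out <- data.frame(chromosome = tab$chromosome,
                    position = as.integer(tab$position),
                    ref = tab$ref, alt = tab$alt, gene = tab$gene,
                    transcript = tab$transcript,
                    consequence = ifelse(tab$consequence == ".", NA_character_,
                                         tab$consequence),
                    stringsAsFactors = FALSE)
  coercion_failures <- stats::setNames(integer(nrow(schema$fields)), schema$fields$name)
  for (j in seq_len(nrow(schema$fields))) {
    fname <- schema$fields$name[[j]]
    cc <- coerce_column(tab[[fname]], schema$fields$dtype[[j]])
    out[[fname]] <- cc$values
  }
  missingness <- vapply(schema$fields$name, function(f) sum(is.na(out[[f]])), integer(1))
  structure(out, schema = schema, missingness = missingness,
            coercion_failures = coercion_failures,
            class = c("annotated_variants", "data.frame"))
}
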