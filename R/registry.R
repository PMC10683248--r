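#' @keywords internal
"_PACKAGE"

GENE_CATEGORIES <- c("mt_protein_coding", "disease_nuclear", "mito_localized_nuclear")

#' Construct a gene registry
#'
#' A gene registry is the panel definition: one record per gene with its
#' genomic interval (1-based, inclusive), strand, panel category, the set of
#' known transcripts and the MANE representative among them.
#'
#' @param records data.frame with columns `symbol`, `chromosome`, `start`,
#'   `end`, `strand`, `category`, `mane_transcript`, `all_transcripts`
#'   (list-column of character vectors, or a character vector of
#'   comma-separated ids).
#' @param build genome build tag carried as metadata (default `"hg19"`).
#' @return An object of class `gene_registry`.
#' @export
gene_registry <- function(records, build = "hg19") {
  required <- c("symbol", "chromosome", "start", "end", "strand",
                "category", "mane_transcript", "all_transcripts")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("registry is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!is.list(records$all_transcripts)) {
    records$all_transcripts <- strsplit(as.character(records$all_transcripts), ",", fixed = TRUE)
  }
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  bad_cat <- setdiff(unique(records$category), GENE_CATEGORIES)
  if (length(bad_cat) > 0L) {
    stop("unknown gene category token(s): ", paste(bad_cat, collapse = ", "))
  }
  if (anyDuplicated(records$symbol)) {
    dups <- unique(records$symbol[duplicated(records$symbol)])
    stop("duplicate gene symbol(s) in registry: ", paste(dups, collapse = ", "))
  }
  if (nrow(records) > 0L) {
    if (any(is.na(records$start)) || any(is.na(records$end))) {
      stop("registry intervals must be integer start/end")
    }
    if (any(records$start > records$end)) {
      stop("registry interval with start > end for gene(s): ",
           paste(records$symbol[records$start > records$end], collapse = ", "))
    }
    if (!all(records$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'")
    }
    mane_ok <- mapply(function(m, all) m %in% all,
                      records$mane_transcript, records$all_transcripts)
    if (!all(mane_ok)) {
      stop("MANE transcript not among all_transcripts for gene(s): ",
           paste(records$symbol[!mane_ok], collapse = ", "))
    }
  }
  structure(list(records = records, build = build), class = "gene_registry")
}

#' Load a gene registry from a tab-separated table
#'
#' The table must have a header row with columns `symbol`, `chromosome`,
#' `start`, `end`, `strand`, `category`, `mane_transcript`,
#' `all_transcripts` (comma-separated transcript ids). Rows with the wrong
#' field count are rejected with the offending line number.
#'
#' @param path path to the TSV registry table.
#' @param build genome build tag (default `"hg19"`).
#' @return A `gene_registry`.
#' @export
load_gene_registry <- function(path, build = "hg19") {
  if (!file.exists(path)) stop("registry file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("registry file is empty: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  n_fields <- vapply(strsplit(lines, "\t", fixed = TRUE), length, integer(1))
  bad <- which(n_fields != length(header) & nzchar(lines))
  bad <- setdiff(bad, 1L)
  if (length(bad) > 0L) {
    stop("malformed registry row at line ", bad[[1]], ": expected ",
         length(header), " fields, found ", n_fields[[bad[[1]]]])
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  gene_registry(tab, build = build)
}

#' Write a gene registry to a tab-separated table
#'
#' @param registry a `gene_registry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_registry <- function(registry, path) {
  stopifnot(inherits(registry, "gene_registry"))
  tab <- registry$records
  tab$all_transcripts <- vapply(tab$all_transcripts, paste, character(1), collapse = ",")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-category gene and transcript counts of a registry
#'
#' @param registry a `gene_registry`.
#' @return data.frame with one row per category plus a `total` row, columns
#'   `category`, `genes`, `transcripts`.
#' @export
category_counts <- function(registry) {
  stopifnot(inherits(registry, "gene_registry"))
  rec <- registry$records
  genes <- vapply(GENE_CATEGORIES, function(cat) sum(rec$category == cat), integer(1))
  tx <- vapply(GENE_CATEGORIES, function(cat) {
    if (genes[[cat]] == 0L) return(0L)
    sum(lengths(rec$all_transcripts[rec$category == cat]))
  }, integer(1))
  out <- data.frame(category = c(GENE_CATEGORIES, "total"),
                    genes = c(genes, sum(genes)),
                    transcripts = c(tx, sum(tx)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Look up a gene record by symbol
#'
#' @param registry a `gene_registry`.
#' @param symbol gene symbol.
#' @return One-row data.frame (with `all_transcripts` list-column).
#' @export
gene_record <- function(registry, symbol) {
  stopifnot(inherits(registry, "gene_registry"))
  idx <- match(symbol, registry$records$symbol)
  if (is.na(idx)) stop("gene not in registry: ", symbol)
  registry$records[idx, , drop = FALSE]
}

#' @export
print.gene_registry <- function(x, ...) {
  cc <- category_counts(x)
  cat("Gene registry (build ", x$build, ")\n", sep = "")
  cat(sprintf("  %-24s %6d genes  %6d transcripts\n",
              cc$category, cc$genes, cc$transcripts), sep = "")
  invisible(x)
}

#' Pick the representative transcript for a gene
#'
#' Returns the gene's MANE transcript when it is among the observed
#' transcripts, or when no transcripts were observed. When the MANE
#' transcript is absent from a non-empty observed set, the
#' lexicographically smallest observed id is returned as a deterministic,
#' auditable fallback.
#'
#' @param gene one-row gene record (as returned by [gene_record()]).
#' @param observed_transcripts character vector of transcript ids seen for
#'   this gene in the data being annotated (may be empty).
#' @return A single transcript id.
#' @export
select_mane_transcript <- function(gene, observed_transcripts = character()) {
  mane <- gene$mane_transcript[[1]]
  if (length(observed_transcripts) == 0L || mane %in% observed_transcripts) {
    return(mane)
  }
  sort(observed_transcripts)[[1]]
}
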