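ANNOTATION_CATEGORIES <- c("basic", "predictor_score", "allele_frequency",
                           "tissue_expression", "amino_acid_property",
                           "mito_specific")
ANNOTATION_DTYPES <- c("integer", "boolean", "continuous")
ANNOTATION_LEVELS <- c("variant", "gene", "transcript")

#' Construct an annotation schema
#'
#' A schema is an ordered list of typed annotation fields. Each field has a
#' unique name, one of six categories (basic, predictor_score,
#' allele_frequency, tissue_expression, amino_acid_property, mito_specific),
#' one of three data types (integer, boolean, continuous) and one of three
#' levels (variant, gene, transcript). The schema fixes the column order of
#' every annotated table derived from it.
#'
#' @param fields data.frame with columns `name`, `category`, `dtype`,
#'   `level` and optionally `source` (free-text provenance).
#' @return Object of class `annotation_schema`.
#' @export
annotation_schema <- function(fields) {
  fields <- as.data.frame(fields, stringsAsFactors = FALSE)
  required <- c("name", "category", "dtype", "level")
  missing_cols <- setdiff(required, names(fields))
  if (length(missing_cols) > 0L) {
    stop("schema is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(fields$source)) fields$source <- ""
  if (anyDuplicated(fields$name)) {
    stop("duplicate field name(s) in schema: ",
         paste(unique(fields$name[duplicated(fields$name)]), collapse = ", "))
  }
  check_enum <- function(values, allowed, what) {
    bad <- setdiff(unique(values), allowed)
    if (length(bad) > 0L) {
      stop("unknown ", what, " token(s): ", paste(bad, collapse = ", "))
    }
  }
  check_enum(fields$category, ANNOTATION_CATEGORIES, "category")
  check_enum(fields$dtype, ANNOTATION_DTYPES, "dtype")
  check_enum(fields$level, ANNOTATION_LEVELS, "level")
  rownames(fields) <- NULL
  structure(list(fields = fields[, c("name", "category", "dtype", "level", "source")]),
            class = "annotation_schema")
}

#' Read an annotation schema from YAML
#'
#' The YAML file is a list of field entries, each with keys `name`,
#' `category`, `dtype`, `level` and optional `source`.
#'
#' @param path YAML file path.
#' @return An `annotation_schema`.
#' @export
read_annotation_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) stop("schema file has no fields: ", path)
  fields <- do.call(rbind, lapply(raw, function(f) {
    data.frame(name = f$name, category = f$category, dtype = f$dtype,
               level = f$level, source = if (is.null(f$source)) "" else f$source,
               stringsAsFactors = FALSE)
  }))
  annotation_schema(fields)
}

#' Write an annotation schema to YAML
#'
#' @param schema an `annotation_schema`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_schema <- function(schema, path) {
  stopifnot(inherits(schema, "annotation_schema"))
  entries <- lapply(seq_len(nrow(schema$fields)), function(i) {
    as.list(schema$fields[i, , drop = FALSE])
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Count schema fields in a category
#'
#' @param schema an `annotation_schema`.
#' @param category category token, e.g. `"mito_specific"`.
#' @return Integer count.
#' @export
n_fields_in_category <- function(schema, category) {
  stopifnot(inherits(schema, "annotation_schema"))
  if (!category %in% ANNOTATION_CATEGORIES) stop("unknown category: ", category)
  sum(schema$fields$category == category)
}

#' @export
print.annotation_schema <- function(x, ...) {
  cat("Annotation schema:", nrow(x$fields), "fields\n")
  tab <- table(factor(x$fields$category, levels = ANNOTATION_CATEGORIES))
  for (cat_name in names(tab)) {
    if (tab[[cat_name]] > 0) cat(sprintf("  %-20s %4d\n", cat_name, tab[[cat_name]]))
  }
  invisible(x)
}
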