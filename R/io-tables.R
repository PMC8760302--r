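#' Read a typed TSV table
#'
#' All pipeline tables are tab-separated with a header row and C-locale
#' decimals.  `schema` names the required columns and their types; extra
#' columns are preserved as character, row order is preserved.
#'
#' @param path path to a TSV file.
#' @param schema named character vector mapping required column names to
#'   `"character"`, `"numeric"` or `"integer"`.
#' @return a data.frame.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop_np("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop_np("missing required column(s): ", paste(missing, collapse = ", "))
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type %in% c("numeric", "integer")) {
      raw <- df[[col]]
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(val) & !(is.na(raw) | raw %in% c("NA", "")))
      if (length(bad))
        stop_np(sprintf("column '%s': unparseable numeric value '%s' at data row %d",
                        col, raw[bad[1]], bad[1]))
      df[[col]] <- if (type == "integer") as.integer(round(val)) else val
    }
  }
  df
}

#' Column schemas for the standard pipeline tables
#'
#' @format Named character vectors usable as the `schema` argument of
#'   [read_table()]: differential-expression tables (`gene_id`, `log2fc`,
#'   `pvalue`), gene association statistics (`gene_id`, `z`), per-gene
#'   loss-of-function mutation rates (`gene_id`, `mu_lof`), de novo counts
#'   (`cohort`, `gene_id`, `count`), cohort sizes (`cohort`, `n_trios`),
#'   term annotations (`gene_id`, `term_id`) and specificity scores
#'   (`gene_id`, `score`).
#' @name table_schemas
NULL

#' @rdname table_schemas
#' @export
schema_deg <- c(gene_id = "character", log2fc = "numeric", pvalue = "numeric")

#' @rdname table_schemas
#' @export
schema_gene_stats <- c(gene_id = "character", z = "numeric")

#' @rdname table_schemas
#' @export
schema_rates <- c(gene_id = "character", mu_lof = "numeric")

#' @rdname table_schemas
#' @export
schema_denovo_counts <- c(cohort = "character", gene_id = "character",
                          count = "integer")

#' @rdname table_schemas
#' @export
schema_cohorts <- c(cohort = "character", n_trios = "integer")

#' @rdname table_schemas
#' @export
schema_annotations <- c(gene_id = "character", term_id = "character")

#' @rdname table_schemas
#' @export
schema_scores <- c(gene_id = "character", score = "numeric")
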