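#' Gene set collections
#'
#' A `gene_set_collection` is a named list in which each element is a
#' `list(description = <chr>, genes = <chr>)`.  Gene ids within a set are
#' unique and unordered; set names are unique within the collection.  It is
#' the in-memory counterpart of a GMT file.
#'
#' @param sets named list of `list(description, genes)` entries, or a named
#'   list of character vectors (descriptions default to `""`).
#' @return a `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets = list()) {
  if (length(sets) > 0 && (is.null(names(sets)) || anyNA(names(sets)) ||
                           any(names(sets) == "")))
    stop_np("every set in a collection must be named")
  if (anyDuplicated(names(sets)))
    stop_np("duplicate set name(s): ",
            paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(s) {
    if (is.character(s)) s <- list(description = "", genes = s)
    if (is.null(s$description)) s$description <- ""
    s$genes <- unique(as.character(s$genes))
    s[c("description", "genes")]
  })
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection with %d set(s)\n", length(x)))
  n <- utils::head(names(x), 5)
  for (nm in n)
    cat(sprintf("  %s: %d genes\n", nm, length(x[[nm]]$genes)))
  if (length(x) > 5) cat(sprintf("  ... and %d more\n", length(x) - 5))
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(unclass(x)[i])
}

#' Extract the gene vector of one set
#' @param collection a [gene_set_collection()].
#' @param name set name.
#' @return character vector of gene ids.
#' @export
set_genes <- function(collection, name) {
  if (!name %in% names(collection)) stop_np("unknown set: ", name)
  collection[[name]]$genes
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one tab-separated line per set, fields are
#' `name`, `description`, then gene ids.  The second field is always a
#' description and never a gene.  Duplicate gene ids within a line are
#' collapsed.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_np("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(gene_set_collection())
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2)
      stop_np(sprintf("malformed GMT line %d: fewer than 2 tab-separated fields", i))
    nm <- fields[[1]]
    if (nm %in% names(sets))
      stop_np(sprintf("duplicate set name '%s' at line %d", nm, i))
    sets[[nm]] <- list(description = fields[[2]],
                       genes = unique(fields[-(1:2)]))
  }
  gene_set_collection(sets)
}

#' Write a GMT gene-set file
#'
#' Genes are written in lexicographic order so output is deterministic and
#' round-trips through [read_gmt()] losslessly.
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    paste(c(nm, s$description, sort(s$genes)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
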