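#' Single-cell expression matrices
#'
#' Container for a genes x cells TPM matrix with per-cell stage/cell-type
#' labels and an explicit stage ordering (progenitor -> mature).  Values are
#' stored dense; sparse MatrixMarket input is densified on load (the
#' profiling operations are dense-arithmetic anyway).
#'
#' @param values numeric genes x cells matrix (TPM, non-negative).
#' @param genes,cells character ids matching the matrix dimensions.
#' @param labels named character vector mapping every cell id to a stage.
#' @param stage_order ordered character vector covering all labels.
#' @return an `sc_matrix` object.
#' @export
sc_matrix <- function(values, genes, cells, labels, stage_order = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(genes))
    stop_np(sprintf("dimension mismatch: matrix has %d rows but %d gene ids",
                    nrow(values), length(genes)))
  if (ncol(values) != length(cells))
    stop_np(sprintf("dimension mismatch: matrix has %d columns but %d cell ids",
                    ncol(values), length(cells)))
  if (any(values < 0)) stop_np("expression values must be non-negative")
  unlabeled <- setdiff(cells, names(labels))
  if (length(unlabeled))
    stop_np("unlabeled cell(s): ", paste(utils::head(unlabeled, 5), collapse = ", "))
  labels <- labels[cells]
  if (is.null(stage_order)) stage_order <- unique(unname(labels))
  extra <- setdiff(unique(labels), stage_order)
  if (length(extra))
    stop_np("stage_order does not cover label(s): ", paste(extra, collapse = ", "))
  dimnames(values) <- list(genes, cells)
  structure(list(values = values, genes = genes, cells = cells,
                 labels = labels, stage_order = stage_order),
            class = "sc_matrix")
}

#' @export
print.sc_matrix <- function(x, ...) {
  cat(sprintf("sc_matrix: %d genes x %d cells, %d stage(s): %s\n",
              length(x$genes), length(x$cells), length(x$stage_order),
              paste(x$stage_order, collapse = ", ")))
  invisible(x)
}

#' Read a cell expression matrix with sidecar files
#'
#' `matrix_path` may be a dense TSV of numbers (genes in rows, no header)
#' or a MatrixMarket `.mtx` file; the two representations load to identical
#' objects.  Sidecars are one-id-per-line gene and cell files plus a
#' two-column TSV (`cell_id`, `label`) labelling every cell.
#'
#' @param matrix_path dense TSV or `.mtx` file of genes x cells values.
#' @param genes_path,cells_path one id per line, in matrix order.
#' @param labels_path TSV with header `cell_id`, `label`.
#' @param stage_order optional explicit stage ordering.
#' @return an [sc_matrix()].
#' @export
read_cell_matrix <- function(matrix_path, genes_path, cells_path, labels_path,
                             stage_order = NULL) {
  genes <- readLines(genes_path, warn = FALSE)
  cells <- readLines(cells_path, warn = FALSE)
  if (grepl("\\.mtx$", matrix_path)) {
    values <- as.matrix(Matrix::readMM(matrix_path))
  } else {
    values <- as.matrix(utils::read.table(matrix_path, sep = "\t",
                                          header = FALSE))
  }
  lab <- read_table(labels_path, c(cell_id = "character", label = "character"))
  labels <- stats::setNames(lab$label, lab$cell_id)
  sc_matrix(values, genes, cells, labels, stage_order)
}

#' Write a cell expression matrix with sidecar files
#'
#' @param mat an [sc_matrix()].
#' @param dir output directory (created if needed).
#' @param sparse write MatrixMarket instead of dense TSV.
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(mat, dir, sparse = TRUE) {
  stopifnot(inherits(mat, "sc_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (sparse) {
    Matrix::writeMM(Matrix::Matrix(mat$values, sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
  } else {
    utils::write.table(mat$values, file.path(dir, "matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  writeLines(mat$genes, file.path(dir, "genes.tsv"))
  writeLines(mat$cells, file.path(dir, "cells.tsv"))
  write_tsv(data.frame(cell_id = mat$cells, label = unname(mat$labels)),
            file.path(dir, "labels.tsv"))
  writeLines(mat$stage_order, file.path(dir, "stages.tsv"))
  invisible(dir)
}
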