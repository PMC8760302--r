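#' Filter low-complexity cells
#'
#' Removes cells expressing (TPM >= `tpm_min`) strictly fewer than
#' `min_frac_genes` of all genes; a cell at exactly the threshold fraction
#' is retained ("less than 5%" is removed).
#'
#' @param matrix an [sc_matrix()].
#' @param min_frac_genes fraction-of-genes threshold (default 0.05).
#' @param tpm_min expression threshold (default 1).
#' @return the filtered [sc_matrix()].
#' @export
filter_cells <- function(matrix, min_frac_genes = 0.05, tpm_min = 1) {
  stopifnot(inherits(matrix, "sc_matrix"))
  assert_prob(min_frac_genes, "min_frac_genes")
  frac <- colSums(matrix$values >= tpm_min) / length(matrix$genes)
  keep <- frac >= min_frac_genes
  if (!any(keep)) stop_np("all cells removed by filter_cells")
  sc_matrix(matrix$values[, keep, drop = FALSE], matrix$genes,
            matrix$cells[keep], matrix$labels[keep], matrix$stage_order)
}

#' Filter rarely expressed genes
#'
#' Removes genes with nonzero expression in strictly fewer than
#' `min_frac_cells` of the (surviving) cells.  Run after [filter_cells()]:
#' gene fractions depend on which cells survive.
#'
#' @param matrix an [sc_matrix()].
#' @param min_frac_cells fraction-of-cells threshold (default 0.05).
#' @return the filtered [sc_matrix()].
#' @export
filter_genes <- function(matrix, min_frac_cells = 0.05) {
  stopifnot(inherits(matrix, "sc_matrix"))
  assert_prob(min_frac_cells, "min_frac_cells")
  frac <- rowSums(matrix$values > 0) / length(matrix$cells)
  keep <- frac >= min_frac_cells
  if (!any(keep)) stop_np("all genes removed by filter_genes")
  sc_matrix(matrix$values[keep, , drop = FALSE], matrix$genes[keep],
            matrix$cells, matrix$labels, matrix$stage_order)
}

#' Z-score expression per gene across all cells
#'
#' Each gene row becomes `(x - mean) / sd` across cells.  The default sd is
#' the population standard deviation (`ddof = 0`); set `ddof = 1` for the
#' sample convention.  Constant genes become all-zero rows and are listed
#' in the `constant_genes` attribute of the result.
#'
#' @param matrix an [sc_matrix()] (filtered).
#' @param ddof degrees-of-freedom correction for the sd (0 or 1).
#' @return an [sc_matrix()] of dimensionless z-scores.
#' @export
zscore_genes <- function(matrix, ddof = 0) {
  stopifnot(inherits(matrix, "sc_matrix"), ddof %in% c(0, 1))
  v <- matrix$values
  n <- ncol(v)
  mu <- rowMeans(v)
  centered <- v - mu
  sd <- sqrt(rowSums(centered^2) / (n - ddof))
  constant <- sd == 0 | !is.finite(sd)
  sd[constant] <- 1
  z <- centered / sd
  z[constant, ] <- 0
  out <- matrix
  out$values <- z
  attr(out, "constant_genes") <- matrix$genes[constant]
  out
}

#' Per-gene average z-scored expression by cell type
#'
#' @param matrix a z-scored [sc_matrix()].
#' @return a `celltype_means` object: genes x stages matrix of gene-level
#'   averages, with stage order preserved.
#' @export
celltype_gene_means <- function(matrix) {
  stopifnot(inherits(matrix, "sc_matrix"))
  stages <- matrix$stage_order
  counts <- table(factor(matrix$labels, levels = stages))
  empty <- names(counts)[counts == 0]
  if (length(empty))
    stop_np("stage(s) with zero cells: ", paste(empty, collapse = ", "))
  means <- vapply(stages, function(s)
    rowMeans(matrix$values[, matrix$labels == s, drop = FALSE]),
    numeric(length(matrix$genes)))
  dimnames(means) <- list(matrix$genes, stages)
  structure(means, class = "celltype_means",
            n_cells = stats::setNames(as.integer(counts), stages))
}

#' Program expression profile across cell types
#'
#' Mean and standard error (sd / sqrt(n)) of the gene-level averages over
#' the program genes present in the data, per stage.
#'
#' @param means a [celltype_gene_means()] result.
#' @param program gene id vector.
#' @return data.frame with `stage`, `mean`, `sem`, `n_genes`.
#' @export
program_profile <- function(means, program) {
  stopifnot(inherits(means, "celltype_means"))
  program <- assert_gene_set(program)
  present <- intersect(program, rownames(means))
  if (length(present) < 2)
    stop_np("fewer than 2 program genes present in the expression data")
  sub <- means[present, , drop = FALSE]
  data.frame(stage = colnames(means),
             mean = colMeans(sub),
             sem = apply(sub, 2, stats::sd) / sqrt(length(present)),
             n_genes = length(present),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' The six successive-stage comparisons of the fetal profiling analysis
#' @export
DEFAULT_STAGE_PAIRS <- list(
  c("RG-early", "RG"), c("RG", "IPC"), c("RG", "Transitioning"),
  c("IPC", "Transitioning"), c("Transitioning", "Newborn"),
  c("Newborn", "Developing"))

#' Stage-difference t tests for a program
#'
#' For each stage pair, a two-tailed Student's t test on the program's
#' gene-level averages, paired across genes by default (the same genes are
#' measured at both stages); set `paired = FALSE` for the two-sample
#' equal-variance test.  P-values are Bonferroni-corrected for the number
#' of pairs.  When the difference vector is (numerically) constant the
#' result is degenerate: t is 0 or +/-Inf and p is 1 or 0, with the
#' `degenerate` flag set.
#'
#' @param means a [celltype_gene_means()] result.
#' @param program gene id vector.
#' @param pairs list of 2-element stage name vectors
#'   (default [DEFAULT_STAGE_PAIRS] intersected with available stages).
#' @param paired pair observations by gene (default TRUE).
#' @return data.frame: `stage1`, `stage2`, `t`, `df`, `p_raw`,
#'   `p_corrected`, `degenerate`.
#' @export
successive_stage_tests <- function(means, program, pairs = NULL,
                                   paired = TRUE) {
  stopifnot(inherits(means, "celltype_means"))
  program <- assert_gene_set(program)
  if (is.null(pairs)) {
    pairs <- Filter(function(p) all(p %in% colnames(means)),
                    DEFAULT_STAGE_PAIRS)
    if (length(pairs) == 0)
      pairs <- mapply(c, colnames(means)[-ncol(means)], colnames(means)[-1],
                      SIMPLIFY = FALSE)
  }
  bad <- Filter(function(p) !all(p %in% colnames(means)), pairs)
  if (length(bad))
    stop_np("pair references unknown stage(s): ",
            paste(unlist(bad), collapse = ", "))
  present <- intersect(program, rownames(means))
  if (length(present) < 3) stop_np("fewer than 3 program genes present")
  eps <- 1e-12
  rows <- lapply(pairs, function(pr) {
    x <- means[present, pr[1]]; y <- means[present, pr[2]]
    n <- length(present)
    if (paired) {
      d <- x - y
      sdd <- stats::sd(d)
      if (sdd < eps) {
        t <- if (abs(mean(d)) < eps) 0 else sign(mean(d)) * Inf
        df <- n - 1
      } else {
        t <- mean(d) / (sdd / sqrt(n)); df <- n - 1
      }
    } else {
      sp2 <- ((n - 1) * stats::var(x) + (n - 1) * stats::var(y)) / (2 * n - 2)
      if (sp2 < eps^2) {
        t <- if (abs(mean(x) - mean(y)) < eps) 0 else sign(mean(x) - mean(y)) * Inf
        df <- 2 * n - 2
      } else {
        t <- (mean(x) - mean(y)) / sqrt(sp2 * 2 / n); df <- 2 * n - 2
      }
    }
    degenerate <- !is.finite(t) || (t == 0 && (paired && stats::sd(x - y) < eps))
    p <- if (is.finite(t)) 2 * stats::pt(abs(t), df, lower.tail = FALSE) else 0
    data.frame(stage1 = pr[1], stage2 = pr[2], t = t, df = df, p_raw = p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- bonferroni(out$p_raw, length(pairs))
  out
}

#' Build fetal-expressed gene sets from the cell matrix
#'
#' Stringent mode (`"tpm"`): genes expressed at TPM >= 1 in at least
#' `min_frac` of the cells of *any* listed stage.  Relaxed mode
#' (`"nonzero"`): genes with nonzero expression in at least one cell of the
#' listed stages.
#'
#' @param matrix an [sc_matrix()] (TPM scale, pre-z-scoring).
#' @param stages stage names to consider (e.g. Newborn, Developing).
#' @param min_frac per-stage cell fraction for stringent mode
#'   (default 0.05).
#' @param mode `"tpm"` (stringent) or `"nonzero"` (relaxed).
#' @param tpm_min stringent-mode expression threshold (default 1).
#' @return character vector of gene ids.
#' @export
expressed_in_cells <- function(matrix, stages, min_frac = 0.05,
                               mode = c("tpm", "nonzero"), tpm_min = 1) {
  stopifnot(inherits(matrix, "sc_matrix"))
  mode <- match.arg(mode)
  if (length(stages) == 0) stop_np("empty stage subset")
  bad <- setdiff(stages, matrix$stage_order)
  if (length(bad)) stop_np("unknown stage(s): ", paste(bad, collapse = ", "))
  if (mode == "nonzero") {
    cells <- matrix$labels %in% stages
    keep <- rowSums(matrix$values[, cells, drop = FALSE] > 0) >= 1
  } else {
    keep <- rep(FALSE, length(matrix$genes))
    for (s in stages) {
      cells <- matrix$labels == s
      frac <- rowSums(matrix$values[, cells, drop = FALSE] >= tpm_min) /
        sum(cells)
      keep <- keep | (frac >= min_frac)
    }
  }
  matrix$genes[keep]
}
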