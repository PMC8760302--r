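#' Expressed-gene universe
#'
#' The background universe of expressed genes ("all expressed in WT or KO
#' lines"), with optional named logical flags per gene (e.g. loss-of-function
#' intolerance, regulator-target membership, a true program label in
#' synthetic data).
#'
#' @param genes character vector of unique gene ids.
#' @param flags named list of logical vectors (length of `genes`) or of
#'   character vectors of flagged gene ids.
#' @return a `gene_universe` object.
#' @export
gene_universe <- function(genes, flags = list()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop_np("duplicate gene ids in universe")
  flags <- lapply(flags, function(f) {
    if (is.character(f)) {
      out <- setdiff(f, genes)
      if (length(out)) stop_np("flagged gene(s) outside universe: ",
                               paste(utils::head(out, 5), collapse = ", "))
      f <- genes %in% f
    }
    stopifnot(is.logical(f), length(f) == length(genes))
    f
  })
  structure(list(genes = genes, flags = flags), class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("gene_universe: %d genes", length(x$genes)))
  if (length(x$flags))
    cat(sprintf("; flags: %s", paste(names(x$flags), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Genes carrying a universe flag
#' @param universe a [gene_universe()].
#' @param flag flag name.
#' @return character vector of flagged gene ids.
#' @export
flagged_genes <- function(universe, flag) {
  if (!flag %in% names(universe$flags)) stop_np("unknown flag: ", flag)
  universe$genes[universe$flags[[flag]]]
}

#' Filter genes by counts-per-million expression
#'
#' Retains genes with cpm >= `cpm_min` in at least
#' `ceiling(sample_frac * n_samples)` samples, where
#' `cpm = count / library_size * 1e6`.  Ties at the threshold are inclusive.
#'
#' @param counts non-negative genes x samples matrix with gene-id rownames.
#' @param cpm_min cpm threshold (default 1).
#' @param sample_frac fraction of samples required (default 1/3).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(counts, cpm_min = 1, sample_frac = 1/3) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1) stop_np("need at least one sample")
  if (any(counts < 0)) stop_np("counts must be non-negative")
  if (is.null(rownames(counts))) stop_np("counts must have gene-id rownames")
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero))
    stop_np("sample(s) with zero total counts: ",
            paste(colnames(counts)[zero] %||% zero, collapse = ", "))
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  need <- ceiling(sample_frac * ncol(counts))
  keep <- rowSums(cpm >= cpm_min) >= need
  rownames(counts)[keep]
}

#' Call differentially expressed gene sets at a Bonferroni threshold
#'
#' A gene is significant when `pvalue * n_tested < alpha`; `n_tested` is
#' the number of genes in the contrast's table (the expressed universe for
#' that contrast), not a genome-wide count.  Significant genes are split by
#' strict log2 fold-change sign; a log2fc of exactly 0 joins neither set.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `pvalue`
#'   (one record per gene).
#' @param alpha familywise significance level (default 0.05).
#' @return a `deg_sets` object: `up`, `down` gene vectors, `alpha`,
#'   `n_tested`.
#' @export
call_deg <- function(table, alpha = 0.05) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop_np("empty or invalid DEG table")
  stopifnot(all(c("gene_id", "log2fc", "pvalue") %in% names(table)))
  if (anyDuplicated(table$gene_id)) stop_np("duplicate gene ids in DEG table")
  if (any(table$pvalue < 0 | table$pvalue > 1, na.rm = TRUE))
    stop_np("p-values outside [0, 1]")
  n <- nrow(table)
  sig <- table$pvalue * n < alpha
  structure(list(up = table$gene_id[sig & table$log2fc > 0],
                 down = table$gene_id[sig & table$log2fc < 0],
                 alpha = alpha, n_tested = n,
                 contrast = attr(table, "contrast")),
            class = "deg_sets")
}

#' @export
print.deg_sets <- function(x, ...) {
  cat(sprintf("deg_sets%s: %d up, %d down (alpha = %g, n_tested = %d)\n",
              if (is.null(x$contrast)) "" else paste0(" [", x$contrast, "]"),
              length(x$up), length(x$down), x$alpha, x$n_tested))
  invisible(x)
}

#' Program labels, in fixed order
#' @export
PROGRAM_LABELS <- c("early-transient", "early-stable", "early-increasing",
                    "late", "none")

#' Classify genes into timecourse transcriptional programs
#'
#' Programs are defined by set algebra on the three wild-type upregulation
#' sets between differentiation days 20, 30 and 60:
#' * `early-increasing` = up(20-30) and up(30-60)
#' * `early-stable`     = up(20-30) and up(20-60), not up(30-60)
#' * `early-transient`  = up(20-30), not up(20-60), not up(30-60)
#' * `late`             = up(30-60), not up(20-30)
#'
#' The extra `not up(30-60)` clause on early-transient (precedence
#' early-increasing > early-stable > early-transient) makes the four labels
#' provably disjoint; all other genes are labelled `none`.
#'
#' @param up_20_30,up_30_60,up_20_60 gene id vectors.
#' @param universe optional full gene universe; defaults to the union of
#'   the three sets.
#' @return a `program_assignment` data.frame (`gene_id`, `label`).
#' @export
classify_programs <- function(up_20_30, up_30_60, up_20_60, universe = NULL) {
  up_20_30 <- assert_gene_set(up_20_30); up_30_60 <- assert_gene_set(up_30_60)
  up_20_60 <- assert_gene_set(up_20_60)
  genes <- if (is.null(universe)) sort(unique(c(up_20_30, up_30_60, up_20_60)))
           else if (inherits(universe, "gene_universe")) universe$genes
           else as.character(universe)
  a <- genes %in% up_20_30; b <- genes %in% up_30_60; c6 <- genes %in% up_20_60
  label <- rep("none", length(genes))
  label[a & b] <- "early-increasing"
  label[a & !b & c6] <- "early-stable"
  label[a & !b & !c6] <- "early-transient"
  label[!a & b] <- "late"
  structure(data.frame(gene_id = genes, label = label,
                       stringsAsFactors = FALSE),
            class = c("program_assignment", "data.frame"))
}

#' Genes carrying a given program label
#' @param assignment a [classify_programs()] result.
#' @param label one of [PROGRAM_LABELS].
#' @return character vector of gene ids.
#' @export
program_genes <- function(assignment, label) {
  if (!label %in% assignment$label && !label %in% PROGRAM_LABELS)
    stop_np("unknown program label: ", label)
  assignment$gene_id[assignment$label == label]
}

#' Program partitions
#'
#' A `program_partition` is a named list of pairwise-disjoint gene sets
#' (the Venn segments of a partition analysis).
#'
#' @param segments named list of character vectors.
#' @return a `program_partition` object.
#' @export
program_partition <- function(segments) {
  stopifnot(is.list(segments), !is.null(names(segments)))
  segments <- lapply(segments, function(s) unique(as.character(s)))
  all_genes <- unlist(segments, use.names = FALSE)
  if (anyDuplicated(all_genes))
    stop_np("partition segments are not pairwise disjoint")
  structure(segments, class = "program_partition")
}

#' @export
print.program_partition <- function(x, ...) {
  cat(sprintf("program_partition with %d segment(s):\n", length(x)))
  for (nm in names(x)) cat(sprintf("  %s: %d genes\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Split programs by knockout down-regulation
#'
#' Each non-exempt program P is split into `P^-/-` (down-regulated in the
#' knockout at day 30) and `P^WTonly`.  Exempt programs (by default the
#' `late` set, which has minimal knockout overlap) pass through intact
#' under their own name.  `none` genes are not part of the partition.
#'
#' @param assignment a [classify_programs()] result.
#' @param ko_down gene ids down-regulated in the knockout contrast.
#' @param exempt program labels not to split (default `"late"`).
#' @return a [program_partition()].
#' @export
split_by_ko <- function(assignment, ko_down, exempt = "late") {
  ko_down <- assert_gene_set(ko_down)
  bad <- setdiff(exempt, PROGRAM_LABELS)
  if (length(bad)) stop_np("unknown exempt label(s): ", paste(bad, collapse = ", "))
  segs <- list()
  for (p in setdiff(PROGRAM_LABELS, "none")) {
    members <- program_genes(assignment, p)
    if (p %in% exempt) {
      segs[[p]] <- members
    } else {
      segs[[paste0(p, "^-/-")]] <- intersect(members, ko_down)
      segs[[paste0(p, "^WTonly")]] <- setdiff(members, ko_down)
    }
  }
  program_partition(segs)
}

#' Partition a reference gene set against program segments
#'
#' Splits `reference` by its overlap with each partition segment, adds an
#' `other-reference` segment for reference genes in no program segment, and
#' retains the non-reference remainder of each segment.  The result is a
#' disjoint, exhaustive partition of `reference` union all segments.
#'
#' @param reference gene set to partition (must lie in `universe`).
#' @param partition a [program_partition()].
#' @param universe a [gene_universe()] or gene id vector.
#' @param reference_name name used in output segment labels
#'   (default `"reference"`).
#' @return a [program_partition()] with segments `"<seg>&<ref>"`,
#'   `"<seg>\\<ref>"` and `"other-<ref>"`.
#' @export
partition_by_set <- function(reference, partition, universe,
                             reference_name = "reference") {
  reference <- assert_gene_set(reference)
  genes <- if (inherits(universe, "gene_universe")) universe$genes
           else as.character(universe)
  out <- setdiff(reference, genes)
  if (length(out))
    stop_np("reference gene(s) outside universe: ",
            paste(utils::head(out, 5), collapse = ", "))
  segs <- list()
  for (nm in names(partition)) {
    s <- partition[[nm]]
    segs[[paste0(nm, "&", reference_name)]] <- intersect(s, reference)
    segs[[paste0(nm, "\\", reference_name)]] <- setdiff(s, reference)
  }
  segs[[paste0("other-", reference_name)]] <-
    setdiff(reference, unlist(partition, use.names = FALSE))
  program_partition(segs)
}
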