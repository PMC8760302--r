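#' Annotation maps
#'
#' Gene -> term annotations as a named list of character vectors.  The
#' companion ontology must know every annotated term.
#'
#' @param map named list: gene_id -> character vector of term ids.
#' @param ontology optional [ontology()] to validate terms against.
#' @return an `annotation_map` (named list).
#' @export
annotation_map <- function(map, ontology = NULL) {
  stopifnot(is.list(map), !is.null(names(map)))
  map <- lapply(map, function(x) unique(as.character(x)))
  if (!is.null(ontology)) {
    unknown <- setdiff(unique(unlist(map, use.names = FALSE)), ontology$terms$id)
    if (length(unknown))
      stop_np("annotation(s) to unknown term(s): ",
              paste(utils::head(unknown, 5), collapse = ", "))
  }
  structure(map, class = "annotation_map")
}

#' Read gene -> term annotations from a TSV file
#'
#' Expects columns `gene_id`, `term_id` and optionally `evidence` and
#' `qualifier`.  When `filter_evidence` is TRUE, rows with evidence codes
#' IEA, NAS or RCA and rows carrying a NOT qualifier are removed before
#' building the map (the standard curation filter for over-representation
#' work).
#'
#' @param path TSV path.
#' @param ontology optional [ontology()] for validation.
#' @param filter_evidence drop IEA/NAS/RCA evidence and NOT qualifiers.
#' @return an [annotation_map()].
#' @export
read_annotations <- function(path, ontology = NULL, filter_evidence = TRUE) {
  df <- read_table(path, schema_annotations)
  if (filter_evidence) {
    if ("evidence" %in% names(df))
      df <- df[!df$evidence %in% c("IEA", "NAS", "RCA"), , drop = FALSE]
    if ("qualifier" %in% names(df))
      df <- df[!grepl("\\bNOT\\b", df$qualifier), , drop = FALSE]
  }
  annotation_map(split(df$term_id, df$gene_id), ontology)
}

#' Propagate annotations to all ancestor terms
#'
#' Closes each gene's term set under the ancestor relation (`is_a` and
#' `part_of` treated identically): a gene annotated to a term is annotated
#' to all parents of that term.  Idempotent and monotone.
#'
#' @param ontology an [ontology()].
#' @param annotations an [annotation_map()].
#' @return the propagated [annotation_map()].
#' @export
propagate_annotations <- function(ontology, annotations) {
  stopifnot(inherits(ontology, "ontology"))
  terms_used <- unique(unlist(annotations, use.names = FALSE))
  unknown <- setdiff(terms_used, ontology$terms$id)
  if (length(unknown))
    stop_np("annotation(s) to unknown term(s): ",
            paste(utils::head(unknown, 5), collapse = ", "))
  closure <- lapply(stats::setNames(terms_used, terms_used), function(t)
    c(t, ontology_ancestors(ontology, t)))
  out <- lapply(annotations, function(ts)
    sort(unique(unlist(closure[ts], use.names = FALSE))))
  annotation_map(out, ontology)
}

#' Invert annotations into size-filtered term gene sets
#'
#' Inverts gene -> terms to term -> genes and retains terms whose gene
#' count lies in `[min_size, max_size]` (inclusive at both ends).
#' Annotations should be propagated first.
#'
#' @param annotations an [annotation_map()].
#' @param min_size,max_size inclusive size bounds (defaults 20 and 2000).
#' @param ontology optional [ontology()]; when given, term names are used
#'   as set descriptions.
#' @return a [gene_set_collection()] keyed by term id.
#' @export
terms_to_sets <- function(annotations, min_size = 20, max_size = 2000,
                          ontology = NULL) {
  if (min_size > max_size) stop_np("min_size must not exceed max_size")
  genes <- rep(names(annotations), lengths(annotations))
  terms <- unlist(annotations, use.names = FALSE)
  inv <- split(genes, terms)
  inv <- lapply(inv, unique)
  sizes <- lengths(inv)
  inv <- inv[sizes >= min_size & sizes <= max_size]
  desc <- if (!is.null(ontology))
    stats::setNames(ontology$terms$name, ontology$terms$id) else NULL
  gene_set_collection(lapply(stats::setNames(names(inv), names(inv)), function(t)
    list(description = unname(desc[t]) %||% t, genes = inv[[t]])))
}

#' Select the top fraction of genes by specificity score
#'
#' Ranks eligible genes by score (descending) and returns the top
#' `floor(fraction * n_eligible)`; when `require_positive` only genes with
#' score > 0 are eligible.  Ties at the cut are broken by lexicographic
#' gene id, so the result is deterministic.
#'
#' @param scores named numeric vector (gene_id -> score) or data.frame with
#'   columns `gene_id`, `score`.
#' @param fraction proportion in (0, 1] (default 0.10).
#' @param require_positive restrict eligibility to score > 0 (default TRUE).
#' @return character vector of selected gene ids.
#' @export
top_fraction_by_score <- function(scores, fraction = 0.10,
                                  require_positive = TRUE) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$score, scores$gene_id)
  if (!is.numeric(scores) || is.null(names(scores)))
    stop_np("'scores' must be a named numeric vector or a gene_id/score table")
  if (any(!is.finite(scores))) stop_np("scores must be finite")
  if (!(fraction > 0 && fraction <= 1)) stop_np("'fraction' must be in (0, 1]")
  if (require_positive) scores <- scores[scores > 0]
  if (length(scores) == 0) stop_np("no eligible genes")
  ord <- order(-scores, names(scores))
  k <- floor(fraction * length(scores))
  names(scores)[ord][seq_len(k)]
}
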