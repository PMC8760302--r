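#' Fisher's exact over-representation test
#'
#' Tests whether a query gene set overlaps a term gene set more (or less)
#' than expected against a fixed expressed-gene background.  The 2x2 table
#' is `a = |q & t|`, `b = |q \ t|`, `c = |t \ q|`,
#' `d = |bg \ (q | t)|`.  The odds ratio is the sample odds ratio
#' `(a*d)/(b*c)` (infinite when `b*c = 0` and `a*d > 0`).  P-values are
#' exact hypergeometric: the one-sided "greater" p is the upper tail at
#' `a`; the two-sided p sums all table probabilities not exceeding the
#' probability of the observed table (the standard exact convention, with
#' a 1 + 1e-7 relative tolerance against floating-point ties).
#'
#' @param query,term gene id vectors, subsets of `background`.
#' @param background background gene id vector (the expressed universe).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return an `overrep_result`: one-row data.frame with `n_overlap`,
#'   `odds_ratio`, `p_raw` and the table margins.
#' @export
fisher_overrep <- function(query, term, background,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  query <- assert_gene_set(query); term <- assert_gene_set(term)
  background <- assert_gene_set(background)
  if (length(background) == 0) stop_np("empty background")
  outq <- setdiff(query, background); outt <- setdiff(term, background)
  if (length(outq) || length(outt))
    stop_np("gene(s) outside background: ",
            paste(utils::head(c(outq, outt), 5), collapse = ", "))
  a <- length(intersect(query, term))
  b <- length(query) - a
  cc <- length(term) - a
  d <- length(background) - a - b - cc
  or <- if (b * cc == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * cc)
  p <- hyper_pvalue(a, m = length(term), n = length(background) - length(term),
                    k = length(query), alternative = alternative)
  structure(data.frame(n_overlap = a, odds_ratio = or, p_raw = p,
                       n_query = length(query), n_term = length(term),
                       n_background = length(background),
                       alternative = alternative, stringsAsFactors = FALSE),
            class = c("overrep_result", "data.frame"))
}

# Exact hypergeometric p for overlap a when drawing k from m white + n black.
hyper_pvalue <- function(a, m, n, k, alternative) {
  lo <- max(0L, k - n); hi <- min(k, m)
  switch(alternative,
    greater = stats::phyper(a - 1, m, n, k, lower.tail = FALSE),
    less = stats::phyper(a, m, n, k),
    two.sided = {
      support <- lo:hi
      dens <- stats::dhyper(support, m, n, k)
      obs <- stats::dhyper(a, m, n, k)
      min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
    })
}

#' Bonferroni adjustment
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param m number of tests (defaults to `length(pvals)`).
#' @return `pmin(1, pvals * m)`, order preserved.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (length(m) != 1 || !is.finite(m) || m <= 0) stop_np("'m' must be a positive count")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop_np("p-values outside [0, 1]")
  pmin(1, pvals * m)
}

#' Iterative refinement of over-represented terms
#'
#' Identifies a semi-independent subset of enriched terms.  At each
#' iteration every surviving term is tested against the query
#' ([fisher_overrep()], Bonferroni-corrected for the number of sets tested
#' in that iteration) and terms with corrected p >= `alpha` are discarded.
#' The surviving term with the largest odds ratio (ties broken by smaller
#' raw p, then lexicographic name) is appended to the output and its
#' current genes are removed from all other surviving terms, so term gene
#' sets are cumulatively depleted across iterations.  The loop ends when no
#' term survives; the result is deterministic and invariant to the input
#' term order.
#'
#' @param query gene set of interest (e.g. knockout down-regulated genes).
#' @param terms a [gene_set_collection()] of candidate terms (normally
#'   pre-filtered to those significant for the query).
#' @param background background gene id vector.
#' @param alpha corrected significance threshold (default 0.05).
#' @param alternative test sidedness passed to [fisher_overrep()].
#' @return data.frame with one row per selected term: `term`, `n_overlap`,
#'   `odds_ratio`, `p_raw`, `p_corrected`, `iteration` (selection order).
#' @export
refine_terms <- function(query, terms, background, alpha = 0.05,
                         alternative = "greater") {
  query <- assert_gene_set(query)
  empty <- data.frame(term = character(0), n_overlap = integer(0),
                      odds_ratio = numeric(0), p_raw = numeric(0),
                      p_corrected = numeric(0), iteration = integer(0),
                      stringsAsFactors = FALSE)
  if (length(terms) == 0) return(empty)
  current <- lapply(names(terms), function(nm) terms[[nm]]$genes)
  names(current) <- names(terms)
  out <- empty
  iteration <- 0L
  repeat {
    iteration <- iteration + 1L
    m <- length(current)
    if (m == 0) break
    res <- do.call(rbind, lapply(names(current), function(nm) {
      r <- fisher_overrep(query, current[[nm]], background, alternative)
      data.frame(term = nm, n_overlap = r$n_overlap,
                 odds_ratio = r$odds_ratio, p_raw = r$p_raw,
                 stringsAsFactors = FALSE)
    }))
    res$p_corrected <- bonferroni(res$p_raw, m)
    res <- res[res$p_corrected < alpha, , drop = FALSE]
    if (nrow(res) == 0) break
    # largest OR; ties -> smaller raw p -> lexicographic name
    or_key <- ifelse(is.nan(res$odds_ratio), -Inf, res$odds_ratio)
    best <- order(-or_key, res$p_raw, res$term)[1]
    sel <- res[best, , drop = FALSE]
    sel$iteration <- iteration
    out <- rbind(out, sel)
    removed <- current[[sel$term]]
    survivors <- setdiff(res$term, sel$term)  # significant this iteration, not selected
    current <- lapply(current[survivors], function(g) setdiff(g, removed))
  }
  rownames(out) <- NULL
  out
}
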