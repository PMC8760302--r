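#' De novo mutation datasets
#'
#' Per-cohort trio counts and observed de novo loss-of-function (LoF)
#' mutation counts per gene.
#'
#' @param cohorts named list: cohort -> `list(n_trios, counts)` where
#'   `counts` is a named non-negative integer vector (gene_id -> count;
#'   genes absent from `counts` have zero mutations).
#' @return a `denovo_dataset` object.
#' @export
denovo_dataset <- function(cohorts) {
  stopifnot(is.list(cohorts), !is.null(names(cohorts)))
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    if (is.null(co$n_trios) || co$n_trios < 0)
      stop_np("cohort '", nm, "': invalid n_trios")
    if (length(co$counts) && (is.null(names(co$counts)) || any(co$counts < 0)))
      stop_np("cohort '", nm, "': counts must be a named non-negative vector")
  }
  structure(cohorts, class = "denovo_dataset")
}

#' @export
print.denovo_dataset <- function(x, ...) {
  cat(sprintf("denovo_dataset with %d cohort(s):\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %s: %d trios, %d mutations\n", nm, x[[nm]]$n_trios,
                sum(x[[nm]]$counts)))
  invisible(x)
}

#' Expected de novo LoF count for a gene set
#'
#' The standard trio expectation `2 * n_trios * sum(mu_g)` over the set
#' (two transmitted haplotypes per trio), where `mu_g` is the per-gene LoF
#' mutation rate in mutations per haploid genome per generation.
#'
#' @param rates named numeric vector (gene_id -> mu) or data.frame with
#'   columns `gene_id`, `mu_lof`.
#' @param n_trios number of parent-offspring trios.
#' @param genes gene ids of the set.
#' @return expected count (numeric scalar).
#' @export
expected_counts <- function(rates, n_trios, genes) {
  if (is.data.frame(rates))
    rates <- stats::setNames(rates$mu_lof, rates$gene_id)
  genes <- assert_gene_set(genes)
  miss <- setdiff(genes, names(rates))
  if (length(miss))
    stop_np("missing mutation rate for gene(s): ",
            paste(utils::head(miss, 5), collapse = ", "))
  if (any(rates[genes] < 0)) stop_np("mutation rates must be non-negative")
  2 * n_trios * sum(rates[genes])
}

#' Exact two-sided Poisson rate-ratio test
#'
#' Compares the observed/expected mutation rate inside a gene set with the
#' rate in all other expressed genes.  Conditional on the total
#' `T = obs_in + obs_out`, the inside count is Binomial(T, pi) with
#' `pi = exp_in / (exp_in + exp_out)` under the null of equal rates; the
#' two-sided p sums binomial probabilities not exceeding the probability of
#' the observed count (minimum-likelihood method, as in
#' [stats::poisson.test()] for rate comparisons), capped at 1.
#'
#' @param obs_in,obs_out observed counts (non-negative integers).
#' @param exp_in,exp_out expected counts (positive).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return one-row data.frame with `obs_in`, `exp_in`, `obs_out`,
#'   `exp_out`, `rate_ratio`, `p`, `degenerate`.
#' @export
rate_ratio_test <- function(obs_in, exp_in, obs_out, exp_out,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (exp_in <= 0 || exp_out <= 0)
    stop_np("expected counts must be positive on both sides")
  if (obs_in < 0 || obs_out < 0) stop_np("observed counts must be non-negative")
  T <- obs_in + obs_out
  degenerate <- (T == 0)
  rr <- if (degenerate) 1 else (obs_in / exp_in) / (obs_out / exp_out)
  if (degenerate) {
    p <- 1
  } else {
    pi0 <- exp_in / (exp_in + exp_out)
    p <- switch(alternative,
      greater = stats::pbinom(obs_in - 1, T, pi0, lower.tail = FALSE),
      less = stats::pbinom(obs_in, T, pi0),
      two.sided = {
        dens <- stats::dbinom(0:T, T, pi0)
        min(1, sum(dens[dens <= dens[obs_in + 1] * (1 + 1e-7)]))
      })
  }
  data.frame(obs_in = obs_in, exp_in = exp_in, obs_out = obs_out,
             exp_out = exp_out, rate_ratio = rr, p = p,
             degenerate = degenerate, alternative = alternative,
             stringsAsFactors = FALSE)
}

#' Rate-ratio scan over a program partition
#'
#' For every cohort x segment, compares the de novo LoF burden inside the
#' segment against all other expressed genes
#' (`universe \ segment`), with expected counts from the per-gene rates,
#' and Bonferroni-corrects per cohort over the number of segments.
#'
#' @param dataset a [denovo_dataset()].
#' @param partition a [program_partition()] (segments within `universe`).
#' @param universe a [gene_universe()] or gene id vector.
#' @param rates per-gene mutation rates as in [expected_counts()].
#' @param alternative passed to [rate_ratio_test()] (default two-sided).
#' @return data.frame: `cohort`, `segment`, counts/expectations,
#'   `rate_ratio`, `p`, `p_corrected`.
#' @export
denovo_partition_scan <- function(dataset, partition, universe, rates,
                                  alternative = "two.sided") {
  genes <- if (inherits(universe, "gene_universe")) universe$genes
           else as.character(universe)
  if (is.data.frame(rates))
    rates <- stats::setNames(rates$mu_lof, rates$gene_id)
  out <- setdiff(unlist(partition, use.names = FALSE), genes)
  if (length(out))
    stop_np("partition gene(s) outside universe: ",
            paste(utils::head(out, 5), collapse = ", "))
  rows <- list()
  for (co in names(dataset)) {
    n_trios <- dataset[[co]]$n_trios
    counts <- dataset[[co]]$counts
    cnt <- stats::setNames(rep(0, length(genes)), genes)
    shared <- intersect(names(counts), genes)
    cnt[shared] <- counts[shared]
    total_obs <- sum(cnt)
    total_exp <- expected_counts(rates, n_trios, genes)
    cohort_rows <- lapply(names(partition), function(seg) {
      sg <- partition[[seg]]
      obs_in <- sum(cnt[sg])
      exp_in <- expected_counts(rates, n_trios, sg)
      r <- rate_ratio_test(obs_in, exp_in, total_obs - obs_in,
                           total_exp - exp_in, alternative = alternative)
      cbind(data.frame(cohort = co, segment = seg, stringsAsFactors = FALSE), r)
    })
    cohort_df <- do.call(rbind, cohort_rows)
    cohort_df$p_corrected <- bonferroni(cohort_df$p, length(partition))
    rows[[co]] <- cohort_df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
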