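#' Gene association statistics
#'
#' Per-gene association Z-scores on the standard-normal scale (the
#' gene-level output of a GWAS gene analysis), with optional named numeric
#' covariates such as gene length or confounder loadings.
#'
#' @param df data.frame with columns `gene_id`, `z`, and optionally `p`
#'   plus covariate columns prefixed `cov_`.
#' @return a `gene_assoc_stats` data.frame.
#' @export
gene_assoc_stats <- function(df) {
  stopifnot(is.data.frame(df), all(c("gene_id", "z") %in% names(df)))
  if (anyDuplicated(df$gene_id)) stop_np("duplicate gene ids in stats")
  if (any(!is.finite(df$z))) stop_np("non-finite z score(s)")
  if ("p" %in% names(df) && any(df$p <= 0 | df$p > 1, na.rm = TRUE))
    stop_np("p-values outside (0, 1]")
  structure(df, class = c("gene_assoc_stats", "data.frame"))
}

#' Convert a gene p-value to a signed Z-score
#'
#' Probit mapping `z = qnorm(1 - p)` with the given direction of effect
#' applied; `z_from_p(0.5) == 0`.
#'
#' @param p p-value(s) in (0, 1).
#' @param direction +1 or -1 (recycled).
#' @return numeric z score(s).
#' @export
z_from_p <- function(p, direction = 1) {
  if (any(p <= 0)) stop_np("p = 0 maps to an infinite z score")
  if (any(p >= 1)) stop_np("p = 1 maps to z = -Inf; clamp upstream if intended")
  sign(direction) * stats::qnorm(p, lower.tail = FALSE)
}

#' Competitive gene-set enrichment on gene-level statistics
#'
#' Ordinary least squares of the gene Z-score on an intercept, the 0/1 set
#' indicator, 0/1 indicators for each conditioning set, and any named
#' numeric covariates.  `beta` is the set-indicator coefficient; its p-value
#' comes from the t distribution with residual degrees of freedom
#' (one-sided "greater" by default, the convention for risk-enrichment
#' scans).  By the Frisch-Waugh-Lovell theorem, conditioning through
#' covariate inclusion is identical to residualizing the Z-scores and the
#' indicator on the conditioning columns first
#' ("condition-residualize" semantics).
#'
#' Gene-gene correlation is not modelled: genes are treated as independent,
#' which is this package's documented deviation from LD-aware
#' implementations; calibration holds under the independence simulation.
#'
#' @param stats a [gene_assoc_stats()] table.
#' @param set gene ids of the set under test (subset of the stats universe).
#' @param conditioning list of gene sets to condition on (each becomes a
#'   0/1 covariate); may be named.
#' @param covariates character vector naming covariate columns of `stats`.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param min_size minimum genes required both inside and outside the set
#'   (default 10).
#' @param set_name label recorded in the result row (default `"set"`).
#' @return an `enrichment_result`: one-row data.frame with `set_name`,
#'   `n_genes`, `beta`, `se`, `stat`, `df`, `p`, `alternative`.
#' @export
competitive_enrichment <- function(stats, set, conditioning = list(),
                                   covariates = character(0),
                                   alternative = c("greater", "two.sided"),
                                   min_size = 10, set_name = "set") {
  alternative <- match.arg(alternative)
  set <- assert_gene_set(set)
  genes <- stats$gene_id
  out <- setdiff(set, genes)
  if (length(out))
    stop_np("set gene(s) missing from stats universe: ",
            paste(utils::head(out, 5), collapse = ", "))
  ind <- as.numeric(genes %in% set)
  n_in <- sum(ind); n_out <- length(genes) - n_in
  if (n_in < min_size || n_out < min_size)
    stop_np(sprintf("need >= %d genes inside and outside the set (have %d/%d)",
                    min_size, n_in, n_out))
  X <- cbind(`(Intercept)` = 1, set = ind)
  if (length(conditioning)) {
    cn <- names(conditioning) %||% paste0("cond", seq_along(conditioning))
    cn[cn == ""] <- paste0("cond", which(cn == ""))
    for (i in seq_along(conditioning)) {
      cs <- assert_gene_set(conditioning[[i]])
      miss <- setdiff(cs, genes)
      if (length(miss))
        stop_np("conditioning gene(s) missing from stats universe: ",
                paste(utils::head(miss, 5), collapse = ", "))
      X <- cbind(X, as.numeric(genes %in% cs))
      colnames(X)[ncol(X)] <- cn[i]
    }
  }
  for (cv in covariates) {
    if (!cv %in% names(stats)) stop_np("unknown covariate column: ", cv)
    X <- cbind(X, stats[[cv]])
    colnames(X)[ncol(X)] <- cv
  }
  fit <- stats::lm.fit(X, stats$z)
  if (is.na(fit$coefficients["set"]) || fit$rank < ncol(X))
    stop_np("degenerate design: set indicator is collinear with the ",
            "intercept/conditioning columns (e.g. set equals the universe ",
            "or a conditioning set)")
  df_resid <- length(genes) - fit$rank
  if (df_resid <= 0) stop_np("no residual degrees of freedom")
  sigma2 <- sum(fit$residuals^2) / df_resid
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  beta <- unname(fit$coefficients["set"])
  tstat <- beta / se
  p <- switch(alternative,
              greater = stats::pt(tstat, df_resid, lower.tail = FALSE),
              two.sided = 2 * stats::pt(abs(tstat), df_resid, lower.tail = FALSE))
  structure(data.frame(set_name = set_name, n_genes = n_in, beta = beta,
                       se = se, stat = tstat, df = df_resid, p = p,
                       alternative = alternative, stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Compare two enrichment coefficients
#'
#' Tests whether common-variant enrichment differs between two gene sets:
#' `d = beta1 - beta2`, `SE(d) = sqrt(SE(beta1)^2 + SE(beta2)^2)`, and
#' `z = d / SE(d)` is compared to a standard normal.
#'
#' @param r1,r2 [competitive_enrichment()] results from the same model
#'   family/universe.
#' @param alternative `"greater"` (is `beta1 > beta2`?) or `"two.sided"`.
#' @return one-row data.frame with `d`, `se_d`, `z`, `p`.
#' @export
compare_coefficients <- function(r1, r2,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- r1$beta - r2$beta
  se_d <- sqrt(r1$se^2 + r2$se^2)
  if (!is.finite(se_d) || se_d == 0) stop_np("SE(d) is zero or non-finite")
  z <- d / se_d
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  data.frame(set1 = r1$set_name, set2 = r2$set_name, d = d, se_d = se_d,
             z = z, p = p, alternative = alternative, stringsAsFactors = FALSE)
}

#' Enrichment scan over a program partition
#'
#' Runs [competitive_enrichment()] for every partition segment under a
#' shared conditioning model (optionally adding one extra conditioning set,
#' e.g. the enclosing program for within-program tests) and applies
#' Bonferroni correction over the number of segments actually tested.
#' Segments below the size floor are reported as skipped rather than
#' raising an error.
#'
#' @param stats a [gene_assoc_stats()] table.
#' @param partition a [program_partition()].
#' @param conditioning list of conditioning gene sets shared by all tests.
#' @param alternative `"greater"` or `"two.sided"`.
#' @param extra_condition optional additional conditioning set applied to
#'   every segment test.
#' @param min_size size floor passed through (default 10).
#' @return data.frame with one row per segment: enrichment fields plus
#'   `p_corrected` and `skipped`.
#' @export
partition_enrichment <- function(stats, partition, conditioning = list(),
                                 alternative = c("greater", "two.sided"),
                                 extra_condition = NULL, min_size = 10) {
  alternative <- match.arg(alternative)
  cond <- conditioning
  if (!is.null(extra_condition)) cond <- c(cond, list(extra = extra_condition))
  rows <- lapply(names(partition), function(nm) {
    seg <- partition[[nm]]
    res <- tryCatch(
      competitive_enrichment(stats, seg, cond, alternative = alternative,
                             min_size = min_size, set_name = nm),
      error = function(e)
        data.frame(set_name = nm, n_genes = length(seg), beta = NA_real_,
                   se = NA_real_, stat = NA_real_, df = NA_real_, p = NA_real_,
                   alternative = alternative, stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  out$skipped <- is.na(out$p)
  m <- sum(!out$skipped)
  out$p_corrected <- ifelse(out$skipped, NA_real_, bonferroni(out$p, max(m, 1)))
  rownames(out) <- NULL
  out
}
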