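#' Pipeline configuration
#'
#' Bundles an embedded simulation config with the per-stage analysis
#' parameters.  All multiple-testing correction counts are derived from
#' the data at run time (number of partition segments, number of stage
#' pairs), never hard-coded.
#'
#' @param sim a [sim_config()].
#' @param outdir output directory for result tables.
#' @param deg_alpha Bonferroni familywise level for DEG calling.
#' @param overrep_alpha corrected threshold for term refinement.
#' @param term_min_size,term_max_size ontology term size filter.
#' @param top_fraction specificity-score top fraction.
#' @param gsea_alternative sidedness of the partition enrichment scan.
#' @param gsea_min_size segment size floor for enrichment tests.
#' @param exempt_programs program labels not split by knockout status.
#' @param sc_ddof degrees of freedom for single-cell z-scoring.
#' @param sc_paired paired stage tests (default TRUE).
#' @param seed overrides `sim$seed` when not NULL.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), outdir = tempfile("run"),
                            deg_alpha = 0.05, overrep_alpha = 0.05,
                            term_min_size = 20, term_max_size = 2000,
                            top_fraction = 0.10,
                            gsea_alternative = "greater", gsea_min_size = 10,
                            exempt_programs = "late",
                            sc_ddof = 0, sc_paired = TRUE, seed = NULL) {
  if (!is.null(seed)) sim$seed <- seed
  cfg <- as.list(environment())
  cfg$seed <- sim$seed
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns all detectable problems as a character vector of issues;
#' an empty vector means the configuration is runnable.
#'
#' @param config a [pipeline_config()].
#' @return character vector of issues (possibly empty).
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  for (a in c("deg_alpha", "overrep_alpha")) {
    v <- config[[a]]
    if (!is.numeric(v) || v <= 0 || v > 1) add(paste0(a, " out of range (0, 1]"))
  }
  if (!is.numeric(config$top_fraction) || config$top_fraction <= 0 ||
      config$top_fraction > 1)
    add("top_fraction out of range (0, 1]")
  if (config$term_min_size > config$term_max_size)
    add("term_min_size exceeds term_max_size")
  bad <- setdiff(config$exempt_programs, PROGRAM_LABELS)
  if (length(bad)) add(paste0("unknown exempt program label: ",
                              paste(bad, collapse = ", ")))
  if (!config$gsea_alternative %in% c("greater", "two.sided"))
    add("gsea_alternative must be 'greater' or 'two.sided'")
  if (!inherits(config$sim, "sim_config"))
    add("sim is not a sim_config")
  sizes <- config$sim$program_sizes
  if (is.numeric(sizes) && sum(sizes) > config$sim$n_genes)
    add("program sizes exceed n_genes")
  known_atoms <- function(nm) {
    ok <- tryCatch({
      atoms <- trimws(strsplit(nm, "&", fixed = TRUE)[[1]])
      all(vapply(atoms, function(at)
        at %in% c("all", "LoFi", PROGRAM_LABELS) ||
          grepl("\\^(-/-|WTonly)$", at), logical(1)))
    }, error = function(e) FALSE)
    ok
  }
  for (nm in names(config$sim$assoc_effects))
    if (!known_atoms(nm)) add(paste0("unknown set name in assoc_effects: ", nm))
  for (co in names(config$sim$cohorts))
    for (nm in names(config$sim$cohorts[[co]]$rate_ratio_by_segment))
      if (!known_atoms(nm))
        add(paste0("unknown set name in cohort '", co, "': ", nm))
  issues
}

log_stage <- function(...) {
  message(sprintf("stage=%s", paste0(...)))
}

#' Run the full synthetic-study analysis pipeline
#'
#' Executes simulate -> program classification -> gene-set construction ->
#' over-representation refinement -> common-variant partition enrichment ->
#' de novo rate-ratio scan -> single-cell program profiling, writing every
#' result table to `config$outdir` as TSV plus a JSON metadata file.
#' Re-running with an identical config reproduces byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return a `results_bundle`: named list of result tables plus `meta`.
#' @export
run_all <- function(config = pipeline_config()) {
  issues <- validate_config(config)
  if (length(issues))
    stop_np("invalid config: ", paste(issues, collapse = "; "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  bundle <- tryCatch({
    log_stage("simulate seed=", config$seed)
    study <- simulate_study(config$sim)
    universe <- study$universe

    stage <- "programs"
    log_stage(stage)
    expressed <- filter_expressed(study$counts)
    deg <- lapply(study$deg_tables, call_deg, alpha = config$deg_alpha)
    assignment <- classify_programs(deg$WT_20v30$up, deg$WT_30v60$up,
                                    deg$WT_20v60$up, universe = universe)
    ko_down <- deg$KO_vs_WT_day30$down
    ko_split <- split_by_ko(assignment, ko_down,
                            exempt = config$exempt_programs)

    stage <- "genesets"
    log_stage(stage)
    propagated <- propagate_annotations(study$ontology, study$annotations)
    go_sets <- terms_to_sets(propagated, config$term_min_size,
                             config$term_max_size, ontology = study$ontology)
    pyramidal_high <- top_fraction_by_score(study$scores,
                                            config$top_fraction)

    stage <- "overrep"
    log_stage(stage)
    keep <- names(go_sets)[vapply(names(go_sets), function(nm) {
      r <- fisher_overrep(ko_down, set_genes(go_sets, nm), universe$genes)
      bonferroni(r$p_raw, length(go_sets)) < config$overrep_alpha
    }, logical(1))]
    refined <- refine_terms(ko_down, go_sets[keep], universe$genes,
                            alpha = config$overrep_alpha)

    stage <- "gsea"
    log_stage(stage)
    early_segments <- program_partition(ko_split[grepl("^early-.*\\^-/-$",
                                                       names(ko_split))])
    lofi_partition <- partition_by_set(flagged_genes(universe, "LoFi"),
                                       early_segments, universe,
                                       reference_name = "LoFi")
    enrichment <- partition_enrichment(study$gene_stats, lofi_partition,
                                       conditioning = list(all_expressed =
                                                             universe$genes),
                                       alternative = config$gsea_alternative,
                                       min_size = config$gsea_min_size)

    stage <- "denovo"
    log_stage(stage)
    rate_ratios <- denovo_partition_scan(study$denovo, lofi_partition,
                                         universe, study$rates)

    stage <- "sc_profiles"
    log_stage(stage)
    sc <- filter_genes(filter_cells(study$sc))
    zs <- zscore_genes(sc, ddof = config$sc_ddof)
    means <- celltype_gene_means(zs)
    early_names <- names(early_segments)
    profiles <- do.call(rbind, lapply(early_names, function(nm)
      cbind(program = nm, program_profile(means, early_segments[[nm]]),
            stringsAsFactors = FALSE)))
    stage_tests <- do.call(rbind, lapply(early_names, function(nm)
      cbind(program = nm,
            successive_stage_tests(means, early_segments[[nm]],
                                   paired = config$sc_paired),
            stringsAsFactors = FALSE)))

    stage <- "bundle"
    log_stage(stage)
    assignment_df <- as.data.frame(assignment)
    partition_df <- data.frame(
      gene_id = unlist(lofi_partition, use.names = FALSE),
      segment = rep(names(lofi_partition), lengths(lofi_partition)),
      stringsAsFactors = FALSE)
    list(expressed = data.frame(gene_id = sort(expressed),
                                stringsAsFactors = FALSE),
         program_assignment = assignment_df,
         lofi_partition = partition_df,
         refined_terms = refined,
         enrichment = enrichment,
         rate_ratios = rate_ratios,
         sc_profiles = profiles,
         sc_stage_tests = stage_tests,
         pyramidal_high = data.frame(gene_id = sort(pyramidal_high),
                                     stringsAsFactors = FALSE))
  }, error = function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(config$outdir, "FAILED"))
    stop_np("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  for (nm in names(bundle))
    write_tsv(bundle[[nm]], file.path(config$outdir, paste0(nm, ".tsv")))
  meta <- list(seed = config$seed,
               n_genes = config$sim$n_genes,
               tables = names(bundle),
               config_hash = config_hash(config),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(config$outdir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(c(bundle, list(meta = meta)), class = "results_bundle")
}

# Stable hash of the configuration (not of timestamps).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  ser <- paste(utils::capture.output(utils::str(cfg, digits.d = 15,
                                                vec.len = 1e6)),
               collapse = "\n")
  # small polynomial rolling hash over the deparsed config; stable across
  # sessions (doubles stay exact below 2^53)
  bytes <- utf8ToInt(ser)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("results_bundle with tables:\n")
  for (nm in setdiff(names(x), "meta"))
    cat(sprintf("  %s: %d rows\n", nm, nrow(x[[nm]])))
  cat(sprintf("seed %s, config %s\n", x$meta$seed, x$meta$config_hash))
  invisible(x)
}
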