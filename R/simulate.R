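#' Simulation configuration
#'
#' Defaults describe a synthetic study shaped like the real one: a
#' 14,000-gene expressed universe (the published background holds 14,274
#' genes), four transcriptional programs whose sizes echo the reported
#' set sizes (a late set of ~1400 genes, a 20-30 upregulated pool of
#' ~3500 split across the three early programs), ~85% knockout
#' down-regulation of early programs versus ~4% of the late set,
#' association effects of 0.2 on the loss-of-function-intolerant (LoFi)
#' cores of the early-stable and early-increasing knockout segments
#' (the published coefficient scale is beta ~ 0.14), trio cohorts at
#' published scale (NDD 31,058; ASD 6,430; SZ 3,444; sibling controls
#' 1,995) with a de novo LoF rate-ratio gradient NDD 5 > ASD 3 > SZ 1.5
#' on the early LoFi segments, log-normal per-gene LoF mutation rates
#' around 5e-6 per haploid genome per generation, and a six-stage fetal
#' cortex single-cell matrix (~2300 cells) with program-shaped stage
#' profiles.
#'
#' @param n_genes expressed-universe size.
#' @param program_sizes named counts per program label.
#' @param ko_down_fraction named per-program probability of knockout
#'   down-regulation ("none" covers background genes).
#' @param deg_effect true |log2FC| of an upregulation step.
#' @param deg_noise_sd sd of log2FC noise; equal to `deg_se` by default so
#'   the Wald p-values are calibrated.
#' @param deg_se per-gene log2FC standard error used for p-values.
#' @param assoc_effects named vector: gene-set expression -> beta (Z units);
#'   names are resolved by [resolve_gene_set()].
#' @param confound_effect Z units per unit of the stored confounder.
#' @param n_background_stats genes with association statistics but outside
#'   the expressed universe (the GWAS universe is wider than the
#'   expressed one, which is what makes conditioning on "all expressed"
#'   non-degenerate).
#' @param lofi_fraction baseline LoFi probability.
#' @param lofi_program_odds odds multiplier for LoFi membership inside the
#'   three early programs.
#' @param cohorts named list: cohort -> `list(n_trios,
#'   rate_ratio_by_segment)` where the latter maps set expressions to
#'   rate-ratio multipliers.
#' @param mu_logmean,mu_logsd log-normal parameters of per-gene LoF
#'   mutation rates.
#' @param sc_celltypes named ordered vector: stage -> cells per stage.
#' @param sc_profile named list: program -> per-stage mean shift
#'   (log-TPM units, one value per stage).
#' @param dropout Bernoulli zeroing probability for single-cell values.
#' @param count_mean_log,count_mean_sd,count_mean_floor log-normal
#'   parameters (and floor) of bulk per-gene mean counts.
#' @param n_unexpressed low-expression filler genes added to the bulk
#'   count matrix (they fail the cpm filter).
#' @param n_samples bulk samples in the count matrix.
#' @param n_terms,n_signal_terms,signal_term_size,signal_fraction random
#'   ontology/annotation parameters; signal terms draw `signal_fraction`
#'   of their genes from the knockout down-regulated set.
#' @param score_shift_late specificity-score shift for late-program genes
#'   (creates the late/pyramidal-high overlap).
#' @param seed master integer seed; every generator derives its own
#'   substream from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 14000,
                       program_sizes = c("early-transient" = 1500,
                                         "early-stable" = 1200,
                                         "early-increasing" = 800,
                                         "late" = 1400),
                       ko_down_fraction = c("early-transient" = 0.85,
                                            "early-stable" = 0.85,
                                            "early-increasing" = 0.85,
                                            "late" = 0.045,
                                            "none" = 0.02),
                       deg_effect = 1,
                       deg_noise_sd = 0.15,
                       deg_se = 0.15,
                       assoc_effects = c("early-stable^-/-&LoFi" = 0.2,
                                         "early-increasing^-/-&LoFi" = 0.2),
                       confound_effect = 0,
                       n_background_stats = 4000,
                       lofi_fraction = 0.2,
                       lofi_program_odds = 3,
                       cohorts = list(
                         NDD = list(n_trios = 31058, rate_ratio_by_segment =
                           c("early-transient^-/-&LoFi" = 5,
                             "early-stable^-/-&LoFi" = 5,
                             "early-increasing^-/-&LoFi" = 5)),
                         ASD = list(n_trios = 6430, rate_ratio_by_segment =
                           c("early-transient^-/-&LoFi" = 3,
                             "early-stable^-/-&LoFi" = 3,
                             "early-increasing^-/-&LoFi" = 3)),
                         SZ = list(n_trios = 3444, rate_ratio_by_segment =
                           c("early-transient^-/-&LoFi" = 1.5,
                             "early-stable^-/-&LoFi" = 1.5,
                             "early-increasing^-/-&LoFi" = 1.5)),
                         SIB = list(n_trios = 1995,
                                    rate_ratio_by_segment = numeric(0))),
                       mu_logmean = log(5e-6),
                       mu_logsd = 1,
                       sc_celltypes = c("RG-early" = 150, "RG" = 500,
                                        "IPC" = 250, "Transitioning" = 250,
                                        "Newborn" = 450, "Developing" = 700),
                       sc_profile = list(
                         "early-transient" = c(0, 0.3, 0.6, 1.0, 0.4, 0),
                         "early-stable" = c(0, 0.2, 0.5, 1.0, 1.0, 1.0),
                         "early-increasing" = c(0, 0.2, 0.4, 0.6, 0.8, 1.0)),
                       dropout = 0.3,
                       count_mean_log = log(300), count_mean_sd = 0.8,
                       count_mean_floor = 30, n_unexpressed = 500,
                       n_samples = 12,
                       n_terms = 60, n_signal_terms = 5,
                       signal_term_size = 200, signal_fraction = 0.7,
                       score_shift_late = 1.5,
                       seed = 1) {
  cfg <- as.list(environment())
  if (sum(program_sizes) > n_genes)
    stop_np("program sizes exceed n_genes")
  assert_prob(unname(ko_down_fraction), "ko_down_fraction")
  assert_prob(lofi_fraction, "lofi_fraction")
  assert_prob(dropout, "dropout")
  assert_prob(signal_fraction, "signal_fraction")
  for (co in names(cohorts)) {
    rr <- cohorts[[co]]$rate_ratio_by_segment
    if (length(rr) && any(rr <= 0))
      stop_np("cohort '", co, "': rate ratios must be positive")
  }
  if (length(sc_celltypes) == 0) stop_np("stage list must be non-empty")
  for (p in names(sc_profile))
    if (length(sc_profile[[p]]) != length(sc_celltypes))
      stop_np("sc_profile for '", p, "' must give one shift per stage")
  structure(cfg, class = "sim_config")
}

#' Resolve a gene-set expression against simulation ground truth
#'
#' Set expressions combine atoms with `&` (intersection).  Atoms:
#' a program label (`early-transient`, ...), a knockout split segment
#' (`<program>^-/-` or `<program>^WTonly`), the flag `LoFi`, or `all`.
#'
#' @param name set expression.
#' @param universe a [gene_universe()] from [simulate_universe()].
#' @return character vector of gene ids.
#' @export
resolve_gene_set <- function(name, universe) {
  atoms <- strsplit(name, "&", fixed = TRUE)[[1]]
  genes <- universe$genes
  sel <- rep(TRUE, length(genes))
  prog <- universe$flags_meta$program
  ko <- universe$flags$ko_down
  for (at in atoms) {
    at <- trimws(at)
    sel <- sel & if (at == "all") TRUE
    else if (at == "LoFi") universe$flags$LoFi
    else if (at %in% PROGRAM_LABELS) prog == at
    else if (grepl("\\^-/-$", at)) {
      p <- sub("\\^-/-$", "", at)
      if (!p %in% PROGRAM_LABELS) stop_np("unknown set expression atom: ", at)
      prog == p & ko
    } else if (grepl("\\^WTonly$", at)) {
      p <- sub("\\^WTonly$", "", at)
      if (!p %in% PROGRAM_LABELS) stop_np("unknown set expression atom: ", at)
      prog == p & !ko
    } else stop_np("unknown set expression atom: ", at)
  }
  genes[sel]
}

#' Simulate the expressed-gene universe and its ground truth
#'
#' Assigns program labels without replacement according to
#' `program_sizes`, draws knockout down-regulation flags per program, and
#' draws LoFi flags with the baseline odds multiplied by
#' `lofi_program_odds` inside the three early programs.  Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `universe` (a [gene_universe()] carrying `LoFi` and
#'   `ko_down` flags plus the true program labels) and `truth` (per-gene
#'   label/flag vectors and the config used).
#' @export
simulate_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "universe"))
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  label <- rep("none", n)
  shuffled <- sample.int(n)
  pos <- 1
  for (p in names(config$program_sizes)) {
    k <- config$program_sizes[[p]]
    label[shuffled[pos:(pos + k - 1)]] <- p
    pos <- pos + k
  }
  kf <- config$ko_down_fraction
  ko <- stats::rbinom(n, 1, unname(kf[label])) == 1
  f <- config$lofi_fraction
  odds <- f / (1 - f)
  early <- label %in% c("early-transient", "early-stable", "early-increasing")
  p_lofi <- ifelse(early,
                   (odds * config$lofi_program_odds) /
                     (1 + odds * config$lofi_program_odds),
                   f)
  lofi <- stats::rbinom(n, 1, p_lofi) == 1
  uni <- gene_universe(genes, flags = list(LoFi = lofi, ko_down = ko))
  uni$flags_meta <- list(program = label)
  truth <- list(program = stats::setNames(label, genes),
                ko_down = stats::setNames(ko, genes),
                lofi = stats::setNames(lofi, genes),
                config = config)
  list(universe = uni, truth = truth)
}

#' Simulate timecourse differential-expression tables
#'
#' Emits the four contrasts `WT_20v30`, `WT_30v60`, `WT_20v60` and
#' `KO_vs_WT_day30`.  True log2 fold-changes follow the program algebra
#' (early-increasing up in both WT steps and cumulatively over 20-60;
#' early-stable up in 20-30 and 20-60 only; early-transient up in 20-30
#' then back down 30-60; late up in 30-60 and 20-60 only), knockout
#' down-regulated genes get `-deg_effect` in the knockout contrast, noise
#' is Normal(0, `deg_noise_sd`), and p-values are two-sided normal tails
#' of `log2fc / deg_se`.
#'
#' @param universe,truth from [simulate_universe()].
#' @param config a [sim_config()].
#' @return named list of DEG data.frames (`gene_id`, `log2fc`, `pvalue`)
#'   with a `contrast` attribute.
#' @export
simulate_deg_tables <- function(universe, truth, config) {
  set.seed(substream_seed(config$seed, "deg"))
  genes <- universe$genes
  lab <- truth$program[genes]
  e <- config$deg_effect
  fc <- list(
    WT_20v30 = ifelse(lab %in% c("early-transient", "early-stable",
                                 "early-increasing"), e, 0),
    WT_30v60 = ifelse(lab == "early-increasing", e,
               ifelse(lab == "late", e,
               ifelse(lab == "early-transient", -e, 0))),
    WT_20v60 = ifelse(lab == "early-increasing", 2 * e,
               ifelse(lab %in% c("early-stable", "late"), e, 0)),
    KO_vs_WT_day30 = ifelse(truth$ko_down[genes], -e, 0))
  out <- lapply(names(fc), function(ct) {
    obs <- fc[[ct]] + stats::rnorm(length(genes), 0, config$deg_noise_sd)
    p <- 2 * stats::pnorm(-abs(obs) / config$deg_se)
    df <- data.frame(gene_id = genes, log2fc = obs, pvalue = p,
                     stringsAsFactors = FALSE)
    attr(df, "contrast") <- ct
    df
  })
  stats::setNames(out, names(fc))
}

#' Simulate gene-level association statistics
#'
#' `Z_g = sum_s beta_s 1[g in s] + delta c_g + eps_g` with standard-normal
#' noise and a stored standard-normal confounder `c_g`.  In addition to the
#' expressed universe, `n_background_stats` pure-null genes are emitted so
#' the statistics universe is wider than the expressed one (as for a
#' genome-wide gene analysis).
#'
#' @inheritParams simulate_deg_tables
#' @return a [gene_assoc_stats()] table with columns `gene_id`, `z`,
#'   `cov_confound`.
#' @export
simulate_gene_stats <- function(universe, truth, config) {
  set.seed(substream_seed(config$seed, "gwas"))
  genes <- c(universe$genes,
             if (config$n_background_stats > 0)
               sprintf("bg%05d", seq_len(config$n_background_stats)))
  mu <- stats::setNames(rep(0, length(genes)), genes)
  for (s in names(config$assoc_effects)) {
    members <- resolve_gene_set(s, universe)
    mu[members] <- mu[members] + config$assoc_effects[[s]]
  }
  conf <- stats::rnorm(length(genes))
  z <- mu + config$confound_effect * conf + stats::rnorm(length(genes))
  gene_assoc_stats(data.frame(gene_id = genes, z = unname(z),
                              cov_confound = conf, stringsAsFactors = FALSE))
}

#' Simulate de novo LoF mutation data
#'
#' Per-gene LoF mutation rates are log-normal; for each cohort, per-gene
#' counts are Poisson with mean `2 * n_trios * mu_g * rho_g`, where `rho`
#' is the cohort's injected rate-ratio multiplier on its configured
#' segments (1 elsewhere; control cohorts use rho = 1 everywhere).
#'
#' @inheritParams simulate_deg_tables
#' @return list with `dataset` (a [denovo_dataset()]) and `rates`
#'   (named per-gene mu vector).
#' @export
simulate_denovo <- function(universe, truth, config) {
  set.seed(substream_seed(config$seed, "denovo"))
  genes <- universe$genes
  mu <- stats::setNames(
    stats::rlnorm(length(genes), config$mu_logmean, config$mu_logsd), genes)
  cohorts <- list()
  for (co in names(config$cohorts)) {
    spec <- config$cohorts[[co]]
    rho <- stats::setNames(rep(1, length(genes)), genes)
    for (s in names(spec$rate_ratio_by_segment)) {
      members <- resolve_gene_set(s, universe)
      rho[members] <- spec$rate_ratio_by_segment[[s]]
    }
    lambda <- 2 * spec$n_trios * mu * rho
    counts <- stats::rpois(length(genes), lambda)
    names(counts) <- genes
    cohorts[[co]] <- list(n_trios = spec$n_trios,
                          counts = counts[counts > 0])
  }
  list(dataset = denovo_dataset(cohorts), rates = mu)
}

#' Simulate a stage-labelled single-cell expression matrix
#'
#' Per cell, log-TPM is Normal(per-gene baseline + per-stage program
#' shift, 1), exponentiated to TPM and zeroed with probability `dropout`.
#' Cells carry ordered stage labels from `sc_celltypes`.
#'
#' @inheritParams simulate_deg_tables
#' @return list with `matrix` (an [sc_matrix()]) and `stage_means` (the
#'   true genes x stages log-TPM means).
#' @export
simulate_sc <- function(universe, truth, config) {
  set.seed(substream_seed(config$seed, "sc"))
  genes <- universe$genes
  stages <- names(config$sc_celltypes)
  baseline <- stats::rnorm(length(genes), 1, 0.5)
  shift <- matrix(0, length(genes), length(stages),
                  dimnames = list(genes, stages))
  for (p in names(config$sc_profile)) {
    members <- truth$program[genes] == p
    shift[members, ] <- matrix(config$sc_profile[[p]], sum(members),
                               length(stages), byrow = TRUE)
  }
  stage_means <- shift + baseline
  n_cells <- sum(config$sc_celltypes)
  cell_stage <- rep(seq_along(stages), config$sc_celltypes)
  cells <- sprintf("c%05d", seq_len(n_cells))
  logtpm <- stage_means[, cell_stage, drop = FALSE] +
    matrix(stats::rnorm(length(genes) * n_cells), length(genes), n_cells)
  tpm <- exp(logtpm)
  if (config$dropout > 0)
    tpm[stats::runif(length(tpm)) < config$dropout] <- 0
  labels <- stats::setNames(stages[cell_stage], cells)
  list(matrix = sc_matrix(tpm, genes, cells, labels, stage_order = stages),
       stage_means = stage_means)
}

#' Simulate a bulk count matrix
#'
#' Per-gene mean counts are log-normal with a floor, so every universe
#' gene clears the cpm filter with overwhelming probability; a block of
#' low-expression filler genes fails it.
#'
#' @inheritParams simulate_deg_tables
#' @return genes x samples integer matrix with gene-id rownames.
#' @export
simulate_counts <- function(universe, truth, config) {
  set.seed(substream_seed(config$seed, "counts"))
  genes <- universe$genes
  mean_hi <- pmax(stats::rlnorm(length(genes), config$count_mean_log,
                                config$count_mean_sd),
                  config$count_mean_floor)
  filler <- sprintf("low%05d", seq_len(config$n_unexpressed))
  mean_lo <- stats::runif(config$n_unexpressed, 0, 0.1)
  all_means <- c(mean_hi, mean_lo)
  m <- matrix(stats::rpois(length(all_means) * config$n_samples,
                           rep(all_means, config$n_samples)),
              nrow = length(all_means))
  rownames(m) <- c(genes, filler)
  colnames(m) <- sprintf("s%02d", seq_len(config$n_samples))
  m
}

#' Simulate a random ontology with annotation signal
#'
#' Builds a random DAG of `n_terms` terms (each non-root term has 1-2
#' parents among earlier terms), annotates genes to terms at random, and
#' plants `n_signal_terms` terms whose genes are drawn preferentially
#' (`signal_fraction`) from the knockout down-regulated set, so
#' over-representation analysis of that set has known positives.
#'
#' @inheritParams simulate_deg_tables
#' @return list with `ontology`, `annotations` (an [annotation_map()]),
#'   `signal_terms` (ids of the planted terms) and `scores` (per-gene
#'   specificity scores, shifted upward for late-program genes).
#' @export
simulate_annotations <- function(universe, truth, config) {
  set.seed(substream_seed(config$seed, "annot"))
  genes <- universe$genes
  n_terms <- config$n_terms
  ids <- sprintf("TERM%04d", seq_len(n_terms))
  # the last n_signal_terms ids are planted signal terms; they are kept as
  # leaves (never sampled as parents) so ancestor propagation cannot dilute
  # them towards the whole universe
  signal_ids <- ids[seq(n_terms - config$n_signal_terms + 1, n_terms)]
  parents <- stats::setNames(vector("list", n_terms), ids)
  parents[[ids[1]]] <- character(0)
  for (i in seq(2, n_terms)) {
    pool <- setdiff(ids[seq_len(i - 1)], signal_ids)
    k <- sample(1:2, 1)
    parents[[ids[i]]] <- sample(pool, min(k, length(pool)))
  }
  terms <- data.frame(id = ids, name = paste("synthetic process", seq_len(n_terms)),
                      namespace = "biological_process", stringsAsFactors = FALSE)
  ont <- ontology(terms, parents)
  ko_down <- names(truth$ko_down)[truth$ko_down]
  other <- setdiff(genes, ko_down)
  term_genes <- list()
  for (i in seq(2, n_terms)) {
    id <- ids[i]
    if (id %in% signal_ids) {
      k <- config$signal_term_size
      k_sig <- min(round(k * config$signal_fraction), length(ko_down))
      term_genes[[id]] <- c(sample(ko_down, k_sig),
                            sample(other, k - k_sig))
    } else {
      k <- sample(30:400, 1)
      term_genes[[id]] <- sample(genes, k)
    }
  }
  signal <- signal_ids
  g <- rep(names(term_genes), lengths(term_genes))
  t <- unlist(term_genes, use.names = FALSE)
  ann <- annotation_map(split(g, t), ont)
  scores <- stats::rnorm(length(genes)) +
    ifelse(truth$program[genes] == "late", config$score_shift_late, 0)
  list(ontology = ont, annotations = ann, signal_terms = signal,
       scores = stats::setNames(scores, genes))
}

#' Simulate the full synthetic study
#'
#' Runs every generator off one master seed and optionally writes the
#' generated inputs as the plain-text files the analysis modules read
#' (TSV tables, GMT sets, an OBO-subset ontology, a MatrixMarket cell
#' matrix, and a ground-truth JSON).
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return named list of all generated objects plus `truth`.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  u <- simulate_universe(config)
  universe <- u$universe; truth <- u$truth
  deg <- simulate_deg_tables(universe, truth, config)
  stats_tab <- simulate_gene_stats(universe, truth, config)
  dn <- simulate_denovo(universe, truth, config)
  sc <- simulate_sc(universe, truth, config)
  counts <- simulate_counts(universe, truth, config)
  ann <- simulate_annotations(universe, truth, config)
  truth$mu <- dn$rates
  truth$stage_means <- sc$stage_means
  truth$signal_terms <- ann$signal_terms
  truth$assoc_effects <- config$assoc_effects
  study <- list(universe = universe, truth = truth, deg_tables = deg,
                gene_stats = stats_tab, denovo = dn$dataset,
                rates = dn$rates, sc = sc$matrix, counts = counts,
                ontology = ann$ontology, annotations = ann$annotations,
                scores = ann$scores, config = config)
  if (!is.null(dir)) write_study(study, dir)
  study
}

# Writes the study inputs as plain-text files under dir.
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ct in names(study$deg_tables))
    write_tsv(study$deg_tables[[ct]], file.path(dir, paste0("deg_", ct, ".tsv")))
  write_tsv(study$gene_stats, file.path(dir, "gene_stats.tsv"))
  write_tsv(data.frame(gene_id = names(study$rates),
                       mu_lof = unname(study$rates)),
            file.path(dir, "mutation_rates.tsv"))
  counts_long <- do.call(rbind, lapply(names(study$denovo), function(co)
    data.frame(cohort = co, gene_id = names(study$denovo[[co]]$counts),
               count = unname(study$denovo[[co]]$counts),
               stringsAsFactors = FALSE)))
  write_tsv(counts_long, file.path(dir, "denovo_counts.tsv"))
  write_tsv(data.frame(cohort = names(study$denovo),
                       n_trios = vapply(study$denovo, `[[`, 0, "n_trios")),
            file.path(dir, "cohorts.tsv"))
  utils::write.table(study$counts, file.path(dir, "bulk_counts.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  write_cell_matrix(study$sc, file.path(dir, "sc"))
  ann_df <- data.frame(
    gene_id = rep(names(study$annotations), lengths(study$annotations)),
    term_id = unlist(study$annotations, use.names = FALSE))
  write_tsv(ann_df, file.path(dir, "annotations.tsv"))
  write_tsv(data.frame(gene_id = names(study$scores),
                       score = unname(study$scores)),
            file.path(dir, "specificity_scores.tsv"))
  write_obo(study$ontology, file.path(dir, "ontology.obo"))
  flags <- gene_set_collection(list(
    LoFi = list(description = "LoF-intolerant genes",
                genes = flagged_genes(study$universe, "LoFi")),
    all_expressed = list(description = "expressed universe",
                         genes = study$universe$genes)))
  write_gmt(flags, file.path(dir, "universe_sets.gmt"))
  jsonlite::write_json(
    list(program = as.list(study$truth$program),
         ko_down = as.list(study$truth$ko_down),
         lofi = as.list(study$truth$lofi),
         signal_terms = study$truth$signal_terms,
         assoc_effects = as.list(study$truth$assoc_effects)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write an ontology as an OBO subset file
#' @param ont an [ontology()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(ont$terms))) {
    id <- ont$terms$id[i]
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", ont$terms$name[i]),
                 paste0("namespace: ", ont$terms$namespace[i]),
                 paste0("is_a: ", ont$parents[[id]], recycle0 = TRUE)), con)
  }
  invisible(path)
}
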