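test_that("simulate_universe honours sizes, determinism and config errors", {
  cfg <- small_sim_config()
  u <- simulate_universe(cfg)
  expect_equal(length(u$universe$genes), cfg$n_genes)
  counts <- table(u$truth$program)[names(cfg$program_sizes)]
  expect_equal(as.integer(counts), unname(cfg$program_sizes))
  u2 <- simulate_universe(cfg)
  expect_identical(u$truth, u2$truth)
  expect_error(sim_config(n_genes = 100,
                          program_sizes = c("late" = 200)), "exceed")
})

test_that("LoFi odds are multiplied inside early programs (analytic oracle)", {
  # realized odds ratio over replicates vs the direct odds computation
  set.seed(1)
  ors <- vapply(1:50, function(i) {
    cfg <- small_sim_config(seed = 1000 + i)
    u <- simulate_universe(cfg)
    early <- u$truth$program %in% c("early-transient", "early-stable",
                                    "early-increasing")
    lofi <- u$truth$lofi
    (sum(lofi & early) / sum(!lofi & early)) /
      (sum(lofi & !early) / sum(!lofi & !early))
  }, numeric(1))
  expect_equal(mean(ors), 3, tolerance = 0.15)
})

test_that("DEG tables are noise-free-exact and recover truth end to end", {
  cfg <- small_sim_config(deg_noise_sd = 0)
  u <- simulate_universe(cfg)
  deg <- simulate_deg_tables(u$universe, u$truth, cfg)
  expect_setequal(names(deg),
                  c("WT_20v30", "WT_30v60", "WT_20v60", "KO_vs_WT_day30"))
  lab <- u$truth$program
  t2030 <- deg$WT_20v30
  ei <- names(lab)[lab == "early-increasing"][1]
  expect_gt(t2030$log2fc[t2030$gene_id == ei], 0)
  expect_lt(t2030$pvalue[t2030$gene_id == ei] * nrow(t2030), 0.05)
  none <- names(lab)[lab == "none"]
  for (ct in names(deg))
    expect_true(all(deg[[ct]]$pvalue[match(none, deg[[ct]]$gene_id)] == 1 |
                    deg[[ct]]$gene_id[match(none, deg[[ct]]$gene_id)] %in%
                      names(u$truth$ko_down)[u$truth$ko_down]))

  called <- lapply(deg, call_deg)
  asn <- classify_programs(called$WT_20v30$up, called$WT_30v60$up,
                           called$WT_20v60$up, universe = u$universe)
  expect_identical(stats::setNames(asn$label, asn$gene_id), lab)
  expect_setequal(called$KO_vs_WT_day30$down,
                  names(u$truth$ko_down)[u$truth$ko_down])
})

test_that("gene stats follow the null and injected linear model", {
  cfg <- small_sim_config(assoc_effects = stats::setNames(numeric(0),
                                                          character(0)),
                          n_background_stats = 9000)
  u <- simulate_universe(cfg)
  s <- simulate_gene_stats(u$universe, u$truth, cfg)
  n <- nrow(s)
  expect_gt(n, 10000 - 200)
  expect_lt(abs(mean(s$z)), 4 / sqrt(n))
  expect_lt(abs(stats::var(s$z) - 1), 4 * sqrt(2 / n))

  cfg2 <- small_sim_config(assoc_effects = c("early-stable" = 0.5))
  u2 <- simulate_universe(cfg2)
  s2 <- simulate_gene_stats(u2$universe, u2$truth, cfg2)
  members <- resolve_gene_set("early-stable", u2$universe)
  diff <- mean(s2$z[s2$gene_id %in% members]) -
    mean(s2$z[!s2$gene_id %in% members])
  expect_lt(abs(diff - 0.5), 4 / sqrt(length(members)))
  expect_identical(s2$z, simulate_gene_stats(u2$universe, u2$truth, cfg2)$z)
  expect_error(
    simulate_gene_stats(u2$universe, u2$truth,
                        small_sim_config(assoc_effects = c("bogus" = 1))),
    "unknown set")
})

test_that("de novo counts calibrate to 2*N*mu and injected rate ratios", {
  cfg <- small_sim_config(cohorts = list(
    CASE = list(n_trios = 20000,
                rate_ratio_by_segment = c("early-stable" = 5)),
    CTRL = list(n_trios = 20000, rate_ratio_by_segment = numeric(0))))
  u <- simulate_universe(cfg)
  dn <- simulate_denovo(u$universe, u$truth, cfg)
  genes <- u$universe$genes
  seg <- resolve_gene_set("early-stable", u$universe)
  rest <- setdiff(genes, seg)

  ctrl <- dn$dataset$CTRL$counts
  total_exp <- expected_counts(dn$rates, 20000, genes)
  expect_lt(abs(sum(ctrl) - total_exp) / total_exp, 5 / sqrt(total_exp))

  case <- dn$dataset$CASE$counts
  obs_in <- sum(case[names(case) %in% seg])
  obs_out <- sum(case[names(case) %in% rest])
  rr <- (obs_in / expected_counts(dn$rates, 20000, seg)) /
    (obs_out / expected_counts(dn$rates, 20000, rest))
  expect_lt(abs(rr - 5) / 5, 0.15)

  zero <- simulate_denovo(u$universe, u$truth,
                          small_sim_config(cohorts = list(
                            E = list(n_trios = 0,
                                     rate_ratio_by_segment = numeric(0)))))
  expect_length(zero$dataset$E$counts, 0)
})

test_that("single-cell generator is deterministic with configured profiles", {
  cfg <- small_sim_config()
  u <- simulate_universe(cfg)
  sc <- simulate_sc(u$universe, u$truth, cfg)
  sc2 <- simulate_sc(u$universe, u$truth, cfg)
  expect_identical(sc$matrix$values, sc2$matrix$values)
  expect_equal(length(sc$matrix$cells), sum(cfg$sc_celltypes))

  # dropout = 1 zeroes everything
  all0 <- simulate_sc(u$universe, u$truth, small_sim_config(dropout = 1))
  expect_true(all(all0$matrix$values == 0))

  # monotone configured program recovers a monotone profile
  filt <- filter_genes(filter_cells(sc$matrix))
  means <- celltype_gene_means(zscore_genes(filt))
  prog <- resolve_gene_set("early-increasing", u$universe)
  prof <- program_profile(means, prog)
  expect_false(is.unsorted(prof$mean))
})

test_that("emitted files re-read through io_formats reproduce the objects", {
  d <- withr::local_tempdir()
  cfg <- small_sim_config()
  study <- simulate_study(cfg, dir = d)
  deg_back <- read_table(file.path(d, "deg_WT_20v30.tsv"), schema_deg)
  expect_equal(deg_back$log2fc, study$deg_tables$WT_20v30$log2fc,
               tolerance = 1e-12)
  stats_back <- read_table(file.path(d, "gene_stats.tsv"), schema_gene_stats)
  expect_equal(stats_back$z, study$gene_stats$z, tolerance = 1e-12)
  gmt <- read_gmt(file.path(d, "universe_sets.gmt"))
  expect_setequal(set_genes(gmt, "LoFi"),
                  flagged_genes(study$universe, "LoFi"))
  ont <- read_obo(file.path(d, "ontology.obo"))
  expect_setequal(ont$terms$id, study$ontology$terms$id)
  sc_back <- read_cell_matrix(file.path(d, "sc", "matrix.mtx"),
                              file.path(d, "sc", "genes.tsv"),
                              file.path(d, "sc", "cells.tsv"),
                              file.path(d, "sc", "labels.tsv"),
                              stage_order = readLines(file.path(d, "sc",
                                                                "stages.tsv")))
  expect_equal(unname(sc_back$values), unname(study$sc$values),
               tolerance = 1e-6)
})
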