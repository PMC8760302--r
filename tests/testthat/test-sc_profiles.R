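toy_matrix <- function(values, stages, stage_order = unique(stages)) {
  genes <- sprintf("g%02d", seq_len(nrow(values)))
  cells <- sprintf("c%02d", seq_len(ncol(values)))
  sc_matrix(values, genes, cells, stats::setNames(stages, cells), stage_order)
}

test_that("filter_cells keeps cells at or above the gene fraction", {
  set.seed(7)
  v <- matrix(rexp(100 * 40), 100, 40)
  v[, 1] <- 0                      # dead cell
  v[1:5, 2] <- 2; v[6:100, 2] <- 0 # exactly 5% of genes at TPM >= 1
  m <- toy_matrix(v, rep(c("A", "B"), each = 20))
  f <- filter_cells(m, min_frac_genes = 0.05, tpm_min = 1)
  expect_false("c01" %in% f$cells)
  expect_true("c02" %in% f$cells)  # threshold inclusive: only "< 5%" removed
  # brute-force oracle over all cells
  keep <- vapply(seq_len(40), function(j) mean(v[, j] >= 1) >= 0.05, logical(1))
  expect_identical(f$cells, m$cells[keep])
  expect_error(filter_cells(toy_matrix(matrix(0, 3, 2), c("A", "A"))), "all cells")
})

test_that("filter_genes keeps genes expressed in enough surviving cells", {
  v <- matrix(1, 4, 20)
  v[1, ] <- 0                      # all-zero gene
  v[2, ] <- c(1, rep(0, 19))       # exactly 5% of cells
  m <- toy_matrix(v, rep("A", 20))
  f <- filter_genes(m, min_frac_cells = 0.05)
  expect_false("g01" %in% f$genes)
  expect_true("g02" %in% f$genes)
  set.seed(19)
  v2 <- matrix(rbinom(50 * 30, 1, 0.1) * rexp(1500), 50, 30)
  m2 <- toy_matrix(v2, rep(c("A", "B", "C"), each = 10))
  f2 <- filter_genes(m2, 0.2)
  keep <- rowMeans(v2 > 0) >= 0.2
  expect_identical(f2$genes, m2$genes[keep])
})

test_that("zscore_genes normalizes per gene and flags constant genes", {
  set.seed(23)
  v <- matrix(rexp(5 * 30), 5, 30)
  v[3, ] <- 7                      # constant gene
  m <- toy_matrix(v, rep(c("A", "B"), 15))
  z <- zscore_genes(m)
  for (i in c(1, 2, 4, 5)) {
    expect_equal(mean(z$values[i, ]), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(z$values[i, ]^2)), 1, tolerance = 1e-12)  # ddof 0
  }
  expect_equal(unname(z$values[3, ]), rep(0, 30))
  expect_equal(attr(z, "constant_genes"), "g03")

  # two-cell closed form, both ddof conventions
  m2 <- toy_matrix(matrix(c(1, 3), 1, 2), c("A", "B"))
  z0 <- zscore_genes(m2, ddof = 0)
  expect_equal(unname(z0$values[1, ]), c(-1, 1))
  z1 <- zscore_genes(m2, ddof = 1)
  expect_equal(unname(z1$values[1, ]), c(-1, 1) / sqrt(2))
})

test_that("celltype_gene_means averages member cells, invariant to order", {
  v <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8,
                0, 0, 10, 10), 3, 4, byrow = TRUE)
  m <- toy_matrix(v, c("A", "A", "B", "B"))
  cm <- celltype_gene_means(m)
  expect_equal(unname(cm["g01", ]), c(1.5, 3.5))
  expect_equal(unname(cm["g02", ]), c(5.5, 7.5))
  expect_equal(unname(cm["g03", ]), c(0, 10))

  perm <- sample(4)
  mp <- sc_matrix(v[, perm], m$genes, m$cells[perm], m$labels[perm],
                  m$stage_order)
  expect_equal(celltype_gene_means(mp), cm, ignore_attr = TRUE)

  # global conservation after z-scoring: cell-weighted stage means ~ 0
  set.seed(29)
  big <- toy_matrix(matrix(rexp(600), 20, 30), rep(c("A", "B", "C"), c(5, 10, 15)))
  zm <- celltype_gene_means(zscore_genes(big))
  w <- attr(zm, "n_cells")
  expect_lt(max(abs(as.matrix(zm) %*% w / sum(w))), 1e-10)
  expect_error(celltype_gene_means(
    toy_matrix(matrix(1, 2, 2), c("A", "A"), stage_order = c("A", "B"))),
    "zero cells")
})

test_that("program_profile reports mean, SEM and gene counts", {
  v <- matrix(rep(c(1, 2), each = 4), 2, 4, byrow = TRUE)
  m <- toy_matrix(v, c("A", "A", "B", "B"))
  cm <- celltype_gene_means(m)
  prof <- program_profile(cm, c("g01", "g02"))
  expect_equal(prof$mean, c(1.5, 1.5))
  expect_equal(prof$n_genes, c(2, 2))
  # identical-profile genes -> SEM 0
  same <- toy_matrix(matrix(3, 4, 4), c("A", "A", "B", "B"))
  p2 <- program_profile(celltype_gene_means(same), sprintf("g%02d", 1:4))
  expect_equal(p2$sem, c(0, 0))
  expect_error(program_profile(cm, "g01"), "fewer than 2")
})

test_that("successive_stage_tests match the paired closed form", {
  set.seed(37)
  n <- 10
  v <- cbind(matrix(exp(rnorm(n * 6, 0)), n, 6),
             matrix(exp(rnorm(n * 6, 1)), n, 6))
  m <- toy_matrix(v, rep(c("A", "B"), each = 6))
  cm <- celltype_gene_means(m)
  prog <- sprintf("g%02d", 1:n)
  res <- successive_stage_tests(cm, prog, pairs = list(c("A", "B")))
  d <- cm[prog, "A"] - cm[prog, "B"]
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(n)))
  expect_equal(res$df, n - 1)
  expect_equal(res$p_corrected, min(1, res$p_raw * 1))

  # identical means -> t = 0, p = 1; constant difference -> degenerate
  same <- successive_stage_tests(celltype_gene_means(
    toy_matrix(cbind(v[, 1:6], v[, 1:6]), rep(c("A", "B"), each = 6))),
    prog, pairs = list(c("A", "B")))
  expect_equal(same$t, 0); expect_equal(same$p_raw, 1)
  expect_true(same$degenerate)
  shifted <- successive_stage_tests(celltype_gene_means(
    toy_matrix(cbind(v[, 1:6], v[, 1:6] + 1), rep(c("A", "B"), each = 6))),
    prog, pairs = list(c("A", "B")))
  expect_true(shifted$degenerate)
  expect_equal(shifted$p_raw, 0)

  expect_error(successive_stage_tests(cm, prog, pairs = list(c("A", "Z"))),
               "unknown stage")
  expect_error(successive_stage_tests(cm, prog[1:2]), "fewer than 3")
})

test_that("expressed_in_cells implements both set definitions", {
  v <- matrix(0, 3, 40)
  v[1, 1:2] <- 2                   # TPM >= 1 in 2/20 = 10% of stage A cells
  v[2, 21] <- 0.5                  # one nonzero cell in stage B, below TPM 1
  m <- toy_matrix(v, rep(c("A", "B"), each = 20))
  expect_setequal(expressed_in_cells(m, c("A", "B"), 0.05, mode = "tpm"), "g01")
  expect_setequal(expressed_in_cells(m, c("A", "B"), mode = "nonzero"),
                  c("g01", "g02"))
  expect_length(expressed_in_cells(m, "B", 0.05, mode = "tpm"), 0)
  expect_error(expressed_in_cells(m, character(0)), "empty stage")
  expect_error(expressed_in_cells(m, "Q"), "unknown stage")
})
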