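make_universe <- function(n) sprintf("u%04d", seq_len(n))

# Build query/term sets over a background realizing a given 2x2 table.
sets_for_table <- function(a, nq, nt, bg) {
  genes <- make_universe(bg)
  query <- genes[seq_len(nq)]
  term <- c(genes[seq_len(a)], genes[nq + seq_len(nt - a)])
  list(query = query, term = term, background = genes)
}

test_that("fisher_overrep reproduces the worked 2x2 examples", {
  s <- sets_for_table(12, 20, 30, 100)
  r <- fisher_overrep(s$query, s$term, s$background)
  expect_equal(r$n_overlap, 12)
  expect_equal(r$odds_ratio, (12 * 62) / (8 * 18))   # 5.1667
  expect_equal(r$p_raw, 0.00183060942472401, tolerance = 1e-12)

  s2 <- sets_for_table(1, 10, 10, 100)               # independence point
  r2 <- fisher_overrep(s2$query, s2$term, s2$background)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p_raw, 0.669523788913275, tolerance = 1e-12)

  # disjoint query/term: OR = 0, one-sided greater p = 1
  s3 <- sets_for_table(0, 10, 10, 100)
  r3 <- fisher_overrep(s3$query, s3$term, s3$background)
  expect_equal(r3$odds_ratio, 0)
  expect_equal(r3$p_raw, 1)

  expect_error(fisher_overrep(c(s$query, "novel"), s$term, s$background),
               "outside background")
  expect_error(fisher_overrep("a", "a", character(0)), "background")
})

test_that("fisher p and OR match the enumeration oracle on random tables", {
  set.seed(101)
  for (rep in 1:60) {
    bg <- sample(20:200, 1)
    nq <- sample(1:(bg - 1), 1)
    nt <- sample(1:(bg - 1), 1)
    lo <- max(0, nq + nt - bg); hi <- min(nq, nt)
    a <- sample(lo:hi, 1)
    s <- sets_for_table(a, nq, nt, bg)
    for (alt in c("greater", "less", "two.sided")) {
      r <- fisher_overrep(s$query, s$term, s$background, alternative = alt)
      expect_equal(r$p_raw, oracle_hyper_p(a, nq, nt, bg, alt),
                   tolerance = 1e-12)
    }
    # two-sided p dominates the enriched one-sided p
    alt_dir <- if (a >= nq * nt / bg) "greater" else "less"
    expect_gte(fisher_overrep(s$query, s$term, s$background, "two.sided")$p_raw,
               fisher_overrep(s$query, s$term, s$background, alt_dir)$p_raw -
                 1e-12)
  }
})

test_that("bonferroni caps and preserves order", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(c(0.5, 0.001), 10), c(1, 0.01))
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_error(bonferroni(0.5, 0), "positive")
  expect_error(bonferroni(1.2, 2), "0, 1")
})

test_that("refine_terms follows the manual trace on the nested fixture", {
  # Term A: 40 query genes + 10 others; B: 20 of A's query genes + 5 others.
  bg <- make_universe(1000)
  query <- bg[1:50]
  A <- c(bg[1:40], bg[101:110])
  B <- c(bg[1:20], bg[201:205])
  terms <- gene_set_collection(list(A = A, B = B))
  res <- refine_terms(query, terms, bg)
  # Manual trace: iteration 1 tests both (m = 2); A has the larger OR
  # (40*940/(10*10) = 376 vs 20*945/(30*5) = 126) and is selected.  B's
  # query genes are all inside A, so the reduced B keeps 0 query genes,
  # re-tests at p = 1 and dies: output is [A] alone.
  rA <- fisher_overrep(query, A, bg); rB <- fisher_overrep(query, B, bg)
  expect_true(rA$odds_ratio > rB$odds_ratio)
  expect_equal(res$term, "A")
  expect_true(all(res$p_corrected < 0.05))
  expect_equal(res$iteration, seq_len(nrow(res)))

  # two disjoint strongly enriched terms: both returned, larger OR first
  C <- bg[1:25]; D <- c(bg[26:45], bg[301:306])
  res2 <- refine_terms(query, gene_set_collection(list(D = D, C = C)), bg)
  expect_equal(res2$term, c("C", "D"))
  orC <- fisher_overrep(query, C, bg)$odds_ratio
  orD <- fisher_overrep(query, D, bg)$odds_ratio
  expect_true(orC > orD)

  # single significant term -> one iteration; empty input -> empty output
  res3 <- refine_terms(query, gene_set_collection(list(A = A)), bg)
  expect_equal(res3$term, "A")
  expect_equal(res3$iteration, 1L)
  expect_equal(nrow(refine_terms(query, gene_set_collection(), bg)), 0)
})

test_that("refine_terms output is invariant to input term order", {
  set.seed(55)
  bg <- make_universe(800)
  query <- sample(bg, 60)
  terms <- lapply(1:6, function(i)
    unique(c(sample(query, sample(10:30, 1)), sample(bg, sample(5:40, 1)))))
  names(terms) <- paste0("t", 1:6)
  col <- gene_set_collection(terms)
  res_fwd <- refine_terms(query, col, bg)
  res_rev <- refine_terms(query, col[rev(names(col))], bg)
  expect_equal(res_fwd, res_rev)
  expect_lte(nrow(res_fwd), length(col))
})
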