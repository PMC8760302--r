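test_that("filter_expressed matches closed-form and brute-force oracles", {
  # 1 gene, 1 sample, count 1: cpm = 1e6 >= 1 -> included
  m <- matrix(1, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(filter_expressed(m), "g1")

  # all-zero gene excluded
  m2 <- rbind(g1 = c(5, 5, 5), g2 = c(0, 0, 0))
  expect_equal(filter_expressed(m2), "g1")

  # zero-total sample errors with the sample named
  m3 <- cbind(s1 = c(g1 = 1, g2 = 1), s2 = c(0, 0))
  expect_error(filter_expressed(m3), "s2")

  # random 50x9 matrix against direct enumeration
  set.seed(5)
  m4 <- matrix(rpois(450, 2), 50, 9,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:9)))
  m4 <- m4 + 1  # avoid zero-count samples
  got <- filter_expressed(m4, cpm_min = 40000, sample_frac = 1/3)
  lib <- colSums(m4)
  want <- rownames(m4)[vapply(seq_len(50), function(g) {
    n_pass <- sum(vapply(1:9, function(s)
      m4[g, s] / lib[s] * 1e6 >= 40000, logical(1)))
    n_pass >= ceiling(9 / 3)
  }, logical(1))]
  expect_identical(got, want)
})

test_that("call_deg applies the Bonferroni rule with strict sign handling", {
  tab <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    log2fc = c(1, -2, 0, rep(0.1, 97)),
                    pvalue = c(4e-4, 4e-4, 1e-9, rep(0.5, 97)))
  d <- call_deg(tab, alpha = 0.05)
  expect_equal(d$up, "g001")      # 0.0004 * 100 = 0.04 < 0.05
  expect_equal(d$down, "g002")
  expect_false("g003" %in% c(d$up, d$down))  # log2fc exactly 0
  expect_equal(d$n_tested, 100)

  tab$pvalue[1] <- 6e-4           # 0.06 -> excluded
  expect_length(call_deg(tab)$up, 0)
  expect_error(call_deg(tab[0, ]), "empty")

  # monotone in alpha: alpha -> large captures all signed genes, alpha = 0 none
  wide <- call_deg(tab, alpha = 1e9)
  expect_setequal(c(wide$up, wide$down), tab$gene_id[tab$log2fc != 0])
  none <- call_deg(tab, alpha = 0)
  expect_length(c(none$up, none$down), 0)
})

test_that("classify_programs implements the four-program set algebra", {
  asn <- classify_programs(up_20_30 = c("a", "b", "c", "d"),
                           up_30_60 = c("a", "e"),
                           up_20_60 = c("b", "e"),
                           universe = letters[1:6])
  lab <- stats::setNames(asn$label, asn$gene_id)
  expect_equal(unname(lab["a"]), "early-increasing")  # 20-30 and 30-60
  expect_equal(unname(lab["b"]), "early-stable")      # 20-30 and 20-60 only
  expect_equal(unname(lab["c"]), "early-transient")   # 20-30 only
  expect_equal(unname(lab["e"]), "late")              # 30-60 only
  expect_equal(unname(lab["f"]), "none")
})

test_that("program assignment is a partition on random set triples", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:300)
  for (rep in 1:20) {
    s1 <- sample(genes, rbinom(1, 300, 0.3))
    s2 <- sample(genes, rbinom(1, 300, 0.3))
    s3 <- sample(genes, rbinom(1, 300, 0.3))
    asn <- classify_programs(s1, s2, s3, universe = genes)
    expect_equal(nrow(asn), 300)
    expect_false(anyDuplicated(asn$gene_id) > 0)
    lab <- stats::setNames(asn$label, asn$gene_id)
    # brute-force re-derivation of each label
    for (g in sample(genes, 25)) {
      a <- g %in% s1; b <- g %in% s2; c6 <- g %in% s3
      want <- if (a && b) "early-increasing"
              else if (a && c6) "early-stable"
              else if (a) "early-transient"
              else if (b) "late" else "none"
      expect_equal(unname(lab[g]), want)
    }
    # non-none labels live inside up_20_30 | up_30_60
    expect_true(all(asn$gene_id[asn$label != "none"] %in% union(s1, s2)))
  }
})

test_that("split_by_ko splits non-exempt programs and passes late through", {
  asn <- classify_programs(c("a", "b"), c("z"), c("b"),
                           universe = c("a", "b", "z", "q"))
  part <- split_by_ko(asn, ko_down = c("a", "z"))
  expect_setequal(part[["early-transient^-/-"]], "a")
  expect_length(part[["early-transient^WTonly"]], 0)
  expect_setequal(part[["late"]], "z")          # exempt: not split
  expect_false("late^-/-" %in% names(part))
  empty <- split_by_ko(asn, ko_down = character(0))
  expect_length(empty[["early-stable^-/-"]], 0)
  expect_setequal(empty[["early-stable^WTonly"]], "b")
  expect_error(split_by_ko(asn, "a", exempt = "nonsense"), "unknown exempt")
})

test_that("partition_by_set yields a disjoint exhaustive partition", {
  part <- program_partition(list(ET = "a", ES = "b"))
  res <- partition_by_set(c("a", "b", "c"), part, c("a", "b", "c", "d"),
                          reference_name = "ref")
  expect_setequal(res[["ET&ref"]], "a")
  expect_setequal(res[["ES&ref"]], "b")
  expect_setequal(res[["other-ref"]], "c")
  expect_length(res[["ET\\ref"]], 0)

  expect_error(partition_by_set("x", part, c("a", "b")), "outside universe")

  # random instance: disjoint and exhaustive vs brute-force set algebra
  set.seed(77)
  genes <- sprintf("g%03d", 1:500)
  segs <- program_partition(split(sample(genes, 300), rep(1:3, each = 100)))
  ref <- sample(genes, 200)
  res2 <- partition_by_set(ref, segs, genes)
  all_members <- unlist(res2, use.names = FALSE)
  expect_false(anyDuplicated(all_members) > 0)
  expect_setequal(all_members, union(ref, unlist(segs, use.names = FALSE)))
})
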