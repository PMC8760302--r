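# neuroprog

Transcriptional-program classification and disease-genetics enrichment
for neuronal differentiation studies.

## The problem

Loss of a synaptic scaffolding gene in human embryonic stem cells disrupts
the transcriptional programs that drive cortical neurogenesis. To connect
that cellular phenotype to psychiatric disease genetics, one analysis
chain recurs: classify genes into timecourse expression programs, ask
whether those programs are over-represented in functional annotations,
whether they capture common-variant association from GWAS gene statistics,
whether they carry an excess of de novo loss-of-function (LoF) mutations
relative to mutation-rate expectations, and whether the same programs are
expressed on schedule in fetal cortex single-cell data. `neuroprog`
implements this whole chain as composable, tested R functions, plus a
synthetic-data generator with known ground truth so every step can be
validated end to end without restricted-access data.

It is aimed at statistical-genetics and neurodevelopmental-transcriptomics
analysts who have: per-contrast DEG tables, gene-level association
Z-scores (e.g. MAGMA output), per-gene mutation rates and de novo counts,
GO-style annotations, and a labelled single-cell expression matrix.

## The statistics at the core

* **Programs** (timepoints 20/30/60; `A = up(20–30)`, `B = up(30–60)`,
  `C = up(20–60)`, each Bonferroni p < 0.05):
  early-increasing `= A ∩ B`, early-stable `= (A ∩ C) \ B`,
  early-transient `= A \ B \ C`, late `= B \ A`; programs are split by
  knockout down-regulation into `P^−/−` and `P^WTonly`.
* **Over-representation**: Fisher's exact test on the 2×2 overlap table
  against the expressed background, OR `= ad/bc`; iterative refinement
  repeatedly selects the largest-OR surviving term, removes its genes
  from the others, re-tests and Bonferroni-corrects per iteration.
* **Competitive enrichment**: OLS of gene Z on
  `[1, 1{g∈set}, conditioning sets, covariates]`; β is the set
  coefficient, p from the t distribution (one-sided by default);
  conditioning via covariates ≡ residualize-then-regress
  (Frisch–Waugh–Lovell). Coefficients compare via
  `z = (β₁−β₂)/√(SE₁²+SE₂²)`.
* **De novo burden**: expected counts `2·N_trios·Σμ_g`; exact conditional
  test `obs_in ~ Binomial(T, exp_in/(exp_in+exp_out))` with two-sided
  minimum-likelihood p; rate ratio `(obs_in/exp_in)/(obs_out/exp_out)`.
* **Single-cell profiles**: filter cells (<5% genes at TPM≥1) then genes
  (<5% cells nonzero), z-score per gene, average per cell type, report
  program mean ± SEM per stage, and test successive stages with paired
  two-tailed t-tests (Bonferroni over the pairs).

## Worked example

A reduced synthetic study (2000 expressed genes) with a 0.35 Z-unit
association effect injected into the early-stable knockout segment, five
planted annotation terms, and a de novo rate-ratio gradient on the
LoF-intolerant (LoFi) program cores:

```r
library(neuroprog)
cfg <- pipeline_config(
  sim = sim_config(
    n_genes = 2000,
    program_sizes = c("early-transient" = 200, "early-stable" = 180,
                      "early-increasing" = 120, "late" = 200),
    n_background_stats = 600, n_unexpressed = 100,
    sc_celltypes = c("RG-early" = 40, "RG" = 80, "IPC" = 50,
                     "Transitioning" = 50, "Newborn" = 70, "Developing" = 90),
    assoc_effects = c("early-stable^-/-" = 0.35),
    signal_term_size = 80, seed = 42),
  outdir = "readme_run")
bundle <- run_all(cfg)

bundle$enrichment[, c("set_name", "n_genes", "beta", "se", "p", "p_corrected")]
#>                     set_name n_genes     beta     se       p p_corrected
#> 1   early-transient^-/-&LoFi      77 -0.01026 0.1172 0.53489      1.0000
#> 2  early-transient^-/-\\LoFi      88 -0.18689 0.1099 0.95547      1.0000
#> 3      early-stable^-/-&LoFi      82  0.30763 0.1135 0.00339      0.0237
#> 4     early-stable^-/-\\LoFi      67  0.33107 0.1251 0.00410      0.0287
#> 5  early-increasing^-/-&LoFi      46  0.10644 0.1504 0.23959      1.0000
#> 6 early-increasing^-/-\\LoFi      52 -0.00416 0.1417 0.51172      1.0000
#> 7                 other-LoFi     333  0.01274 0.0605 0.41662      1.0000
```

The partition scan tests all seven segments of the LoFi-by-program
partition, conditioning on the expressed universe; only the two halves of
the early-stable knockout segment — where the effect was injected —
survive Bonferroni correction (β̂ ≈ 0.31 and 0.33 against a true 0.35).

```r
head(bundle$refined_terms, 3)
#>       term n_overlap odds_ratio    p_raw p_corrected iteration
#> 1 TERM0056        56       8.87 4.96e-20    7.44e-19         1
#> 2 TERM0058        52       8.15 6.06e-18    8.48e-17         2
#> 3 TERM0059        41       6.53 7.80e-13    6.24e-12         3
```

Iterative refinement of terms over-represented in the knockout
down-regulated set returns the planted signal terms, largest odds ratio
first, each re-tested on genes not already claimed by an earlier term.

```r
subset(bundle$rate_ratios, cohort == "NDD" & grepl("&LoFi", segment))[,
  c("segment", "obs_in", "exp_in", "rate_ratio", "p_corrected")]
#>                     segment obs_in exp_in rate_ratio p_corrected
#> 1  early-transient^-/-&LoFi    157   33.0       3.86    1.60e-40
#> 3     early-stable^-/-&LoFi    190   35.7       4.41    2.65e-56
#> 5 early-increasing^-/-&LoFi    107   19.4       4.36    1.13e-32
```

The NDD-scale cohort (31,058 trios, injected rate multiplier 5) shows a
strong observed-over-expected LoF excess in every early LoFi segment; the
estimates sit below 5 because the comparison side ("all other expressed
genes") is itself elevated by the other injected segments.

`run_all()` also writes every table (`enrichment.tsv`, `rate_ratios.tsv`,
`sc_profiles.tsv`, ...) to `outdir`; two runs with the same config are
byte-identical.

## Command line

```sh
Rscript inst/cli/neuroprog.R simulate --outdir inputs --seed 7
Rscript inst/cli/neuroprog.R run-all  --outdir results --seed 7
```
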