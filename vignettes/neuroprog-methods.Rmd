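---
title: "Methods: transcriptional programs and disease-genetics enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptional programs and disease-genetics enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis this package implements

`neuroprog` re-implements, as a tested and reusable pipeline, a chain of
analyses that starts from timecourse differential-expression tables of
cortical neuronal differentiation and ends at disease-genetics conclusions:

1. **Program classification.** Genes upregulated between differentiation
   days 20–30, 30–60 and 20–60 (Bonferroni p < 0.05 within the expressed
   universe) are combined by set algebra into four transcriptional
   programs: *early-transient*, *early-stable*, *early-increasing* and
   *late*. Non-exempt programs are further split by membership in the
   knockout day-30 down-regulated set (`P^-/-` vs `P^WTonly`).
2. **Conditional over-representation.** Fisher's exact tests of gene-set
   overlap against the expressed background, plus an iterative refinement
   that yields a semi-independent subset of enriched ontology terms.
3. **Competitive common-variant enrichment.** Regression of gene-level
   association Z-scores on set membership, with conditioning gene sets as
   covariates, one-sided or two-sided, a coefficient-difference z-test,
   and partition-wide scans under Bonferroni control.
4. **De novo burden.** Exact two-sided Poisson rate-ratio tests of
   de novo loss-of-function (LoF) mutation counts in a segment versus all
   other expressed genes, with expectations `2 N mu_g` from per-gene
   mutation rates.
5. **Single-cell stage profiling.** Cell/gene filtering, per-gene
   z-scoring, per-cell-type averaging, program mean ± SEM profiles across
   six fetal cortical stages, and paired t-tests between successive
   stages.

None of the restricted inputs (GWAS summary statistics, the deposited
RNA-seq, mutation catalogues) is required: a synthetic-data generator with
known ground truth emulates every input at the study's scale.

## Models and statistical choices

### Program algebra and its one ambiguity

With `A = up(20-30)`, `B = up(30-60)`, `C = up(20-60)`:
early-increasing `= A ∩ B`; early-stable `= (A ∩ C) \ B`;
early-transient `= A \ B \ C`; late `= B \ A`. The verbal definitions
permit one pathological overlap — a gene in `A ∩ B` but not `C` satisfies
both the early-increasing and early-transient wordings — so the package
fixes the precedence early-increasing > early-stable > early-transient,
which makes the four labels provably disjoint (a property test checks the
algebra against brute-force set enumeration on random triples).

### Fisher over-representation and iterative refinement

The odds ratio reported is the sample odds ratio `ad/bc` (infinite when
`bc = 0` with `ad > 0`), not the conditional MLE; one-sided p-values are
hypergeometric tails and the two-sided p sums all table probabilities not
exceeding the observed table's probability (the standard exact convention,
with a `1 + 1e-7` relative guard against floating-point ties — the same
guard `binom.test` uses). Refinement repeats: test all surviving terms,
Bonferroni-correct by the number tested *in that iteration*, discard
corrected p ≥ 0.05, select the survivor with the largest odds ratio (ties:
smaller raw p, then lexicographic name — without this rule the "largest
odds ratio" selection is non-deterministic once infinite odds ratios
appear), and remove its current genes from all other survivors. Testing
precedes selection so that every returned term was significant at its
selection iteration; gene sets are cumulatively depleted across
iterations. The output is invariant to input term order.

### Competitive enrichment and conditioning

The enrichment coefficient is the set-indicator coefficient of an ordinary
least-squares fit of Z on `[1, set, conditioning sets..., covariates...]`.
By the Frisch–Waugh–Lovell theorem this is identical to residualizing both
Z and the indicator on the conditioning columns and regressing the
residuals ("condition-residualize" semantics); an acceptance criterion
verifies agreement to 1e-8 on random designs. P-values use the t
distribution with residual degrees of freedom — exact in small universes,
indistinguishable from the normal at study scale.

Two deliberate deviations from LD-aware implementations, documented here
as the package's known approximations: gene–gene correlation is not
modelled (no reference LD panel is reproducible at desk scale), and the
SNP-to-gene model that produces the Z-scores is out of scope — the package
consumes gene-level statistics. Calibration is therefore stated, and
verified, under independence: the null rejection rate of the one-sided
test at α = 0.05 lies in [0.03, 0.07] over 2000 simulated universes.

Conditioning on "all expressed genes" is only meaningful when the
statistics universe is wider than the expressed universe (otherwise the
indicator is collinear with the intercept and the fit correctly aborts
with a degenerate-design error). The generator mirrors the real situation
— a genome-wide gene analysis containing the expressed set as a subset —
by emitting `n_background_stats` additional null genes.

### Exact rate-ratio test

"Two-sided Poisson rate ratio test" is read as the exact conditional test:
given the total `T = obs_in + obs_out`, the inside count is
`Binomial(T, exp_in/(exp_in + exp_out))` under the null of equal rates,
and the two-sided p is the minimum-likelihood sum — the same convention as
`poisson.test` for two-sample comparisons. The test is swap-invariant and
its p matches full pmf enumeration to 1e-12 for all totals ≤ 500
(acceptance criterion 1). Discreteness makes it conservative; the null
rejection rate stays below 0.07. When the scan injects elevated rates into
*several* segments at once, each segment's estimate is attenuated relative
to the injected multiplier because the "all other genes" side is elevated
too; this is a property of the design (set versus rest), not an estimator
defect, and single-segment injection recovers the multiplier within 20%.

### Single-cell profiling

Filtering follows the stated order — cells first (< 5% of genes at
TPM ≥ 1 removed; a cell at exactly 5% is retained), then genes (< 5% of
surviving cells nonzero removed) — because gene fractions depend on which
cells survive. Z-scoring uses the population sd (`ddof = 0`, switchable):
the source analysis does not state a convention and at thousands of cells
the difference is negligible. Stage tests default to *paired-by-gene*
t-tests: the same genes' averages are measured at both stages, so pairing
is the statistically appropriate reading of "Student's t test" here; the
unpaired equal-variance test is available via `paired = FALSE`. The six
default stage pairs are RG-early v RG, RG v IPC, RG v Transitioning,
IPC v Transitioning, Transitioning v Newborn, Newborn v Developing; the
Bonferroni divisor is always the number of pairs supplied, never a
hard-coded 6.

### Gene-set construction conventions

Ontology ancestor propagation treats `is_a` and `part_of` identically and
is idempotent; term sets are kept when their post-propagation size lies in
the inclusive window [20, 2000]. The top-specificity selection takes
`floor(fraction × n_eligible)` genes — "top 10%" does not state a rounding
rule, and floor is conservative and deterministic — with ties at the cut
broken by gene id. Evidence-code filtering (IEA/NAS/RCA, NOT qualifiers)
is applied at annotation ingestion when the columns are present.

## What the synthetic generator emulates — and what it does not

The generator's defaults *are* the stated world of the study: a
14,000-gene expressed universe (published: 14,274); program sizes of
1500/1200/800/1400 summing to a 20–30 upregulated pool of ~3500 (published
overlap with the knockout down set: 3075 genes, 85%, which motivates the
0.85 knockout-down fraction for early programs and ~4% for the late set,
published 62/1399); enrichment effects of 0.2 Z-units on the LoFi cores of
the early-stable and early-increasing knockout segments (published
coefficient scale beta ≈ 0.14 for a 3075-gene set; smaller sets carry
larger coefficients); trio counts NDD 31,058 / ASD 6,430 / SZ 3,444 /
sibling controls 1,995 with a rate-ratio gradient 5 > 3 > 1.5 on the early
LoFi segments and none in siblings; log-normal per-gene LoF mutation rates
with median 5e-6 per haploid genome per generation (genome-wide de novo
LoF expectation of the right order); ~2300 cells across six ordered stages
(published: 2318) with program-shaped log-TPM stage profiles of at most
1.0 unit and 30% dropout.

Each generator draws from its own substream derived from one master seed,
so components are independently reproducible and every emitted file is a
pure function of the configuration.

Features of real data the generator does **not** model, and which a green
test therefore does not establish: count-model dispersion in differential
expression (p-values come from a normal Wald statistic on log2FC — the
pipeline boundary is the DEG table, and negative-binomial estimation is
out of scope); linkage disequilibrium and gene–gene correlation in the
association statistics; mutation-rate misspecification; batch effects,
library-size variation and doublets in the single-cell matrix; and any
read-level artefact. Conclusions about calibration and recovery hold under
these idealizations.

## Numerical and degenerate-input conventions

* Exact-test ties are compared with a `1 + 1e-7` relative tolerance.
* `p = 0` (or 1) inputs to the probit mapping raise errors rather than
  returning infinities.
* A constant gene z-scores to an all-zero row and is flagged, not dropped.
* A stage-test difference vector that is numerically constant yields the
  degenerate results t = 0/p = 1 (zero mean) or |t| = Inf/p = 0, flagged.
* Empty term collections refine to an empty table; an empty overlap gives
  OR = 0 and one-sided p = 1; a both-margins-zero odds ratio is NaN.
* Segments below the enrichment size floor are reported as skipped, and
  the Bonferroni divisor counts only segments actually tested.
* All emitted tables are TSV with C-locale decimals; table writers are
  deterministic, and pipeline determinism is asserted byte-for-byte.

## Known limitations

Beyond the generator idealizations above: the OBO parser covers the 1.2
subset the pipeline needs (`[Term]` stanzas, `is_a`,
`relationship: part_of`, `is_obsolete`), not full OBO 1.4 semantics;
cross-species orthology mapping and identifier-history resolution are out
of scope (scores and ids are assumed pre-mapped); and the pipeline's
multiple-testing counts, while derived from the data, implement Bonferroni
only — no FDR alternatives are provided.
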