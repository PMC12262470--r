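---
title: "Methods: simulating and detecting cell-type-mediated nephrotoxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting cell-type-mediated nephrotoxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nephrosig` studies a single question from several angles: if a drug's
toxicity is mediated by particular kidney cell subtypes, when is that
signal detectable — and when does averaging over cells (bulk or
pseudo-bulk RNA-seq) destroy it? This vignette documents the models,
parameter choices, and numerical decisions behind each stage. Everything
here is implemented and exercised by the test suite; no empirical claim is
made beyond what the tests and `scripts/acceptance.R` themselves compute.

## The synthetic kidney

Real analyses of this kind start from an integrated multi-donor kidney
atlas annotated at two resolutions: four abstract compartments — Nephron,
Endothelium, Immune, Stroma, at prevalences of roughly 82.4%, 7.8%, 7.1%
and 2.6% — refined into 32 detailed subtypes. The generator reproduces
that structure synthetically:

- **Cell types.** `kidney_cell_type_specs()` fixes the four compartment
  prevalences (renormalized from the published 0.999 sum to exactly 1) and
  splits each compartment over its subtypes by a 1/rank (Zipf) series, so
  a few subtypes dominate each compartment as in real atlases. The 32
  subtype names follow kidney-atlas nomenclature (Indistinct intercalated
  cell, MNP-b/non-classical monocyte derived, Peritubular capillary
  endothelium 1, Distinct proximal tubule 1, Proliferating Proximal
  Tubule, Epithelial progenitor cell, and so on), with their conventional
  compartment assignments.
- **Counts.** Gene base means are lognormal (`sdlog = 1.25`); each gene
  has a negative-binomial dispersion drawn uniformly from [0.5, 2]; on top
  of NB zeros, a multiplicative per-entry dropout (default 5%) is applied.
  NB-plus-dropout is the field's standard count model; nothing downstream
  depends on the specific choice beyond sparsity and overdispersion being
  realistic.
- **Sparsity calibration.** Rather than tuning means by hand, the
  generator solves analytically for a global mean scale such that the
  expected zero fraction `d + (1-d)·E[(θ/(θ+μ))^θ]` matches
  `target_sparsity` (default 0.85, a typical droplet-data zero fraction);
  the realized value lands within a few percentage points.
- **Markers.** Each detailed type receives a disjoint panel of marker
  genes (default 25 per type) whose mean is multiplied by `marker_fold`
  (default 8) in that type only — a typical fold for discriminative
  cell-type markers, fixed a priori as part of the study conditions.
  Markers are therefore top-expressed in their own type by construction.
  On small test universes the panel is capped at `n_genes/n_types`; tests
  use panels of about 12, since very small panels (3–4 genes) make all
  toxic drugs share targets and induce spurious correlated score shifts in
  off-target types.
- **Donors.** Cells are spread over donors (default 24, mirroring a
  multi-sample integrated atlas) in near-equal blocks; each donor carries
  a lognormal depth factor (`sdlog = 0.3`) so donor-level pseudo-bulk
  replicates have realistic between-replicate variability. Per-cell
  log-normalization removes the depth factor itself; residual
  donor-to-donor variation comes from finite cells per donor.
- **Gene universe.** Default 20,000 genes. The per-gene significance
  threshold used throughout the power analysis, `2.5×10⁻⁶`, is a
  Bonferroni-style `0.05/20,000`, which motivates that default.
- **Drugs.** `simulate_drug_db()` draws per-drug target-set sizes as
  `1 + Poisson(5)` (typical curated-database target counts). Nephrotoxic
  drugs draw a fraction `enrichment_strength` of their targets from the
  marker genes of the designated susceptible types; everything else is
  uniform over the universe. `enrichment_strength = 0` yields a null
  database whose labels are provably independent of target composition.
  The default 215:641 class ratio matches curated FDA-label drug sets.

What the generator does **not** emulate: batch effects requiring
integration, gene–gene co-regulation (each gene is sampled independently
given its type), ambient RNA, doublets, or diseased-tissue states.
Passing tests on this generator therefore show that the pipeline's
statistics behave correctly under its assumptions — not that real kidney
data will show the same effect sizes.

## QC and normalization

`qc_filter()` keeps cells with UMI ≥ 500 and detected genes ≥ 250
(read as inclusive minimums) and complexity
`log10(genes)/log10(UMI) > 0.85` (strict, as stated); genes must then be
detected in ≥ 10 surviving cells. All four thresholds are configurable.
`log_normalize()` is `ln(1 + count/total × 10⁴)`. HVG selection follows
the published VST recipe: a loess fit (span 0.3, degree 2) of
log10 variance on log10 mean predicts each gene's expected sd; counts are
standardized and clipped at `√n_cells`; genes are ranked by the variance
of the clipped values. A per-gene z-scoring step (`scale_genes()`) exists
for consumers that want it, but drug scoring deliberately consumes
log-normalized values: z-scores can be negative, which would break the
subsequent log transform of the scores.

## The power simulation

`run_power_grid()` implements the dilution experiment per combination of
effect size, response rate and affected cell type, repeated over
`n_replicate_runs` fresh subsamples:

1. draw a 10% subsample preserving detailed-type prevalence
   (`round(f·n)` per type; types rounding to zero are dropped with a
   warning);
2. select `floor(rate·n_type)` responding cells (at least 1) of the
   affected type and multiply their whole log-normalized expression
   vector by `(1 + e)` — the multiplicative model applied to all genes of
   a responding cell;
3. test every gene between the treated and untreated version and count
   `p < 2.5×10⁻⁶`; power is that count over all genes.

Two comparison designs are provided, reflecting a genuine openness in how
such per-gene tests can be set up:

- **pseudo_bulk**: cell annotations are masked and each arm is collapsed
  to donor-level per-gene means; the Welch t-test compares `n_donor`
  treated vs `n_donor` untreated profiles. Donors are the only replicate
  structure available, so they serve as the test's unit of observation.
- **cell_level**: annotations remain available — the defining advantage
  of single-cell data — so the test compares treated vs untreated cells
  *within the affected type*. A pooled-cells variant (ignoring the
  annotations at cell level too) was considered and rejected: it inherits
  the same dilution as pseudo-bulk and makes the comparison between the
  modes vacuous for rare-subtype signal.

Genes with no usable variance (e.g. all-zero in the subsample) can never
be significant; with ~85% sparsity this is what caps pseudo-bulk power
well below 1 even at extreme effect sizes — the plateau is the fraction
of genes expressed above the noise floor, not a numerical artifact.

The default effect-size grid is 13 points log-spaced over
`[0.001, 10]`. The source material states the range once as 0.01–10 and
once as 0.001–10; the wider range is used, and the discrepancy noted here
rather than resolved silently. Response rates default to
{0.3, 0.8, 0.95}: 0.8 as the assumed standard drug response rate, 0.95
for unusually responsive drugs and 0.3 for weak responders.

## Drug scores and signature tests

A cell's raw score for a drug is the arithmetic mean of its log-normalized
expression over the drug's measured target genes (plain mean, no
background correction). Scores are log-transformed as `ln(score + ε)`
with `ε = 10⁻⁹` recorded in the object; the natural log is fixed by the
downstream convention `FC = e^{logFC}`, which reproduces the printed
(logFC, FC) pairs of the reference tables to three decimals. Logged
scores, not raw, feed all downstream analyses.

Per cell type, the representative value per drug is the mean logged score
over that type's cells; the signature test is a Welch (unequal-variance)
two-sample t-test between nephrotoxic and non-nephrotoxic drugs, with the
drug — not the cell — as the unit of observation (the groups being
compared are drug groups; a cell-level variant would pseudo-replicate).
Welch is chosen because the group sizes and variances are unequal by
construction. `logFC` is the difference of group means on the logged
scale; the 95% CI is the exponential of the Welch interval; BH correction
is applied within an abstraction level (4 tests at abstract, 32 at
detailed), and rows sort by corrected p, ties by |t| descending.

## Classification

`cross_validate()` uses stratified k-fold splits (plain k-fold under a
~25% positive rate produces single-class folds too easily), pools
out-of-fold positive-class probabilities, and reports accuracy, F1,
AUROC, sensitivity and specificity at a 0.5 threshold with the
nephrotoxic class as positive. The AUROC 95% CI is a stratified bootstrap
(2,000 resamples) of the pooled out-of-fold scores — the CI method is a
package choice, recorded in the report metadata. Eight families are
supported with default hyperparameters and no tuning: regularized
logistic regression (glmnet, CV-selected lambda), RBF SVM (e1071), random
forest (randomForest), extremely randomized trees (ranger with the
extratrees split rule, no resampling), two tree-boosting variants
(xgboost with conservative eta 0.1/depth 3, and with default-style
eta 0.3/depth 6 — no classical GBM implementation is declared, so both
boosting flavors are realized through xgboost), a soft-voting ensemble
averaging the six base families' probabilities (the ensemble's membership
is a documented choice), and a single-hidden-layer MLP (nnet, 8 units,
decay 0.01).

## Bulk differential expression

Bulk signature profiles (z-score-like, possibly negative) are collapsed
one-per-drug by averaging replicates, then tested gene-wise with Welch
t-tests and BH FDR. The "log2 fold change" is reported as the difference
of group means: the profiles are already on a signature (log-like) scale
and the upstream scale convention is not recoverable, so the convention
is declared in the output metadata rather than guessed. Gene selection
defaults to the rule as printed alongside such analyses —
`p < 0.05` and `|log2FC| ≤ 1` — even though it bounds the effect size
from above, which is unusual; the conventional `≥` direction is available
via `selection = "at_least"`. The intent of the printed rule is not
guessed; both behaviors are tested.

## Numerical and degenerate-input decisions

- Seeds: every sampling function takes an explicit seed; compound
  operations derive per-stage seeds from one global seed and restore the
  caller's RNG state. Identical seeds give byte-identical outputs.
- Welch tests are computed vectorized over genes; rows where both groups
  are constant and equal give `NaN` t and `NA` p, which never count as
  significant.
- Zero drug scores are floored at `ln(10⁻⁹)` rather than `-∞`.
- Subsample allocation uses round-to-nearest per type; responding-cell
  counts use floor with a minimum of one.
- Drugs whose targets are all unmeasured are excluded from scoring with a
  warning; empty universes, degenerate groups (< 2 drugs), single-class
  feature tables and zero-total cells raise errors naming the problem.

## Problem sizes used by the tests

The default synthetic dataset is 6,000 cells × 20,000 genes × 24 donors —
large enough that the power analysis runs in the regime of interest
(donor pseudo-bulk replicates of a ~600-cell subsample) while staying
desk-scale. Property suites (FDR control, parameter recovery, dilution,
classifier calibration) run at 300–6,000 cells, 200–400 genes and 50–200
drugs over 20–50 seeds each; those sizes were chosen once to make the
properties statistically meaningful at interactive runtimes and are stated
alongside each test.

## Known limitations

Genes are conditionally independent given cell type, so the generator
cannot express co-regulated modules; donor effects are purely
multiplicative depth factors; the drug-target model treats all targets as
equivalent (no affinity weighting); and only healthy-tissue baselines are
modeled. Results on this synthetic system quantify the statistical
machinery — dilution, FDR control, recoverability — not the biology of
any particular nephrotoxicant.
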