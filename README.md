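# nephrosig

Cell-type-resolved nephrotoxicity signatures from single-cell drug scores.

Drug-induced acute kidney injury is hard to predict partly because toxicity
is often mediated by specific kidney cell subtypes, and bulk transcriptomics
averages those subtypes away ("signal dilution"). `nephrosig` implements a
complete, seeded simulation-and-analysis pipeline for studying this problem:

- **Synthetic kidney data.** A negative-binomial/dropout generator for
  annotated cell×gene count matrices with the kidney's four abstract
  compartments (Nephron, Endothelium, Immune, Stroma at 82.4/7.8/7.1/2.6%
  prevalence) partitioned into 32 detailed subtypes, multi-donor replicate
  structure, and a drug → target-genes → nephrotoxicity database generator
  with a controllable embedded toxicity signal (215:641 toxic:non-toxic
  class ratio by default).
- **Preprocessing.** Standard scRNA-seq QC (UMI ≥ 500, genes ≥ 250,
  log10 genes/UMI > 0.85, genes in ≥ 10 cells), `ln(1 + count/total × 10⁴)`
  log-normalization, and VST-based highly-variable-gene selection.
- **Power simulation.** The pseudo-bulk dilution experiment: subsample 10%
  of cells preserving prevalence, multiply responding cells of one type by
  `(1 + e)` for effect sizes `e ∈ [0.001, 10]` and response rates
  {0.3, 0.8, 0.95}, pseudo-bulk by donor, t-test every gene at
  `p < 2.5×10⁻⁶`, and report power = significant/total genes. A cell-level
  mode keeps the annotations and tests within the affected type, exposing
  the dilution gap.
- **Drug scoring.** drug2cell-style composite scores: a cell's score for a
  drug is the mean log-normalized expression of the drug's target genes;
  scores are natural-log transformed (`ln(score + 10⁻⁹)`) and aggregated to
  cell-type means.
- **Signature statistics.** Per cell type, Welch t-tests of nephrotoxic vs
  non-nephrotoxic drug scores with `logFC = mean difference` on the log
  scale, `FC = e^{logFC}`, t-based 95% CIs, and Benjamini–Hochberg FDR
  across cell types.
- **Toxicity classification.** Stratified 5-fold cross-validation of eight
  model families (regularized linear, RBF SVM, random forest, extra trees,
  two gradient-boosting variants, a soft-voting ensemble, and an MLP) on
  drugs × cell-type score features, with accuracy, F1, AUROC, sensitivity,
  specificity, and a stratified-bootstrap AUROC CI.
- **Bulk arm.** Replicate collapsing and per-gene differential expression
  between toxic and non-toxic signature profiles with the
  `p < 0.05, |log2FC| ≤ 1` selection rule (conventional `≥` available).

## Worked example

```r
library(nephrosig)

specs  <- kidney_cell_type_specs(n_genes = 400, markers_per_type = 12, seed = 1)
cfg    <- synthetic_config(n_cells = 800, n_genes = 400, n_donors = 6, seed = 1,
                           cell_type_specs = specs)
kidney <- log_normalize(simulate_cell_matrix(cfg))
kidney
#> cell_matrix: 800 cells x 400 genes
#>   sparsity: 85.1% zeros | layers: counts, logcounts
#>   abstract types: Nephron (83.4%), Endothelium (8.4%), Immune (6.1%), Stroma (2.1%)
#>   donors: 6

# drug database with a toxicity signal seeded in proximal-tubule markers
drugs  <- simulate_drug_db(50, 150, signal_spec("Proximal tubule", 0.5),
                           gene_universe = gene_ids(kidney),
                           markers = marker_genes(specs), seed = 2)
scores <- log_transform_scores(score_cells(kidney,
            build_target_matrix(drugs, gene_ids(kidney))))
sig    <- compare_groups(aggregate_by_cell_type(scores, "detailed32"))
head(as.data.frame(sig), 3)
#>                cell_type t_statistic log_fold_change fold_change      p_value  corrected_p
#> 1        Proximal tubule   12.925360        6.461377  639.941804 5.644650e-27 1.806288e-25
#> 2    Thin ascending limb    2.539297        1.986132    7.287295 1.281856e-02 2.050969e-01
#> 3 Glomerular endothelium    1.965563        1.518645    4.566032 5.267552e-02 3.154642e-01
```

The seeded susceptible type (Proximal tubule) is recovered as the only
cell type significant after FDR correction, with nephrotoxic drugs scoring
higher (positive t and logFC; `fold_change = exp(log_fold_change)`). The
inflated fold change is a property of the log-score scale on sparse
synthetic data, not of real kidneys. Classifying drugs from the same
cell-type features:

```r
feats <- build_feature_table(aggregate_by_cell_type(scores, "detailed32"))
cross_validate(feats, "extra_trees", seed = 3)
#> eval_report: 1 model(s), positive class = nephrotoxic
#>    model_name accuracy  f1 auroc sensitivity specificity auroc_ci_lower auroc_ci_upper
#> 1 extra_trees     0.83 0.5 0.958        0.34       0.993          0.929           0.98
```

An AUROC of 0.96 with a bootstrap CI well above 0.5 shows the embedded
cell-type signal is learnable from the score features (the low sensitivity
at the default 0.5 threshold reflects the 1:3 class imbalance, not ranking
quality).

For the full chain (simulate → QC → score → signatures → classify) with an
output directory and reproducibility manifest, see `run_pipeline()` /
`pipeline_config()`, or the command-line wrapper
`inst/scripts/nephrosig.R`. The power simulation is available as
`run_power_grid()`; `plot()` on its result draws the power curves.

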