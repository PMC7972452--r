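# wormlineage

Quantitative analysis of tracked 4D cell lineages in early
*Caenorhabditis elegans* embryos.

The first division of the *C. elegans* zygote is unequal: the anterior
daughter AB takes ~60% of the embryo, the posterior daughter P1 ~40%.
When this division is experimentally equalized (relative AB size
48–53%), a large fraction of embryos dies even though the lineage
program starts out looking normal. `wormlineage` implements the
quantitative machinery needed to ask *which* lineage features
distinguish dying from surviving embryos:

- **IO** for nucleus-tracking data: a native long-format table and
  best-effort StarryNite/AceTree `t###-nuclei` exports, with Sulston
  nomenclature utilities (founder assignment, canonical daughters,
  stage cohorts).
- **Alignment**: temporal scaling of each embryo's cell-count curve to
  a reference pace (scale `s` maximizing the Pearson correlation of the
  interpolated curves, time zero at ABa division), A-P/D-V/L-R axis
  inference (PCA + MS-lineage centroid), and a control reference model
  built by Generalized Procrustes Analysis of per-cell metaphase
  landmarks.
- **Features**: 13 per-cell variables — StartTime, EndTime, LifeTime;
  pAP, pLR, pDV; totdis, netdis; aAP, aLR, aDV; and against the
  reference model the angular deviation aMean = ∠(v, v_ref) and the
  positional deviation pOV = ‖x − x_ref‖ — plus qualitative phenotype
  flags (EMS skew > 35°, MSa/MSp left-right inversion, extra germline
  divisions, AB–P1 asynchrony, 4-cell T-arrangement).
- **Statistics**: Welch tests with BH correction, a 15%-effect screen
  whose p-value cutoff α is calibrated to a 10% false discovery rate by
  label permutation (FDR(α) = E[passes under shuffles] / observed),
  per-cell SD/CV variability with ANOVA + Tukey HSD, a robustness
  screen (mean unchanged, variance inflated), and AB-size bin /
  correlation analyses.
- **Classifier**: L1-penalized logistic regression (glmnet) with
  stratified 5-fold cross-validation repeated 250 times, λ chosen at
  minimal CV mean squared error, per-feature inclusion frequencies,
  and the ROC of the best model, compared across the 4-, 8-, 15- and
  28-cell stage feature universes.
- **Synthetic embryos**: a seeded generator producing lineages with the
  statistical structure above (canonical topology, lineage clocks,
  eggshell-constrained positions, planted dead-embryo signatures), so
  the whole pipeline is testable end to end without microscopy data.

## Worked example

Simulate a small cohort, build the control reference, and run the
screen and the classifier:

```r
library(wormlineage)

cfg <- pipeline_config(
  seed = 11,
  sim = sim_config(n_embryos = c(wild_type = 3, control = 6,
                                 equalized_alive = 8,
                                 equalized_dead = 10, inverted = 3),
                   truncation_fraction = 0.1),
  lasso = lasso_config(n_repeats = 40),
  stages = c(4, 8, 15))
res <- run_pipeline(cfg, out_dir = "run1")
str(res$summary)
#> List of 8
#>  $ n_embryos                       : int 30
#>  $ gpa_residual                    : num 3.21
#>  $ alpha_star                      : num 0.001
#>  $ n_passing_features              : int 2
#>  $ asynchrony_ab_size_r            : num 0.82
#>  $ asynchrony_ab_size_p            : num 2.92e-08
#>  $ extra_p4_fraction_equalized_dead: num 0.4
#>  $ accuracy_by_stage               : Named num [1:3] 0.762 0.735 0.925
```

Reading the output: the AB–P1 division asynchrony correlates strongly
with relative AB size across the cohort (r = 0.82) — asynchrony shrinks
as the first division approaches equality; 40% of the dying equalized
embryos show at least one extra germline (P4-lineage) division; and the
Lasso predicts death far better from 15-cell-stage features (accuracy
0.93) than from the 4-cell stage (0.76), because the planted
dead-embryo signatures (dorsal displacement of ABar progeny, inflated
Ca motility, MS division-angle skew) only become measurable at the
8–15-cell stages. `run1/` contains the lineages, feature tables,
screen, classifier results and a provenance manifest; rerunning with
the same config reproduces `result.json` byte-identically.

Individual stages are plain functions: `simulate_cohort()`,
`build_reference()`, `extract_features()`, `permutation_fdr_alpha()`,
`lasso_cv()`, `phenotype_flags()`, … — see the help pages and the
vignette in `vignettes/lineage-analysis.Rmd` for the methods.

Real recordings can be validated offline with
`validate_against_deposit("<dir>")`, where `<dir>` holds one
subdirectory of `t###-nuclei` files per embryo plus a `metadata.csv`;
nothing is ever downloaded.

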