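# lipidcap

Plasma phospholipid biomarker discovery for community-acquired pneumonia
(CAP), implemented as a reusable, fully tested R pipeline.

Acute pneumonia reorganizes the plasma lipidome: phosphatidylcholines
(PC), lysophosphatidylcholines (lysoPC) and sphingomyelins (SM) drop
sharply at admission and normalize with clinical recovery, while
ceramides and acid sphingomyelinase (ASM) activity rise. These shifts
carry diagnostic information — against healthy controls and against the
clinically similar COPD exacerbation with infection — and their time
course tracks resolution. `lipidcap` packages the statistical workflow
needed to mine a targeted lipidomics panel (145 analytes: 76 PC, 14
lysoPC, 15 SM, 40 acylcarnitines, plus an optional 4-ceramide extension)
for such biomarkers, for clinical metabolomics analysts working with
wide-format concentration tables.

## What it computes

* **QC and imputation** — analytes are kept when measured above the
  limit of detection (LOD) in at least 75% of samples; remaining flagged
  cells are replaced by per-analyte ordinary least-squares regression on
  age, sex, disease group and collection timepoint, floored at LOD/2.
* **47 metabolic indicators** — class sums, class ratios and lipid-pair
  ratios (11 + 11 + 25), e.g. total lysoPC, total SM/total PC,
  lysoPC a C16:0 / lysoPC a C16:1, dicarboxyl-AC/total AC, from an
  editable YAML definition file.
* **Differential abundance** — fold change as the ratio of group
  medians, two-sided Mann–Whitney U and Kruskal–Wallis tests,
  Benjamini–Hochberg correction at FDR 0.05, applied separately to the
  analyte and indicator families.
* **Cross-validated ROC biomarker calls** — per feature, a univariate
  logistic scorer under stratified 5-fold cross-validation repeated 25
  times; mean AUC with a 2.5/97.5 percentile CI over the 125 fold AUCs.
  A feature is a biomarker candidate when mean AUC ≥ 0.80, the
  Mann–Whitney asymptotic p < 0.05, and the lower 95% CI bound stays
  above the chance line AUC = 0.50. Minority-class oversampling and a
  corticosteroid-adjusted logistic check are included.
* **Resolution markers (LFS / NDF)** — for each feature, the ratios of
  CAP timepoint medians to the control median (d1, d2, d4, f1, f2) are
  fitted by least squares against ordinal time. The linear fitting slope
  (LFS) measures speed of normalization; the normalized distance to
  fitting, NDF = Σ|residual| / (max − min) / 5, measures linearity.
  Features are ranked by |LFS| · (1 − NDF).
* **Ordination and correlation** — PCA centroid trajectories per
  group/timepoint, Euclidean "reprogramming distance" between group
  means in standardized feature space (normalized by √p for comparable
  subclasses), and Pearson correlation of every feature with CRP and
  procalcitonin over the CAP time course.
* **Synthetic cohorts** — because the emulated study design involves
  data that are not publicly deposited, a seeded generator reproduces
  its structure (29 CAP subjects at 5 timepoints with one lost after
  d4, 13 COPD, 33 controls; log-normal concentrations with
  class-specific disease effects and recovery; LOD censoring; Table-1
  style CRP/PCT/ASM distributions coupled to a latent inflammation
  scale), with a truth sidecar for parameter-recovery testing.

## Worked example

```r
library(lipidcap)

cohort <- generate_cohort(generator_config(seed = 42))
cohort$dataset
#> <lipid_dataset> 189 samples x 145 analytes (CAP=143, COPD=13, CTRL=33);
#>   14.2% cells flagged missing

qc <- lod_filter(cohort$dataset)
qc$report
#> <qc_report> 111/145 analytes kept (detected fraction >= 0.75)
#>        kept dropped
#> AC       10      30
#> lysoPC   13       1
#> PC       75       1
#> SM        8       2
#> SM(OH)    5       0

ds <- impute_missing(qc$dataset)

rt <- roc_table(ds, default_contrasts()$CAP_d1_vs_CTRL, seed = 42)
head(rt[, c("feature", "mean_auc", "ci_low", "ci_high", "is_biomarker")], 3)
#>       feature  mean_auc    ci_low ci_high is_biomarker
#> 1 PC ae C38:0 1.0000000 1.0000000       1         TRUE
#> 2 PC aa C32:2 0.9992381 0.9785714       1         TRUE
#> 3 PC ae C38:4 0.9970794 0.9722222       1         TRUE

lt <- lfs_table(ds)
head(lt[!lt$wrong_direction, c("feature", "lfs", "ndf", "rank_score")], 3)
#>          feature       lfs        ndf rank_score
#> 1 lysoPC a C26:0 0.1502030 0.05152488  0.1424638
#> 2 lysoPC a C20:4 0.1320914 0.05562339  0.1247441
#> 3 lysoPC a C24:0 0.1170737 0.03373032  0.1131248

i <- c(sample_index(ds, "CAP", "d1"), sample_index(ds, "CTRL"))
cv_auc(ds$samples$asm_activity[i], ds$samples$group[i] == "CAP", seed = 42)
#> <cv_auc> mean AUC 0.976 [0.882, 1.000] over 125 folds (29 vs 33, up)
```

Reading the output: the QC screen keeps 111 of 145 analytes, with
acylcarnitines by far the worst detected, as expected for this panel on
plasma. The strongest CAP-vs-control classifiers are
phosphatidylcholines with cross-validated AUCs near 1 under this
synthetic effect size; the resolution-marker screen ranks
lysophosphatidylcholines on top — their configured recovery profile is
the steepest and most linear — and ASM activity alone separates CAP from
controls with a mean cross-validated AUC near 0.98.

One call runs everything and writes CSV artifacts plus a deterministic
manifest:

```r
cfg <- run_config(generator = generator_config(seed = 0),
                  seed = 7, out_dir = "run1")
run_all(cfg)
report_run("run1")
```

## Further reading

The methods vignette (`vignettes/lipidcap-methods.Rmd`) documents the
generative model and its default parameters, the statistical choices
(CI construction, tie handling, degenerate-input rules), what the
synthetic cohorts do and do not emulate, and known limitations.
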