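---
title: "Methods: models, parameters and design choices in lipidcap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in lipidcap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidcap)
```

`lipidcap` implements the statistical workflow for discovering plasma
phospholipid biomarkers of community-acquired pneumonia (CAP) against
infection-associated COPD exacerbation and matched controls. This
vignette is the package's own account of the science: the models and
procedures, the parameters that matter and why their defaults are what
they are, the numerical edge-case rules, and what the synthetic cohorts
can and cannot tell you about real data.

## The analysis problem

The input is a wide concentration table (samples × analytes, µM) from a
targeted lipidomics panel — 76 phosphatidylcholines (PC), 14
lysophosphatidylcholines (lysoPC), 15 sphingomyelins (SM, including 5
hydroxy-SM), 40 acylcarnitines (AC), optionally 4 ceramides — plus
per-sample metadata: subject, group (CAP / COPD / CTRL), collection
timepoint (admission d1; d2; d4; two follow-ups f1, f2 for CAP), age,
sex, CRP, procalcitonin (PCT), acid sphingomyelinase (ASM) activity and
corticosteroid treatment. The questions: which lipid features separate
the groups at baseline, which track clinical resolution over the CAP
time course, and how much of the signal is mere inflammation (CRP/PCT).

## Preprocessing

**LOD filter.** An analyte is kept when its measured value exceeds its
limit of detection in at least `min_detect_frac` (default 0.75) of all
samples, pooled over groups and timepoints. The boundary is inclusive.
Below-LOD cells keep the raw reported value in the container but are
flagged in a missingness mask; flags, not values, drive the filter.

**Imputation.** Flagged cells of the kept analytes are replaced by
predictions from a per-analyte ordinary least-squares regression of the
observed concentrations on age, sex, disease group, and collection
timepoint — one pooled model per analyte, fitted across all groups.
Timepoint is coded as categorical indicators with non-CAP samples mapped
to the baseline (d1) reference level; this avoids imposing a linear time
trend and keeps group and timepoint separately estimable. Design
choices an implementer must make that the procedure itself does not fix:

* *Fitting scope*: one pooled model (group and timepoint are
  predictors, which only makes sense jointly fitted).
* *Negative predictions*: OLS predictions can be negative;
  concentrations cannot. Imputed values are floored at half the
  analyte's LOD, the conventional substitution value for censored
  concentrations.
* *Feasibility*: each analyte needs at least p + 2 observed values
  (p = number of design columns); rank-deficient designs drop aliased
  columns with a warning. Analytes censored so heavily that no model is
  estimable are exactly the analytes the LOD filter removes first.

## The 47 metabolic indicators

Derived features come in three kinds: class sums (11), class ratios
(11), and specific lipid-pair ratios (25), computed per sample from an
editable YAML file. The shipped set reconstructs the panel-typical
collection: the six indicators named in the field's reports on this
panel (total lysoPC; total SM; total SM / total PC;
lysoPC a C16:0 / C16:1; lysoPC a C20:4 / C20:3; dicarboxyl-AC / total
AC) completed with per-class and per-bond-type sums, saturation splits,
and pair ratios stepping one double bond or one chain modification —
16 of the 47 involve acylcarnitines. The exact membership of the
original set is not published; since the definitions live in a config
file, the original can be dropped in verbatim if obtained.

Two interpretation decisions: sums are per-sample sums (cohort summaries
of them reproduce "sums of mean concentrations" up to exchange of sum
and mean, and the downstream tests are per-sample); and a zero
denominator yields an undefined value for that sample, flagged and
excluded from that indicator's tests rather than propagated as
infinity. In the full pipeline, indicators are computed from imputed
values for QC-passing analytes and raw reported values for dropped ones
(the instrument reports a number either way), so ratios referencing
poorly detected acylcarnitines remain computable.

## Differential abundance

Fold change is the ratio of case to control medians — robust, and
interpretable on concentrations. Group differences use the two-sided
Mann–Whitney U test and, across the CAP timepoints, the Kruskal–Wallis
H test, both with average-rank tie handling and tie-corrected variance;
the Mann–Whitney p uses the normal approximation with continuity
correction (verified against exact permutation within 0.017 at n = 5 per
arm). Degenerate inputs (all values tied) return p = 1 with a flag.
Benjamini–Hochberg correction at FDR 0.05 is applied within each feature
family — analytes and indicators separately, since the two families are
reported and annotated independently; pooling them would couple their
thresholds for no analytic gain.

## ROC biomarker screening

Each feature is scored alone: a univariate logistic regression under
stratified k-fold cross-validation (k = 5) repeated 25 times. The
feature is standardized with training-fold statistics only, so no
information leaks into the held-out fold; the logistic model is fitted
unpenalized (a separation-prone fold simply yields a saturated but
rank-consistent scorer, which is all the AUC uses). The point estimate
is the mean over the 125 fold AUCs; the 95% CI is the 2.5/97.5
percentile of the fold-AUC distribution — distribution-free and the
natural interval for a repeated-CV estimate, since no closed form
exists for it. A biomarker call requires all of: mean AUC ≥ 0.80
("excellent classification"), Mann–Whitney asymptotic p < 0.05, and
lower CI bound above the chance line 0.50.

The full-data rank AUC equals U/(n₁·n₂) from the Mann–Whitney statistic
— an identity the tests verify exactly — which ties the second and
first criteria to the same ordering information.

To ask whether an unbalanced comparison (13 COPD vs 33 controls) is
biomarker-poor because of size, `oversample_minority()` resamples the
minority arm with replacement up to the majority size before the CV is
re-run. Oversampling before the fold split replicates the referenced
procedure but lets duplicates span folds, which optimistically biases
the CV estimate; this caveat is documented and duplicates are tagged in
the returned dataset so a leakage-safe variant (oversampling within
training folds only) can be applied by filtering on the tags.
`covariate_adjusted_test()` fits label ~ feature + corticosteroid and
reports the Wald p for the feature; complete separation is detected and
handed to a small fixed-ridge logistic fit, flagged in the output.

## Resolution markers: LFS and NDF

For each feature, the five ratios of CAP timepoint medians to the
control median are regressed on ordinal time 1..5. The slope (LFS)
measures how fast the feature normalizes; the normalized distance to
fitting, NDF = Σₜ|residualₜ| / (max ratio − min ratio) / 5, measures how
linear the trajectory is (0 = perfectly linear). Decisions:

* *Ordinal time*: follow-up visits occur at variable per-patient times,
  so calendar days would inject per-patient noise the medians cannot
  carry; positions 1..5 are used and are configurable. LFS rescales by
  the known factor under any affine re-axis; NDF is invariant (tested).
* *Distance*: vertical absolute residual. The quantities are ratios
  against ordinal time; perpendicular distance would mix units.
* *Degenerate range*: a constant series fits its own line perfectly, so
  max = min gives NDF = 0 (and LFS = 0).
* *Ranking*: the screen is usually read off the (LFS, 1 − NDF) scatter
  by eye; the package makes the composite explicit,
  rank\_score = |LFS| · (1 − min(NDF, 1)), flags features whose d1
  ratio sits on the wrong side of 1 for their slope direction (moving
  away from control levels), and exports the scatter coordinates so
  users can apply their own cut.

## Ordination and correlation

PCA operates on the feature matrix standardized with the population
variance (divisor n, matching the standardize-then-decompose
convention); zero-variance columns are dropped with a warning. Group ×
timepoint centroids are reported in component space and in full
standardized space. The "reprogramming distance" between two groups is
the Euclidean distance between their mean vectors in full standardized
feature space, not in the 2-component projection: subclasses of
different dimensionality are compared, and a 2-D projection would
confound subclass differences with projection loss. Dividing by √p
makes a 76-feature and a 14-feature distance comparable (a per-feature
mean displacement); the raw distance is reported alongside.

Pearson correlations with CRP and PCT are computed over CAP samples
pooled across the time course, on raw concentrations. Note that Pearson
on strongly right-skewed raw markers is attenuated relative to the
log scale; the generator couples lipids and markers on the log scale, so
log-scale correlations in synthetic cohorts are substantially stronger
than their raw-scale counterparts.

## The synthetic cohort generator

No public data accompany the emulated design, so the generator is a
first-class, tested module whose defaults *are* the study conditions:
29 CAP subjects sampled at d1, d2, d4, f1, f2 with exactly one lost to
follow-up after d4; 13 COPD and 33 controls sampled once; ~60-year-old,
sex-balanced arms; corticosteroid probabilities 0.22 / 0.62 / 0.03.

Concentrations are log-normal:
log C = µₐ + u₍ₛ,ₐ₎ + Lₛ · r_c(t) · log mₐ + ε, with per-analyte
baselines µₐ drawn around class-typical plasma levels, a per-subject ×
analyte biological effect u (log-SD 0.30), measurement noise ε (log-SD
0.15), class multipliers mₐ and recovery fractions r_c(t), and a latent
per-subject inflammation scalar Lₛ (log-SD 0.3) that scales both the
lipid effect and the CRP/PCT/ASM medians — producing the negative
lipid–inflammation correlations without hard-coding any correlation
target. Default effect directions mirror the reported baseline pattern:
PC strongest down (×0.42 at d1), then lysoPC (×0.55, fastest and most
linear recovery), SM down (×0.70) with three SM up in COPD, AC flat
except the short-chain C5 up, PC ae C36:0 up, ceramides C16:0 / C18:0 /
C24:1 up in the extension panel. Effect jitter across analytes is
*relative* (log mₐ = log m_class · (1 + ε), SD 0.25), so null classes
stay exactly null — this keeps type-I calibration testable.

Clinical markers draw log-normally around the group medians of the
emulated study population (CRP 102 / 14 / 3.1 mg/l, PCT 0.23 / 0.09 /
0.02 ng/l, ASM fold 2.8 / 1.75 / 1 over controls), floored at their
assay reporting limits, decaying toward control medians by f2. The ASM
dispersion (log-SD 0.36 plus the inflammation coupling) was fixed a
priori so the configured 2.8-fold implies a discrimination consistent
with the reported ASM ROC accuracy.

LODs are the configured quantile of each analyte's *parametric* control
marginal (the generator knows its truth), because an empirical quantile
of 33 controls cannot reach the tiny tail quantiles a real assay LOD
corresponds to. Per-analyte default quantiles (phospholipids 10⁻⁶, ten
well-detected AC 0.03, the remaining AC and four specific phospholipids
0.5) reproduce the panel's characteristic QC outcome: ~111 of 145 kept,
acylcarnitines worst. Raising a quantile can only add masked cells
(tested monotonicity).

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: correlated lipid co-regulation
within pathways (analytes are conditionally independent given class and
inflammation), non-log-normal tails, batch/plate effects, informative
dropout, diet effects, or etiology subgroups. Effect-to-noise under the
defaults is somewhat cleaner than in clinical cohorts, so biomarker
*counts* on synthetic data run higher than a real study would report;
the qualitative orderings (PC > lysoPC ≥ SM > AC reprogramming
distance, lysoPC-dominated resolution ranks) and the calibration
properties are the transferable claims.

## Problem sizes used by the tests

Module tests run on miniature panels (16 analytes) and small arms;
calibration and ordering checks use the full default cohort: 500+ null
features over 5 seeds for type-I calibration, 50 seeds for the
qualitative orderings, 50 replicates for each Monte-Carlo recovery
check, 1,000 random p-vectors for the Benjamini–Hochberg oracle, and
2 × 9-stage pipeline runs for determinism. These sizes were chosen so
the complete suite exercises every stochastic claim while staying
comfortably within a coffee break on one CPU.

## Known limitations

* The indicator set and panel membership are reconstructions with the
  correct counts and naming conventions, not certified copies of the
  proprietary originals; both are user-replaceable config files.
* Imputation is single-draw OLS: no uncertainty propagation into
  downstream p-values.
* The CI for the CV-AUC is a percentile over fold AUCs, which reflects
  fold-to-fold variability, not a full sampling distribution of the
  mean; with 125 correlated folds it is somewhat anti-conservative.
* Oversampling before CV (the replicated procedure) optimistically
  biases the balanced-design AUCs; use the duplicate tags to build the
  leakage-safe variant when that matters.
* Raw-scale Pearson correlations with heavily skewed markers are
  attenuated; consider log-transforming markers for screening.
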