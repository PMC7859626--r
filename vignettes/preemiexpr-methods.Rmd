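---
title: "Methods: transcriptomic biomarkers for preterm respiratory outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptomic biomarkers for preterm respiratory outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`preemiexpr` implements an analysis pipeline for bulk RNA-seq biomarker
discovery in preterm infants, where the outcomes of interest are
bronchopulmonary dysplasia (BPD) in the extremely premature subgroup (born
before 29 weeks gestational age) and post-prematurity respiratory disease
(PRD) across preterm and term infants at one year corrected age. The
pipeline covers: count preprocessing (conditional upper-quartile
normalization with prevalence filters), neonatal oxygen-exposure metrics and
outcome labeling, three univariate differential-expression screens, a
screened-principal-components (sPCA) classifier for BPD, a
pathway-eigengene forward-selection classifier for PRD, and a synthetic
cohort generator used for calibration and power studies. Real cohorts of
this design are typically controlled-access, so the generator is a
first-class, tested component rather than a test fixture.

# Preprocessing model

Raw HTSeq-style counts (genes x subjects) pass through a fixed sequence:

1. **Zero-prevalence gene filter.** A gene with zero counts in *over* one
   third of subjects is considered not consistently expressed and removed.
   The boundary is strict: exactly one third is retained. All prevalence
   comparisons are done in integer arithmetic so boundaries are exact.
2. **Low-read subject filter.** A subject whose fraction of genes at raw
   count <= 5 strictly exceeds 75% is excluded.
3. **Conditional upper-quartile (UQ) normalization.** For each subject the
   conditional UQ is the 75th percentile of that subject's *non-zero*
   counts. The normalization factor is `f_s = UQ_s / mean(UQ)`, with the
   mean taken over subjects retained at this stage, so factors average to 1
   by construction (the alternative — computing the mean before subject
   exclusion — would leave factors off-centre for no benefit). Normalized
   values are `raw / f_s`; adding 1 and taking log2 gives the working
   matrix. Two consequences worth knowing: the conditional UQ of every
   subject's normalized values equals the global mean UQ *exactly*, and the
   factors are invariant to rescaling all counts by a constant.
4. **Low-normalized gene filter.** Genes whose normalized (pre-log) value
   is <= 3 in strictly more than 75% of subjects are removed.

The 75th-percentile convention is linear interpolation between order
statistics (R quantile type 7). The convention is parameterized
(`quantile_type`) because published descriptions of UQ normalization rarely
pin it down; the oracle tests pin the default.

Outlier screening by hierarchical clustering or PCA is inherently
judgment-based, so `flag_pca_outliers()` is report-only: it flags subjects
beyond `k_sd` (default 4) standard deviations on PC1/PC2 of the log2 matrix
but never excludes anyone automatically.

# Oxygen exposure and outcome labels

**Effective FiO2.** Oxygen delivered by low-flow nasal cannula is diluted by
entrained room air. The correction is
`0.21 + (FiO2 - 0.21) * c(weight, flow)` with the dilution fraction `c`
interpolated bilinearly from a shipped weight-by-flow table. The published
bedside conversion charts are not redistributable, so the shipped table
(`synthetic_effective_fio2_table.tsv`) is a synthetic stand-in derived from
a simple inspiratory-flow model (`c = min(1, flow / (0.9 L/min/kg * kg))`).
It preserves the qualitative structure of such charts — monotone in flow,
diminishing with weight, exact room air at zero flow — and is versioned so
a site-specific chart can be dropped in.

**Oxygen AUC.** Cumulative oxygen utilization through day `d` is, by
default, the sum over days 1..d of the daily noon effective FiO2 excess
over 0.21 (units: FiO2-excess x days; 14 days at FiO2 0.30 gives 1.26). The
original formulation is cited in the clinical literature but the integrand
(how support pressure and mode weigh in) is not recoverable from the
sources this package follows; the integrand is therefore a named,
swappable strategy (`convention`), and the default ignores pressure. The
choice preserves the ordering of exposure severity, which is all the
downstream rank-based screen consumes. Missing flowsheet days are carried
forward for at most 2 days, beyond which room air is assumed with a
warning.

**Labels.** BPD by the birth-weight criterion is supplemental oxygen at 36
weeks postmenstrual age in infants under 1500 g (at or above 1500 g the
label is "not-applicable"). BPD by physiologic (room-air-challenge)
criterion requires at least 28 — not necessarily consecutive — days above
room air plus a failed challenge; an eligible infant without a recorded
challenge is "not-assessed". The two definitions may disagree and are never
coerced. PRD is positive when at least two of the four caregiver surveys
(3, 6, 9, 12 months corrected age) report a positive respiratory-morbidity
domain. With missing surveys, "no" is only assigned when a second positive
survey is arithmetically impossible (`positives + missing < 2`), which
implies at least three completed surveys — otherwise the label is
"missing".

# The three univariate screens

All screens default to a false-discovery threshold of 0.1, matching the
reporting convention of the analyses this pipeline reproduces (their
methods sections sometimes quote 0.05; the threshold is configuration, and
the run manifest logs what was used).

1. **Oxygen correlation.** Per gene, Spearman rank correlation between log2
   normalized expression and 14-day oxygen AUC in the at-risk (<29 week)
   subgroup, two-sided t-approximation p-values, Benjamini–Hochberg (BH)
   q-values.
2. **Resampling count test.** A reimplementation of the two-class
   resampling rank test for sequencing counts: subjects are Poisson
   down-sampled to the minimum subject depth (default 20 resamples), a
   standardized Wilcoxon rank-sum statistic (tie-aware via the
   finite-population rank-variance formula) is averaged over resamples, and
   label permutations (default 1000) provide the null. The median FDR at a
   cutoff is the median across permutations of null exceedances divided by
   observed exceedances, with monotonicity enforced. It operates on raw
   counts of the retained genes/subjects: down-sampling, not UQ
   normalization, is its depth correction.
3. **GAB-adjusted LRT.** Per gene, logistic regression of the outcome on
   gestational age (null) versus gestational age plus log2 expression
   (full); `2 * (ll_full - ll_null)` referred to chi-square(1), BH
   q-values. Fits are by IRLS; (quasi-)separated genes are refit with a
   small ridge penalty (lambda = 1e-3) and flagged rather than dropped.

Fold changes are reported as the log2 ratio of group medians of normalized
(pre-log) values with a +0.5 offset against zero medians; published
fold-induction numbers rarely define their estimator, so this one is
deliberately simple and robust.

# Screened principal components (BPD)

Genes are screened univariately (two-sided Wilcoxon rank-sum, nominal
p < 0.10 by default; exact distribution when both groups are small and
untied, otherwise normal approximation with tie and continuity
corrections). PC1 of the survivors is computed on centered, unit-variance
genes (correlation-scale PCA; covariance mode available — the scale choice
is open in the source material, and correlation scale avoids letting a few
high-variance genes dominate a screen that is already variance-agnostic).
Loadings below 10% of the maximum absolute loading are pruned and PC1
refit once; the sign is fixed so loadings sum positive. A logistic model
predicts the outcome from the PC1 score (optionally plus gestational age;
with adjustment, the screen itself uses rank-residualized expression, a
rank-based partial association).

The screening threshold is chosen by inner cross-validation over
`{0.001, 0.005, 0.01, 0.05, 0.10}` (stratified 10-fold, 3 repeats by
default; ties prefer the smaller, more stringent threshold). Honest
performance comes from an outer nested-CV loop in which the *entire*
procedure — screening, threshold selection, PC fitting — is rerun inside
each outer training fold and held-out probabilities are pooled into one
ROC. The naive AUC is computed from in-sample predictions of the full-data
refit; the contrast between naive and CV AUC is reported side by side
because that gap is the single most informative honesty check in this
design (on pure-noise cohorts the naive AUC approaches 1 while the CV AUC
stays near 0.5). AUC is computed as the tie-corrected Mann–Whitney
statistic, which equals the trapezoidal area of the reported ROC points
exactly.

# Pathway-eigengene classifier (PRD)

Curated gene sets (GMT format; membership is many-to-many) are each reduced
to the PC1 of their member genes ("pathway eigengene", no loading pruning).
Genes absent from the matrix are dropped per set; genes in no pathway never
contribute. A univariate logistic likelihood-ratio test screens pathway
scores; bivariate CV jointly selects the screening threshold and the number
of forward-selection steps (or the LASSO penalty, via `glmnet`), with ties
broken toward fewer pathways and then the more stringent screen. The final
model reports pathways in selection order with their joint logistic
coefficients (log odds ratios) and, per member gene, a univariate odds
ratio on standardized log2 expression — the per-gene column is a
descriptive annotation (its definition is not pinned down in the published
table format it mirrors) and is labeled as such in the output.

Pathway PC1s are computed inside training folds by default, so no
information from held-out subjects reaches the eigengene construction; a
`global` PC mode exists for sensitivity analysis, since fitting eigengenes
once on all subjects is a common (mildly leaky) practice. Gestational-age
adjustment is a flag, default off for the PRD recipe (adjustment is
supported in both screen and model; in the motivating analyses it did not
improve PRD performance). A gestational-age-only logistic baseline ROC is
always fit alongside the nested evaluation for comparison.

`count_model_genes()` counts *distinct* genes across selected pathways —
a gene shared by two selected pathways counts once. The shipped
`prd_pathways.gmt` carries the published four-pathway, 28-distinct-gene
PRD classifier membership (29 membership rows; one organic-anion
transporter gene appears in two sets) and doubles as the worked example.

# Synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, at
the scale of the motivating study (defaults: 13,500 genes x 145 subjects):

- **Counts**: gene-wise negative binomial (dispersion 0.3) with log-normal
  base means (median ~60) and log-normal per-subject depth multipliers
  (sigma 0.35). The depth factor makes UQ normalization consequential and
  testable.
- **Gestational age**: 23–41 weeks, drawn half below / half above 29 weeks
  so the at-risk subgroup is about half the cohort, as in the cohort design
  this emulates (72 of 145 born <29 weeks).
- **Outcomes**: BPD only below 29 weeks at prevalence 34/72, with risk
  rising as gestational age falls; PRD via a logistic link in gestational
  age (slope -0.25/week) whose intercept is calibrated on the drawn sample
  so the marginal prevalence matches the configured 70/116; 14/130 of
  subjects have missing PRD status. A physiologic-challenge BPD label
  mostly agrees with the birth-weight label (15% disagreement), because
  downstream code must represent disagreement, never coerce it.
- **Pathway blocks**: disjoint gene blocks share a per-subject latent
  factor. The factor loading is calibrated per gene against the NB sampling
  noise (`tau^2 = rho/(1-rho) * log(1 + dispersion + 1/mu)`) so that the
  *observed* pairwise correlation within a block approximates the
  configured value — at a target of 0.8 the realized mean pairwise Spearman
  correlation lands within 0.1 of it at n = 500.
- **Planted signal**: a configurable fraction of genes (default 0.4%,
  roughly 54 genes) has its mean multiplied by `2^signal_log2fc` (default
  0.75, i.e. a 1.7-fold change — deliberately below 2, matching the modest
  effect sizes typical of this setting) in outcome-positive subjects;
  whole pathways can carry the effect too. Truth is serialized as
  versioned JSON so recovery tests never parse logs.
- **Oxygen traces**: 28 daily records following a declining-exponential
  FiO2-excess trajectory floored at room air; lower gestational age raises
  the peak, BPD slows the wean. Support mode, cannula flow and pressure are
  derived from the daily target. A term infant without BPD produces a flat
  room-air trace. No clinical realism is claimed beyond monotonicity in
  severity.

What the generator does *not* emulate — batch effects, library-preparation
artifacts, cell-sorting purity, realistic co-expression beyond single-factor
blocks, and any true biology of CD8+ T cells — bounds what green tests
mean: they show the machinery is correct and calibrated under the stated
model, not that the pipeline would recover any particular biological
signal.

# Numerical choices and degenerate inputs

- Quantiles: type 7; parameterized.
- Wilcoxon: exact only for small untied samples; otherwise normal
  approximation with continuity correction and tie correction through the
  observed rank variance (which handles constant genes gracefully: their
  statistic is 0 and p is 1).
- Logistic fits: IRLS to tolerance 1e-10, ridge fallback (lambda 1e-3) on
  separation, flagged. LRT statistics are clipped at 0.
- PC1: SVD; constant genes are dropped before fitting (all-constant input
  errors); sign fixed by positive loading sum, first nonzero loading on an
  exact tie.
- Empty screen survivor sets inside CV folds fall back to predicting the
  training prevalence; an empty survivor set at the final refit is an
  error for the sPCA fit and, in nested pathway evaluation, downgrades the
  affected fold to the prevalence predictor.
- Fold assignment is stratified; if a class has fewer members than folds,
  the fold count is reduced with a warning so every fold holds both
  classes.
- All randomized procedures take explicit seeds, restore the caller's RNG
  state, and derive child seeds deterministically, so identical
  configuration and seed give byte-identical artifacts.

# Problem sizes used by the test suite

The full study scale (13,500 genes x 145 subjects) is exercised by the
acceptance script. The test suite scales simulations to keep iteration
fast while keeping the study's subject counts: null-calibration runs use
72-subject, 4,000-gene cohorts over 20 seeds for the screens and 3 seeds
for the nested classifiers; signal-recovery runs plant 50 genes at log2
fold change 1 among 2,000 genes (n = 72) and one signal pathway among 200
nulls (n = 300) over 10 seeds. These sizes were chosen as the smallest at
which the calibration and recovery properties are stable across seeds.

# Known limitations

- The effective-FiO2 table is a constructed stand-in, adequate for
  monotone exposure ranking but not for bedside use.
- The oxygen AUC integrand ignores applied pressure and support mode; a
  pressure-weighted strategy can be slotted in via `convention`.
- The resampling count test's global-scaling invariance is distributional,
  not exact: Poisson down-sampling draws differ across scales.
- qPCR validation assumes the endogenous-control orientation (higher
  expression, lower dCt); correlations are reported against -dCt so that
  agreement is positive, and the orientation is noted in the output.
- The pipeline reproduces the *machinery* of the motivating analyses;
  identities of specific published gene lists depend on controlled-access
  data and are out of scope.
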