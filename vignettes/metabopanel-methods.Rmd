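---
title: "Methods: from aligned peak tables to a validated metabolite panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from aligned peak tables to a validated metabolite panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(metabopanel)
```

`metabopanel` implements a two-stage workflow for plasma metabolomics
biomarker discovery in a case-control design (here: colorectal cancer
patients versus healthy volunteers). Stage one prioritizes discriminative
spectral features from an untargeted LC-MS peak table; stage two builds an
interpretable logistic-regression panel from quantified concentrations of
the annotated metabolites and stress-tests it across clinical subgroups and
demographic confounds. Because patient-level data of this kind are rarely
public, the package ships a synthetic-cohort generator with known ground
truth; every stage is exercised against cohorts whose answer is known.

## The data model

An aligned peak table is a samples-by-features matrix of nonnegative ion
intensities, each feature carrying an m/z (Da) and a retention time
(minutes). Missing cells are explicit (`NA`), never zeros: a zero intensity
is a measurement, a missing cell is the absence of one, and the two must not
be conflated by a parser. The `feature_matrix` container enforces unique
sample and feature identifiers, positive m/z, and nonnegative present
intensities.

## Post-alignment processing

Four operations, applied in this order:

1. **Minimum peak height** (`filter_min_height`, default 30 000): features
   whose maximum intensity never reaches the threshold are instrument noise.
   The boundary is inclusive — a feature peaking exactly at the threshold is
   kept, which is the conventional reading of a "minimum height" rule.
2. **Internal-standard normalization**
   (`normalize_internal_standards`): three isotope-labeled standards
   (phenylalanine-d2 at 30 nmol/mL, cholic-d4 and lysoPC 19:0 at 2 nmol/mL)
   are spiked into every sample at known levels, so their measured
   intensities estimate each sample's technical gain. Each sample is divided
   by the geometric mean of its three standard intensities and rescaled by
   the across-sample geometric mean of those factors, preserving the global
   intensity scale. The composite geometric mean is used rather than
   chemistry-matched pairing because a single drifting standard then
   perturbs the factor by at most its cube root; a `per-is` mode (each
   feature normalized by the standard nearest in retention time) is
   available where matched pairing is preferred. The operation is
   idempotent. With the default data-derived reference the *relative*
   structure is invariant to per-sample gain; supplying a fixed `reference`
   makes the output exactly invariant to rescaling any single sample.
3. **QC reproducibility filter** (`filter_qc_cv`): features whose
   coefficient of variation across pooled-QC replicate injections is not
   strictly below 15% are dropped — an analytically irreproducible feature
   cannot be a biomarker regardless of its p-value.
4. **Imputation** (`impute_missing`): remaining missing cells become half
   the feature's minimum present value, the standard surrogate for
   below-detection-limit peaks. Imputation is always explicit; no function
   imputes silently.

No log or variance-stabilizing transformation is applied before the
machine-learning stage: the selection machinery below is either
tree-based or rank-based, hence invariant to monotone transforms, and the
final panel is deliberately fit on concentrations in their native units so
its coefficients remain clinically interpretable.

## Stage one: random-subspace random-forest consensus selection

With ~10^5 features and a few hundred samples, a single feature ranking is
both expensive and unstable. The feature space is therefore randomly
partitioned into `k = 10` disjoint subsets of (near-)equal size, and each
subset is ranked independently: a 20-tree random forest (Gini split
criterion, sqrt(p) candidate features per split, unlimited depth, minimum
leaf size 1) is fit on a stratified 70% training split, and features are
ranked by mean decrease in Gini impurity. Twenty trees is deliberately
small — importance *rankings* stabilize long before prediction error does,
and the forest here is a ranking device, never the final classifier.

"Consistently informative" is operationalized as a per-subset top fraction:
the top `ceiling(top_fraction * subset size)` features of each subset are
flagged and the consensus set is their union. The default
`top_fraction = 0.007` reproduces the conventional candidate-set scale of
roughly 1 000 consensus features out of ~147 000; at the synthetic test
scale of 2 000 features we use 0.05, i.e. a candidate set of ~100, about
twice the planted marker count — the analogue of carrying a generous
candidate list into univariate triage. A stability mode
(`subspace_select_stable`) repeats the whole pass over fresh partitions,
training splits and forests, and keeps features selected in at least
`min_support` runs. `tune_top_fraction` grid-searches the fraction by
stratified 5-fold cross-validation confined to training samples.

The consensus set is evaluated by refitting a forest on the stratified 70%
split and scoring the held-out 30%. Held-out sizes use the ceiling
convention with largest-remainder allocation across classes, so a
287-sample cohort yields an 87-sample test set (52 cases + 35 controls) and
a 94-sample cohort yields 29.

**A calibration caveat measured honestly.** On a *fixed* null cohort (no
planted effects), features that separate the classes by chance keep their
high Gini rank under every repartition: the cross-run selection support of
null features is far from binomial-independent. In our measurements
(100/100 samples, 2 000 features, default fraction, ten repartition runs)
the most-selected null feature appeared in 3-4 of 10 runs. Repartition
support therefore separates planted markers (support near 10/10) from noise
only with a high support threshold, and a low threshold such as 25% will
flag a handful of null features. The corresponding acceptance property is
asserted at the low threshold and fails by design rather than being
weakened; treat selection support as a ranking signal, not a familywise
error control.

## Univariate triage

For every consensus feature: the log2 fold change of arithmetic group means
(case over control), a two-sided Mann-Whitney p-value, and a
Benjamini-Hochberg q-value (`volcano`; classes `up`/`down` at q < 0.05 and
|log2FC| >= log2(1.5), both configurable — thresholds of this kind are
conventions, not claims). The per-feature ROC AUC (`feature_auc`) is
computed by midranks, exactly the normalized Mann-Whitney U with ties
counted one half; `auc_filter` retains features with
`max(AUC, 1 - AUC) > 0.90`. The triage is direction-agnostic because
disease-associated metabolites are as often depleted as elevated — in this
setting the discriminative markers are predominantly *reduced* in cases.

Annotation (`annotate_features`) matches feature masses to a reference
table within 0.01 Da (MS1) and scores MS2 fragmentation agreement by cosine
similarity with greedy peak pairing within 0.025 Da; matches are accepted
at a score of at least 0.80. This is a transparent cosine, not any vendor's
composite identification score; when a feature carries no MS2 spectrum the
match is reported as MS1-only with an undefined score and is never
auto-accepted.

## OPLS-DA

`fit_oplsda` implements orthogonal projections to latent structures
discriminant analysis from the NIPALS recursion for a single response:
the class is encoded +/-1, data are mean-centered and unit-variance scaled
(Pareto scaling available), class-orthogonal components are deflated first,
and one predictive component is extracted. By construction the predictive
score is exactly orthogonal to every orthogonal score (asserted at 1e-8 in
the tests). R2Y is the training-data explained response variation; Q2 is
computed by stratified 7-fold cross-validation (the convention of
mainstream OPLS software; the fold count is configurable), with held-out
samples centered and scaled by training-fold parameters. One orthogonal
component is the default; `n_orthogonal = "auto"` adds components while
they raise Q2 by more than 0.01.

OPLS-DA *training* scores always separate the classes — the predictive
weight is estimated toward the response — so model validity is never judged
from the score plot. It is judged by the label-permutation test
(`permutation_test`, default 100 permutations of the labels, statistic Q2,
plus-one estimator `p = (1 + #{permuted >= observed}) / (1 + n_perm)`,
which is bounded below by 1/(n_perm+1) and can therefore never be zero).

## Stage two: the five-metabolite logistic panel

The quantified panel metabolites (N-methylcytisine and 2-piperidone in
ng/mL; theophylline, dl-norleucine and linolenic acid in ug/mL) enter a
logistic regression in native units. Two training modes exist because both
appear in practice: `discovery-train` (the default) fits on the discovery
cohort and applies the coefficients to the validation cohort without
retraining; `validation-split` fits on a stratified 70% of the validation
cohort and evaluates on the held-out 30%. The two modes answer different
questions (transferability versus within-cohort fit) and the package
implements both rather than silently choosing.

Fitting is maximum likelihood via IRLS. Perfect separation — which *does*
occur when group concentration distributions barely overlap — is detected
from diverging standardized coefficients or degenerate fitted
probabilities and flagged; with `penalized = TRUE` a ridge-penalized IRLS
fit (penalty 1e-3 on standardized predictors, intercept unpenalized) is
returned so predictions remain finite and usable.

Performance reporting follows clinical conventions: a confusion matrix at
the 0.5 probability cutoff; sensitivity, specificity, accuracy and F1 as
percentages rounded to one decimal with halves away from zero (base R's
round-half-even would turn a balanced accuracy of 87.25 into 87.2 where the
clinical literature prints 87.3); Wilson score intervals by default with
exact Clopper-Pearson available — the two disagree at the extremes (for
46/47 observed sensitivity the Wilson lower bound is 88.9% while the
Clopper-Pearson upper bound is 0.975^(1/47) = 99.9%), and published
intervals mix them, so both are provided. Balanced accuracy is reported as
the mean of the *rounded* sensitivity and specificity percentages, the
bookkeeping used when rates are quoted to one decimal. The AUC confidence
interval uses the DeLong placement-value variance, with a seeded stratified
bootstrap (2 000 resamples) as the alternative.

Covariate adjustment (`adjust_covariates`) fits, per metabolite, the crude
model `status ~ metabolite` and the adjusted `status ~ metabolite + age +
sex`, reporting both coefficient paths side by side. This is the standard
check when cases are systematically older than controls: a marker whose
apparent effect is entirely age-mediated loses significance under
adjustment, while a marker with a direct effect retains it.

## Cutoffs, strata, trends

Per-metabolite diagnostic cutoffs (`youden_cutoff`) maximize Youden's
J = sensitivity + specificity - 1 over midpoints between adjacent sorted
unique values; ties break toward higher specificity, then the smaller
cutoff. The positive direction is auto-detected from the AUC orientation
(all five panel markers are reduced in disease, so test-positive is
*below* the cutoff). The cutoff method is a convention choice: published
cutoffs of this kind rarely state their optimizer, and Youden's J on the
empirical ROC is the field standard.

Subgroup robustness (`subgroup_compare`) uses the Mann-Whitney test for two
strata and Kruskal-Wallis beyond, with strata under n = 3 excluded loudly.
Stage is dichotomized early (I-II) versus late (III-IV); age is split at
the median of the data at hand, never a hard-coded year. The ordered stage
trend (`stage_trend_test`) uses the Jonckheere-Terpstra statistic — the sum
of pairwise Mann-Whitney counts over ordered stage pairs — with a
tie-corrected normal approximation and a seeded exact-permutation option
for small groups; the test is implemented in-package because no installed
dependency provides it. All of these are rank-based and therefore invariant
under monotone transforms of the concentrations.

## The synthetic cohort generator

`generate_untargeted_cohort` emulates the structure of the discovery
design: 172 cases and 115 controls by default; log2-normal feature
intensities with feature baselines from N(17, 2) on the log2 scale and
within-feature spread 0.5 (the log-normal family is the standard model for
LC-MS intensities — a modeling convention, since peak-intensity
distributions are rarely published); planted markers shifted in cases by a
uniform |log2FC| in [2, 3], two-thirds of them *down*-regulated, mirroring
the down-dominant volcano structure of this disease setting; three
internal-standard features with zero biological effect and ~5% technical
CV; 5% missing-at-random cells (an intensity-dependent censoring mode is
available but off by default); ages drawn per group (cases 71 +/- 9.47
years, controls 40 +/- 12.08) so the age-by-group confound of the real
design is reproduced *on purpose*, giving the adjustment machinery a
realistic test bed; stage (28/47/60/37 over I-IV) and tumor site for cases
only. `generate_qc_replicates` jitters pooled means log-normally at a
requested CV (mean-preserving), and `generate_panel_concentrations` draws
per-group metabolite concentrations from moment-matched log-normals (or
zero-truncated normals) at the published group means and standard
deviations, 47 + 47 samples by default.

What the generator does *not* emulate: correlated feature blocks (real
metabolite features co-vary through shared pathways and adducts),
batch/injection-order drift, heavy-tailed outliers, and the full
uncertainty of published summary statistics. Two consequences are worth
stating plainly. First, passing recovery tests on independent log-normal
features shows the selection machinery works, not that it would recover
correlated marker families at the same rate. Second, at the published
per-group means and standard deviations several metabolites barely overlap
between groups, so simulated per-metabolite and panel AUCs approach 1.0,
*above* the published AUCs (0.69-0.94, panel 0.9679) — real cohorts are
messier than their summary rows, and the generator is faithful to the
summaries, not to the messiness. Simulated performance figures are
therefore upper bounds tied to the generator's assumptions, and the
package's exact reproductions are confined to arithmetic identities
(confusion-matrix reconstructions, interval closed forms), which hold
regardless.

## Reproducibility and numerical choices

All randomness flows from one master seed through named streams
(`derive_seed(master, label)`), so partitioning, forests, folds,
permutations and bootstraps can each be replayed independently; two
pipeline runs with the same configuration are byte-identical, and the run
manifest records every parameter and the MD5 of every input and output.
Logistic IRLS converges at a 1e-10 relative tolerance within 100
iterations; OPLS deflation stops early if no orthogonal variation remains
(weight norm < 1e-12); zero-variance features are dropped with a warning
before unit-variance scaling; degenerate AUC intervals are clamped to
[0, 1]; Youden cutoffs on constant data are flagged degenerate rather than
invented. Problem sizes in the test suite (cohorts of 100-287 samples,
120-2 000 features, 10-20 simulation seeds per property) were chosen as the
smallest scales at which the tested properties are statistically decidable.

## Interfaces

The pipeline entry points are plain functions: `run_discovery` and
`run_validation` orchestrate the stages around `run_config`, and the
generator writers (`write_cohort`, `write_peak_table`) produce the same CSV
dialects the readers ingest, so a full simulate-process-select-validate
loop needs nothing outside R. `scripts/acceptance.R` is a worked example of
exactly that loop.

## Known limitations

Raw-data processing (peak picking, deconvolution, retention-time
alignment) is upstream and out of scope; annotation is offline cosine
matching against a user-supplied reference, not a live spectral-library
query; there is no survival or longitudinal modeling; and the published
headline numbers that depend on the original cohorts (consensus set of
1 007 features, validation panel AUC 0.9679, per-metabolite cutoffs) are
treated as scale context for defaults, not as reproduction targets — they
cannot be recomputed without the original measurements.
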