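---
title: "Connectome fingerprinting in developing cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome fingerprinting in developing cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neofinger)
```

## The problem

A brain connectome — a node-by-node matrix of structural (tractography-derived)
or functional (BOLD-correlation) connectivity over an anatomical parcellation —
carries an individually distinctive component often called a *fingerprint*: in
adults, a subject's scan can be re-identified among many others from the
similarity of their connectivity matrices across sessions. Whether such a
fingerprint already exists in the perinatal brain is a different question,
because the developing connectome is reorganising rapidly between a preterm
scan and a term-equivalent scan weeks later. This package implements the
test-retest fingerprinting analysis for exactly that two-timepoint design:
given each subject's connectomes at scan 1 (preterm-age) and scan 2
(term-equivalent age), it quantifies how identifiable individuals are from
structural versus functional connectivity, and how age at scan and the
interval between scans shape self- and self-to-other-similarity.

## The identification procedure

For `N` subjects with connectomes at two timepoints, the pipeline is:

1. **Density thresholding.** Each subject's *timepoint-1* matrix is reduced
   to its strongest edges at a proportional network density `d` (default
   0.25): the `ceil(d * n(n-1)/2)` largest upper-triangle weights over all
   possible node pairs are retained. For the 90-node atlas at 25% this is
   exactly 1002 of 4005 pairs. Ties at the retention boundary are broken by
   ascending (row, column) node-pair order, making the mask deterministic.
   Density is counted over *possible* pairs, not nonzero ones, so sparse
   matrices can have zero-weight edges retained (this is logged).
2. **Masking.** The thresholded matrix is binarized and used as an edge mask
   for both timepoints, so the same inter-regional connections are compared.
3. **Masked Spearman similarity.** Entry `(i, j)` of the similarity matrix
   is the Spearman rank correlation (average ranks under ties) between
   subject `i`'s masked timepoint-1 edge weights and subject `j`'s
   timepoint-2 weights over the same edges. Rows index timepoint-1 subjects,
   columns timepoint-2 subjects; the diagonal is self-similarity. Spearman
   makes the result invariant to any monotone rescaling of edge weights, so
   it is indifferent to whether structural weights arrive raw or
   log-scaled, or functional ones Fisher-transformed.
4. **Identification.** Subject `i` is successfully matched when their
   self-similarity is *strictly* higher than every self-to-other-similarity
   in their row; ties count as non-matches. The identifiability rate is the
   matched fraction.
5. **Normalisations.** For visualisation, each row can be divided by its own
   maximum (`row_max_normalize()`, so 1 marks the best match) or
   standardised to mean 0 / sd 1 (`zscore_rows()`). Both are strictly
   monotone within each row, so the identification outcome is provably
   unchanged — the test suite asserts this on every instance it generates.
6. **Threshold sweep.** `threshold_sweep()` repeats the analysis over a grid
   of densities and reports the maximal-rate plateau, since the optimal
   density is an empirical property of each dataset.

### The cross-subject mask convention

The masking step is fully specified only for the within-subject comparison.
For cross-subject entries this package uses the **row** subject's timepoint-1
mask for every column (the default): each row then compares one fixed edge
set, which keeps all entries within a row commensurable — the natural choice
given that both the match criterion and the normalisations are row-wise.
`union` and `intersection` of the row and column subjects' masks are provided
as `mask_convention` options for sensitivity analysis, and `density = NULL`
gives the fully unmasked variant.

## Functional connectivity construction

`pearson_fc()` correlates each pair of ROI timeseries; `partial_fc()`
computes the partial correlation of each pair controlling for all remaining
ROIs, read off the precision matrix `P` of the sample covariance as
`-P[i,j]/sqrt(P[i,i] P[j,j])`. In both cases negative values are set to zero
*after* the correlation computation, never inside it, and the diagonal is
zeroed. Partial correlation requires more samples than nodes; an optional
ridge on the covariance diagonal is available for near-singular cases but is
off by default since typical acquisitions (2300 volumes for 90 nodes) are
far from singular. No scrubbing or filtering is applied — denoising belongs
to the upstream preprocessing, and the package deliberately consumes
already-clean timeseries. The equivalence of the precision-matrix form with
explicit residualisation (regress out all other ROIs, correlate the
residuals) is asserted in the tests to 1e-8 on every instance up to 8 nodes.

## Statistical models

* `partial_corr(x, y, z)` — Pearson correlation of residuals after removing
  covariates by least squares, with `t`-distributed p on `n - k - 2` degrees
  of freedom. Pearson-on-residuals is the standard definition; a Spearman
  variant is available by flag. A variable explained exactly by the
  covariates gets `r = 0` by convention rather than numerical noise.
* `glm_self_similarity()` — OLS of self-similarity on PMA at scan 1 and days
  between scans. The design's condition number is reported when the two
  predictors are nearly collinear (they are correlated by construction:
  infants scanned younger tend to have longer intervals), but the fit is
  still returned.
* `lme_self_to_other()` — the `N(N-1)` off-diagonal similarities stacked in
  long form, with a REML random intercept per timepoint-1 subject
  (repeated-measures rows) and the scan interval as fixed effect. For
  cross-subject pairs the interval is defined as
  `(column subject's PMA at scan 2 − row subject's PMA at scan 1) × 7` days —
  the only interval that exists between two different subjects' scans.
  PMA at scan 1 is included as a second fixed effect by default
  (`form = "days_plus_pma"`), because the age-at-first-scan effect on
  self-to-other-similarity is a question of direct interest in this design;
  `form = "days_only"` gives the minimal model. P-values use Satterthwaite
  degrees of freedom (lmerTest).
* `bonferroni()` — `min(1, p·m)` with a default family of `m = 7`, one test
  per anatomical cluster, applied separately per modality and per predictor.
* `motion_analysis()` — correlation of mean framewise displacement (averaged
  over the two scans, with per-scan correlations also reported) with
  self-similarity, plus the subgroup with FD below threshold (default
  0.3 mm) at *both* timepoints.

## Regional analysis

`regional_pipeline()` reruns the entire procedure inside each of seven
anatomical clusters of the 90-node AAL parcellation (central 8, frontal 22,
limbic 14, occipital 14, parietal 10, deep grey matter 8, temporal 14 nodes;
`study_clusters()` carries the node map, and `read_clusters()` accepts
arbitrary JSON definitions for other atlases). "Regional" edges are the
cluster's *internal* node pairs: repeating the analysis on a cluster most
directly means analysing its own connectome, and the density is recomputed
on the cluster's own pair count so 25% means the same thing at every scale.
The cluster-to-whole-brain alternative (`edge_scope = "to_all"`) is kept for
sensitivity analysis since either reading is defensible. Compositionality —
regional results equal the global pipeline run on pre-extracted
submatrices — is asserted in the tests.

## The synthetic cohort generator

Real two-timepoint neonatal connectome cohorts cannot be shipped with a
package, so `simulate_cohort()` generates one with controllable structure.
All draws happen in a fixed order under one seed, so a cohort is exactly
reproducible.

**Structural arm.** A shared group backbone holds an edge with probability
`backbone_density` (default 0.6) with Normal(0,1) baseline log-weights.
Subject `i`'s scan at post-menstrual age `p` has log edge weights

```
log W = baseline + gamma * (p - 40) * D + alpha_sc * F_i + sigma_sc * eps
```

with `D` a shared developmental gradient, `F_i` the subject's persistent
fingerprint field, and `eps` per-scan noise (all i.i.d. standard normal per
backbone edge). The log-additive form keeps weights positive without
clipping, and since the downstream similarity is rank-based only the edge
ordering matters. Non-backbone edges are structurally absent (zero) at every
scan.

**Functional arm.** The correlation structure at age `p` comes from a factor
model, `L_i(p) = L_group + alpha_fc * L_i + gamma * (p - 40) * L_dev` with
`n_latent = 10` factors; the covariance `L Lᵀ + psi I` (with `psi = 0.5 > 0`,
guaranteeing positive-definiteness for any parameter values) is converted to
a correlation matrix, and the BOLD-like timeseries are 2300 independent
multivariate-normal samples from it. Functional connectomes are then built
from these timeseries with the same `pearson_fc()`/`partial_fc()` code path
as real data.

**Panel.** PMA at scan 1 is uniform on 29.3–37.4 weeks and at scan 2 on
38.4–45 weeks (a preterm first scan and a term-equivalent second scan);
gestational age at birth is PMA1 minus Uniform(0.5, 4) weeks; sex alternates
and carries no effect, existing only to exercise the metadata path.

### Default calibration

The defaults are chosen to place the two arms in the qualitative regime
characteristic of perinatal cohorts — a stable, strongly identifiable
structural connectome over a shared developmental backbone, and a weakly
identifiable functional connectome whose cross-subject similarity falls with
the interval between the scans being compared:

* `alpha_sc = 0.5`, `sigma_sc = 0.1`: the structural fingerprint is large
  against per-scan noise, giving near-ceiling structural identifiability and
  per-subject structural self-similarity consistently above functional
  self-similarity.
* `alpha_fc = 0.08`, `gamma = 0.05`: the functional fingerprint is small
  against the age-driven reshaping of the correlation structure, so
  functional identifiability stays near chance and self-to-other-similarity
  declines with the scan interval.

These were fixed once, verified across independent seeds at the paired
sample size, and are exercised (not re-fit) by the test suite.

### What the generator does and does not emulate

It emulates the statistical skeleton the analysis depends on: paired scans
with realistic age structure, a common backbone plus individual fingerprint
plus drift plus noise in log-weight space, and timeseries with
subject/timepoint-specific correlation structure long enough for partial
correlation to be well-posed. It does **not** model haemodynamics, motion
artefacts, spatial node geometry, tractography biases, or any sex or
birth-age effect. Passing tests on synthetic cohorts therefore validate the
*pipeline's* correctness and calibration (chance-level identification when
no fingerprint exists; perfect identification when noise vanishes;
monotonicity in fingerprint strength), not claims about any particular real
dataset.

## Numerical choices and degenerate inputs

* Asymmetries up to 1e-10 are symmetrised by averaging; anything larger is
  an error, since real connectomes are symmetric by construction.
* Nonzero diagonals are zeroed (silently for functional matrices, which
  conventionally carry 1.0 there; with a warning for structural ones).
* Mask tie-breaks are lexicographic, identification ties are non-matches,
  Spearman ties get average ranks — all deterministic.
* Row z-scores use the sample (N−1) standard deviation and pool each row's
  self and self-to-other entries; global pooling is available by flag, as
  the pooling set is a genuine free choice.
* Validation sizes: the oracle equivalences run exhaustively at small sizes
  (rank formula to length 12, residualisation to 8 nodes); null calibration
  uses 200 cohorts of N = 10; monotonicity averages 50 seeds at N = 20; the
  regime check runs the paired-modality size N = 26 with full-size
  (90-node, 2300-sample) data. These sizes give stable Monte-Carlo averages
  for each property while keeping the suite quick to run.

## Known limitations

* The package consumes parcellated matrices and ROI timeseries as
  plain-text; image-space processing (segmentation, tractography, denoising,
  FD computation) is upstream and out of scope.
* Identifiability with strict-tie handling is conservative on data with
  exactly tied similarities (essentially only degenerate synthetic cases).
* The LME treats rows (timepoint-1 subjects) as the only grouping factor;
  column subjects also repeat across rows, and a crossed random effect would
  be a natural extension.
* No nonlinear age models: both age models are linear by design, and real
  developmental effects need not be.
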