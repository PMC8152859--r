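---
title: "Methods: representational similarity analysis of body-part coding"
author: "bodyrsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational similarity analysis of body-part coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodyrsa)
```

## The question and the statistical machinery

Multivoxel activation patterns in lateral occipitotemporal cortex evoked by
viewed body parts are hypothesized to be organized by function rather than by
visual form: action effectors (hand, foot, arm, leg) cluster together,
noneffector trunk parts (chest, waist) form a second cluster, and face parts
(upper/lower face) a third. `bodyrsa` implements the full chain of analyses
used to test this three-category model and to compare its expression across
two age groups, together with a generative simulation that makes every stage
testable without access to scanner data.

This vignette documents the model and procedure choices, their parameters and
defaults, what the synthetic cohort does and does not emulate, and the
numerical decisions a reader would otherwise have to reverse-engineer from
the code.

## Block design

A run presents 10 conditions (whole body, chair, and the 8 body parts) in
20 blocks of 12 s (2 blocks per condition), with fixation baselines of 27 s
before the first block, 12 s after blocks 5, 10 and 15, and 15 s at the end:
318 s per run, 106 volumes at TR = 3 s, 4 runs per participant. Each block
holds 12 pictures (500 ms on, 500 ms inter-stimulus interval); the full set
is 44 pictures per condition, 440 in total. `design_spec()` encodes these
constants and validates their mutual consistency (the run length must divide
by the TR; the picture train must exactly fill a block). `design_summary()`
reports the derived quantities: 404 analyzed volumes across 4 runs after
discarding 5 dummy volumes per run.

Block order is an independent uniform permutation per run, subject to each
condition appearing exactly twice. The source design is described only as
pseudo-randomized; we deliberately impose no further constraint (such as
forbidding immediate repeats) because any such rule would be a guess, and a
uniform permutation is the simplest seed-reproducible choice. Stimulus-level
timing is carried in the design metadata but the forward model and the GLM
operate on block-level boxcars — the first-level model of record models
blocks, not pictures.

## Synthetic cohort: what is planted and what is not

`generate_patterns()` plants the category geometry directly in the
condition-by-voxel amplitude matrix. For body-part condition $c$ in category
$g$:

$$ \beta_c = \sqrt{\kappa}\, p_g + \sqrt{1-\kappa}\, u_c, $$

with prototype $p_g$ and condition-unique $u_c$ i.i.d. standard normal over
voxels. The mixing weight $\kappa \in [0,1]$ (cohesion) is the single dial of
the planted geometry: the expected correlation between two same-category
patterns equals $\kappa$, distinct categories are uncorrelated in
expectation, and $\kappa = 1$ makes same-category patterns identical. The
whole-body and chair conditions get independent patterns whose mean
amplitudes differ by `contrast_gain`, so the univariate localizer contrast
has a planted effect.

`simulate_bold()` inverts the GLM forward: boxcars convolved with the
canonical HRF, scaled by the planted amplitudes, plus a one-cycle cosine
drift with voxel-random phase, stationary AR(1) Gaussian noise
(`noise_sd` is the innovation SD), and a constant baseline of 100 so that
global scaling is well defined.

`cohort_config()` fixes the study conditions: 26 adults and 22
children/adolescents. Where the source experiment gives no number we chose
values a practitioner would call realistic and left them alone: adult
cohesion $\kappa \sim N(0.7, 0.10)$, child/adolescent
$\kappa \sim N(0.6, 0.15)$ (both truncated to $[0,1]$; the child group is
noisier and slightly less coherent, matching its weaker decoding and higher
motion); AR(1) innovation SD 1.0 vs 1.5; drift amplitude 1; motion
random-walk steps calibrated so mean framewise displacement lands near the
reported group means of 0.10 mm (adults: 0.025 mm, 0.00035 rad per volume)
and 0.19 mm (children: 0.047 mm, 0.00066 rad). A unit-mean lognormal
participant scale factor (log-SD 0.6) spreads motion across participants so
the FD ratio of SD to mean is near the reported ~0.7 rather than degenerate.
Trait scores are linear in $\kappa$ plus Gaussian noise
(`trait_slope * kappa + N(0, trait_noise_sd)`), the minimal model under
which rank-correlation recovery is a testable property.

The generator emulates the *statistical* structure the analyses consume —
pattern geometry, autocorrelated noise, drift, motion, trait coupling. It
does not emulate spatial structure (no 3-D voxel topology, no smoothness, no
draining veins), physiological noise, inter-regional covariance, or
realistic trait distributions. Passing tests therefore demonstrate that the
*pipeline* is correct and calibrated, not that real LOTC data behave this
way.

## First-level GLM

The canonical HRF is the conventional double-gamma form: gamma response with
shape 6 and scale 1 s minus a 1/6-amplitude undershoot with shape 16, on a
32-s support, peak-normalized. The source analysis says only "canonical";
this parameterization is the de facto standard. Boxcars are convolved at 16
bins per TR and sampled at volume onsets.

The design matrix holds 10 condition regressors, the 6 mean-centered motion
parameters (all-zero columns dropped), a discrete-cosine high-pass basis
with $K = \lfloor 2T/128\rfloor$ components (periods above 128 s; $K = 4$
for the 303-s analyzed run) and an intercept. Rank deficiency is an error
that names the offending columns. The first 5 volumes of each run are
discarded *before* design construction, with onsets shifted by 15 s; because
the HRF is causal, the retained-volume regressor values are unaffected by
the discarded samples, and noiseless simulation is inverted exactly (tested
to $10^{-8}$).

Whitening follows the pooled-AR(1) convention: OLS residuals from a first
pass give a single lag-1 autocorrelation pooled over all voxels (the source
pools "active" voxels; in synthetic data all voxels carry signal, so all are
pooled), and data and design are pre-whitened with it before the final fit.
Global scaling multiplies each run to grand mean 100 — the constant is not
stated in the source; 100 is the standard convention. Note one honest
caveat, visible in our own tests: the residual-autocorrelation estimate is
attenuated when the high-pass basis absorbs low-frequency noise power; the
estimator is validated against planted AR coefficients on designs without
the high-pass basis.

Activation detection thresholds the contrast t-map at the one-sided
uncorrected $P < 0.01$ quantile for the pooled degrees of freedom; a
participant counts as activated if any ROI voxel survives, and activation
size is the suprathreshold voxel count times the voxel volume (8 mm³ on the
2-mm grid). The full cluster machinery of the original software is
deliberately not reproduced. The 8-mm sphere ROI on a 2-mm grid contains 257
voxels (2056 mm³), verified against brute-force lattice enumeration.

## Split-half RDMs and representational correlations

Condition patterns are averaged over odd runs (1, 3) and even runs (2, 4) —
acquisition order, the simplest stable convention, as the source does not
define the split — and the RDM entry is $1 - r$ between condition $i$'s
odd-half pattern and condition $j$'s even-half pattern. The directional
matrix is symmetrized as $(D + D^\top)/2$; its diagonal is one minus the
split-half reliability and is *not* forced to zero, but all vectorized
statistics (ANOSIM, Mantel, RDM correlations) operate on the 28 off-diagonal
unordered pairs only.

Within/between-group correlations are Pearson correlations between a
participant's 28-vector and the leave-one-out mean RDM of their own group
versus the mean RDM of the other group. Pearson (not Spearman) is used
because the Mantel statistic in the same analysis family is a Pearson
correlation; the source says only "correlation coefficients".

MDS is metric least-squares scaling by SMACOF stress majorization (reported
as Kruskal stress-1), with the classical-scaling solution as first start
plus seeded random restarts; nonmetric Kruskal scaling is available as an
option. Metric scaling is the default because the original visualization
toolbox's default criterion is metric stress.

## ANOSIM, the 420-partition null, and the Mantel test

The ANOSIM statistic ranks the 28 dissimilarities ascending with average
ranks for ties and contrasts between- versus within-category mean ranks,
scaled by $M/2 = 14$ so that $R \in [-1, 1]$. The permutation null is the
*complete* enumeration of all $\binom{8}{4}\binom{4}{2} = 420$ labeled
assignments of the 8 conditions to class sizes (4, 2, 2), in lexicographic
order, with the hypothesized model appearing exactly once.

P counts alternatives whose R *strictly* exceeds the hypothesized R, plus
one: $P = (1 + \#\{R_{alt} > R_{hyp}\})/420$. This choice is forced by the
printed results themselves: swapping the two size-2 class labels duplicates
every R value exactly, so counting ties would make the minimum attainable P
equal to 2/420 ≈ 0.005, while the analysis being reproduced reports a
minimum of 0.002 = 1/420. Under strict counting all attainable P values are
multiples of 1/420 (0.002, 0.005, 0.012, ...). The same convention is used
for the decoding permutation test. Two exact properties are tested: the
mean of the 420 R values is zero (to $10^{-12}$; every pair is within-class
equally often across the enumeration), and the statistic is invariant under
strictly monotone transforms of the dissimilarities.

The Mantel statistic is the Pearson correlation between the two 28-vectors;
the null permutes condition labels of one matrix. The default is 9,999
random permutations (the source does not state a count); complete
enumeration of all $8! = 40{,}320$ relabelings is available and exact.

## Decoding

One sample per condition per run — the run-level beta pattern — gives 8
samples per run, labeled with the partition's three classes. For each
leave-one-run-out fold, features are standardized with training-fold
statistics (zero-variance features dropped with a warning), and the
unbalanced training classes (4:2:2 conditions) are reduced to 100 balanced
bootstrap subsamples, each drawn without replacement down to the smallest
class count. A linear soft-margin SVM (cost 1, one-vs-one multiclass — the
LIBSVM defaults matching the original toolbox's linear SVM) is trained per
subsample and scored on the held-out run; accuracy averages over bootstraps,
then folds, reported against the 1/3 chance level. Standardization per
training fold is our choice (the source is silent); it prevents leakage and
makes accuracy invariant to global feature rescaling.

One property worth stating because it shapes what the decoder can show: the
test samples are the *same conditions* in a held-out run, so stable
condition-unique patterns support above-chance classification even with no
category structure ($\kappa = 0$) when noise is low. The cohesion benefit is
therefore tested in a high-noise, few-voxel regime where category pooling in
the training set has to carry the decoder. Null calibration (accuracy minus
chance centered on zero) is tested with patterns drawn independently per
run, which removes all cross-run structure.

## Group and trait statistics

The 2×2 chi-square is the uncorrected Pearson statistic with Cramér's
$V = \sqrt{\chi^2/N}$; no Yates correction by default because the
uncorrected form reproduces the printed worked examples (6.596, 1.207)
exactly, with the correction available by flag. Welch versus Student
t-tests are selected explicitly by the caller rather than by an automatic
variance-test gate (the reported fractional dfs show Welch was used for
unequal-variance comparisons, but no gating rule is stated); both accept
summary statistics (mean, SD, n), and Cohen's d always uses the pooled SD,
the conventional reporting choice even alongside Welch t.

The mixed-design ANOVA uses classical sums of squares on a balanced long
table: the between-group effect is tested against subject-within-group
error, the within effect and interaction against the subject-by-within
error, with partial $\eta^2$ computed within each effect's own error
stratum. The covariate (mean FD) enters grand-mean centered in the
between-subject stratum only. The implementation rides on `stats::aov`
error strata and is verified against an independent brute-force
sums-of-squares decomposition. One documented discrepancy in the source —
within-effect denominator dfs reported as 46 where the conventional mixed
design gives 7 × 46 — is resolved in favor of conventional dfs.

Trait screening is Spearman rank correlation per score with a Bonferroni
threshold of 0.05/m (0.005 for the ten-score battery); partial correlation
controls mean FD by correlating the residuals of both variables after
regression on the covariate, on $n-3$ dfs. Framewise displacement is
$\sum|\Delta \text{translations}| + 50\,\text{mm} \times \sum|\Delta
\text{rotations}|$ with FD = 0 at the first volume — the standard 50-mm
sphere convention, which the source cites without parameters.

## Pipeline, seeds and problem sizes

`run_pipeline()` executes all stages on a generated cohort and returns (or
writes as CSV/JSON) the per-group mean RDMs, MDS embeddings, ANOSIM results
per group and participant, the Mantel test between group RDMs, the
within/between correlation ANOVA and FD-adjusted ANCOVA, activation-ratio
chi-square, decoding statistics, and the trait report. Every stochastic
stage draws from a stream derived deterministically from the master seed by
a hash, so stages are reproducible independently of evaluation order and
reruns are bit-identical — which the test suite asserts on serialized
output files.

The test suite runs the cohort-level checks on reduced problem sizes chosen
to keep the suite quick while leaving the tested properties intact
(cohorts of 4–8 participants, 40–120 voxels, 10–20 bootstraps where the
property does not depend on the bootstrap count); the calibration checks use
their natural sizes (500 RDM nulls for P-uniformity, 100 decoder nulls,
1000 detector nulls, 20 recovery seeds). The paper-scale cohort (26 + 22
participants, 100 bootstraps) is the default configuration of
`cohort_config()` / `pipeline_config()`.

## Known limitations

- The abstract voxel grid has no spatial structure, so nothing here can
  probe smoothing, searchlights, or anatomical localization; NIfTI readers
  are provided for real beta arrays and masks, but spatial preprocessing is
  out of scope.
- The pooled AR(1) estimate is attenuated on high-pass-filtered designs
  (see above); this mirrors the behavior of the convention it implements.
- Group-level voxelwise inference (nonparametric cluster statistics) is not
  implemented; the pipeline's group statistics operate on ROI summaries.
- The decoder's permutation test re-runs the full cross-validation 420
  times and is correspondingly expensive at paper scale; it is exposed as
  its own function rather than run by default in the pipeline.
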