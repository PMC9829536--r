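---
title: "Methods: receptor-network mapping, permutation inference and population modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor-network mapping, permutation inference and population modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnmap)
```

## The model

srnmap treats a brain-wide expression map of a receptor gene as a spatial
template: a vector over the regions of a parcellation, normalized across
regions. Given K such templates stacked into a regions-by-K matrix A and a
parcellated fMRI run Y (time by regions), the package assumes the linear
mixing model

    Y(t, ) = a(t) + TC(t, ) %*% t(A) + noise,

where TC is a time-by-K matrix of latent network amplitudes. Dual regression
estimates this structure in two ordinary-least-squares stages:

1. **Stage 1 (spatial).** At each time point, the regional signal vector is
   regressed on all K demeaned template columns jointly (with an intercept).
   The coefficient traces are the network amplitude time-courses.
2. **Stage 2 (temporal).** Each region's time-series is regressed on all K
   standardized stage-1 time-courses jointly. The coefficients form the
   subject's functional connectivity map (regions by K).

Standardizing the stage-1 time-courses between stages makes stage-2
coefficients comparable across networks and subjects: they are in signal
units per standard deviation of network amplitude. Under the mixing model
with vanishing noise, stage 1 recovers TC and stage 2 recovers maps
proportional to the template columns; both facts are asserted in the test
suite with an independent normal-equations oracle.

**Residualized stage 1** stacks confound templates (receptor maps of other
neurotransmitter families) into the spatial design and returns only the
interest coefficients. By the Frisch–Waugh theorem this equals regressing
confound-residualized signal on confound-residualized interest templates, so
the resulting amplitudes reflect spatial variance unique to the templates of
interest. A template occurring in both sets (by name or numerically) is an
error, not a silent drop.

### Assumptions

- Region order is carried by labels; templates and runs are aligned by
  region id, never by position.
- The demeaned spatial design must be well-conditioned. Condition numbers
  above 1e8 raise an error naming the most collinear template pair; the
  package never falls back to a pseudoinverse, because silent rank handling
  would change coefficients irreproducibly.
- Both stages include an intercept and demean design columns. This is the
  conventional dual-regression setup; the alternative (no intercept) is not
  exposed.
- Stage-1 time-courses are standardized per run, not per concatenated
  session.

## Atlas construction

The expression-atlas builder reproduces a standard microarray-to-region
pipeline: probes without a gene assignment are dropped; probes passing the
intensity filter in fewer than `min_pass_fraction` (default 0.5) of samples
are dropped; surviving probes of a gene are averaged **in linear space**
(`log2(mean(2^x))`), as are samples sharing a region label within a donor;
per-donor log2 regional values are then averaged arithmetically across the
designated donors. Samples are assigned to regions by minimal Euclidean
distance to the region centroid, ties broken to the earliest atlas row.
Genes sampled on a single hemisphere can be mirrored by copying values to
the contralateral homolog before normalization (mirroring is idempotent and
leaves midline regions untouched); the package mirrors first and normalizes
second. Regions sampled by no donor are dropped with a warning rather than
imputed.

Two normalizations are provided, both monotone: a z-score across regions
(sample standard deviation), and a rank-based inverse-normal transform using
the Blom offset, `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for
ties. Blom's constant is the common default in genetics and imaging; the
choice only shifts extreme quantiles slightly and does not affect rank-based
downstream statistics.

## Permutation inference

Group and condition effects on amplitudes (time by networks) and
connectivity maps (regions by networks) are tested with a permutation GLM.
For each permutation of the observation rows (the identity always first),
the contrast t-statistic is recomputed for every element; the maximum over
all elements, networks and both signed tails forms the null distribution,
and each element's family-wise-error-corrected p-value is the fraction of
permutation maxima reaching its observed value. Counting the identity
guarantees p >= 1/n_perm and makes the test exact under exchangeability.
Two-tailed inference is a single max over the +t and -t enhancements, not a
Bonferroni doubling.

**TFCE.** For time-resolved inference the t-series of each network is
enhanced with one-dimensional threshold-free cluster enhancement:
`enhanced(t) = sum_h extent(t, h)^E * h^H * dh` over thresholds up to the
local statistic, where the extent is the length of the contiguous
suprathreshold run containing t. Defaults are E = 0.5, H = 2 with an
adaptive step `dh = max|stat|/100`, the reference implementation's
enhancement exponents, exposed as parameters because only the tool, not its
settings, is conventionally reported. For a rectangular bump of height h0
and width w the sum converges to `w^E * h0^(H+1)/(H+1)`; the implementation
(in C++, as this is the hot loop of the permutation engine) matches that
closed form within 0.5% at dh = h0/1000 and satisfies the lambda^(H+1)
scaling law to machine precision. Connectivity-map inference applies no
enhancement: the correction family is regions x networks x tails.

**Permutation schemes.** Two-group comparisons across independent runs
shuffle whole observations; when the number of distinct group reassignments
(`choose(n, n1)`) does not exceed `n_perm`, the stream enumerates all of
them exactly (for the 8-vs-4 run geometry: 495), otherwise Monte-Carlo draws
are used. A subtlety worth recording: data rows are permuted against a fixed
design, so the enumeration must range over *which rows land in a group's
design positions* — enumerating row placements naively produces duplicate
assignments and a degenerate null. Paired (drug on/off) designs restrict
permutation to within-subject blocks; blocks of size 1 are rejected because
they carry no exchangeability. The within-block stream is enumerated when
`prod(size!)` is small and never maps an observation outside its block,
which the test suite asserts structurally over the full stream.

**Specificity analysis.** The Spearman partial correlation relates each
receptor's regional map to a regional effect map, adjusting for the rank
pattern of other-family receptor maps: all variables are rank-transformed,
target and effect ranks residualized on covariate ranks, and the residuals
Pearson-correlated. Significance is by permuting region labels of the
effect map with FWE across receptors via the max-|rho| null (default alpha
0.025, a two-tails split of 0.05). Same-family receptors are deliberately
not used as covariates: their strong co-expression would absorb the effect
of interest; the covariate set is the caller's choice.

## Population modes (permutation CCA)

Subject-level connectivity features (optionally PCA-reduced to 20
components) and behavioral variables are related by canonical correlation
analysis after both sides are residualized on confounds. Mode k is tested
stepwise with the Wilks-type statistic `-sum(log(1 - r_i^2))` over the
remaining correlations i >= k; p-values count the permutations (identity
included) whose statistic reaches the observed one, and FWE across modes
uses the permutation distribution of the maximum statistic over modes with
a cumulative-maximum monotonicity step.

The deflation deserves a note, because a naive scheme is anti-conservative.
At step k the package removes the first k-1 canonical directions from each
side's orthonormal span basis and keeps the **full remaining
dimensionality** of both spans (via basis completion from the full SVD), so
that the observed statistic and every permuted statistic optimize over
spaces of identical size. Projecting the behavior side onto only the
K = min(p, q) original canonical directions instead — so the observed
statistic enjoys the full q-dimensional optimization while the null does
not — inflates significance grossly; the package's null calibration test
(independent 200-subject sides, any-mode rejection rate at alpha 0.05)
guards against this failure mode.

Permutations respect family structure: whole families swap only with
families of the same size, and subjects shuffle within family. The identity
is always the first permutation and the stream is asserted never to map a
subject outside its size class.

Cross-loadings are the correlations of each residualized variable with the
*opposite* side's canonical variate (the standard cross-loading; the
same-side loading is available by passing the same-side variate).
Cross-loading matrices are decomposed with a single-component PCA on the
raw, uncentered matrix — uncentered so that a rank-1 matrix decomposes
exactly into its factors — with the sign fixed so the largest-magnitude
network coefficient is positive. Median splits of the subject scores assign
ties to the low group, and the Bonferroni factor is modes times variables
in the domain tested.

### Estimation bias at desk scale

The first sample canonical correlation is biased upward by overfitting,
roughly in proportion to (p + q)/(2n). With 20 imaging and 45 behavioral
variables this bias is material at n = 500 (the package's planted-mode
recovery simulations estimate a true 0.5 around 0.59) and shrinks toward
the truth as n grows; the simulation suite checks the convergence at
n in {100, 500, 2000}. The package reports the raw estimate, as the field
does; interpret it with the dimensionality in mind. The Wilks-type
statistic likewise sums over all modes, so the power to detect a single
planted mode is diluted when K is large.

## The synthetic-data generator

The generator exists so every statistical claim in the package can be
checked against a known truth; it is first-class, tested code.

- `stimulus_design()` defaults to the optogenetic protocol the analysis is
  built around: 6 cycles of 20 s stimulation and 40 s rest at a 2 s
  sampling interval, preceded by 40 baseline volumes — 220 volumes, 60 of
  them stimulation-on.
- `synthetic_atlas()` draws 90 regions x 9 receptor-gene templates from an
  equicorrelated Gaussian (inter-template correlation 0.3, mimicking
  receptor co-expression) and z-scores columns.
- `simulate_ofmri_run()` implements exactly the mixing model above: boxcar
  (optionally single-gamma-convolved, shape 6 scale 1 in TR units; off by
  default since nothing hemodynamic is modeled explicitly) latent
  time-courses, per-network amplitudes, i.i.d. Gaussian noise with optional
  AR(1) temporal autocorrelation to stress the permutation tests (off by
  default).
- `simulate_ofmri_study()` defaults to 8 runs versus 4, the effective
  group geometry of the stimulation experiment.
- `simulate_population()` plants a single canonical mode of exactly rho:
  the latent pair occupies one coordinate of each side's feature space
  before a random orthonormal rotation, so the population canonical
  correlation equals rho by construction (additive noise on a loading
  direction would dilute it). Defaults are 20 imaging and 45 behavioral
  variables, families of two with a singleton remainder.

What the generator does **not** emulate: hemodynamic nonlinearity,
physiological noise structure, motion artifacts, spatial autocorrelation of
noise across regions, non-Gaussian behavioral distributions, missing data,
and realistic receptor-density spatial patterns. Passing tests therefore
demonstrate correctness of the estimators and exactness/calibration of the
inference under the stated model, not robustness to every property of real
data.

## Numerical choices

- Linear-space averaging is `log2(mean(2^x))` in double precision.
- All OLS fits go through QR (`lm.fit`); oracles in the tests use explicit
  normal equations so the two routes are independent.
- An exact fit with a negligible contrast (relative to the data scale) is
  reported as t = 0, not infinity, so constant data yields p = 1.
- Canonical correlations are clipped to [0, 1]; `log1p(-r^2)` is guarded at
  1 - 1e-12.
- Nearest-centroid ties break to the earliest atlas row; median-split ties
  go to the low group; the loading-PCA sign makes the largest-|coefficient|
  entry positive. All three are arbitrary but deterministic and documented.
- Every stochastic function takes a seed and restores the caller's RNG
  state, so pipelines are bit-reproducible given (parameters, seed).

## Problem sizes used by the checks

The package's deep checks run at the study geometry where that geometry is
what is being claimed: FWE calibration uses 200 null simulations of the
9-network, 220-volume, 8-vs-4 design with 1,000 requested permutations
(enumerated to the 495 distinct reassignments); CCA null calibration uses
40 seeds of 200 subjects with 500 permutations; planted-mode recovery uses
25 seeds of 500 subjects. Quick property tests (super-uniformity,
permutation-stream structure, oracle equivalences) use smaller instances
since their claims are scale-free.

## Known limitations

- Inference assumes exchangeable runs (or blocks); temporal autocorrelation
  within a run affects only the time-resolved statistics' interpretation,
  not their validity, since permutation is across runs.
- The stepwise CCA tests beyond mode 1 are conditional on earlier estimated
  directions and are approximate, as in the method family this follows.
- Voxel-wise computation, volumetric I/O and image preprocessing are out of
  scope; all computation is region-wise on parcellated inputs.
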