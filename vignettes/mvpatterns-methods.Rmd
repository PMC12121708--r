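---
title: "Methods: pattern similarity, discriminability and variance partitioning in mvpatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pattern similarity, discriminability and variance partitioning in mvpatterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpatterns)
```

## The analysis problem

Condition-rich block-design fMRI experiments — for instance a design in
which participants judge trait adjectives about themselves or another
person, introspect on their current state, categorize words, retrieve
autobiographical memories, or verify general knowledge — produce one
activation pattern per condition per scanner run: a vector with one entry
per voxel under a brain or region mask. The scientific questions this
package addresses are about the *geometry* of those patterns:

* Are two conditions' patterns similar (representational similarity
  analysis, RSA)?
* Are they nonetheless discriminable (classifier-based multivoxel pattern
  analysis, MVPA)?
* How much of one condition's pattern is explained — uniquely or jointly —
  by the patterns of other conditions (cross-run multivariate pattern
  regression with commonality analysis)?
* Where in the volume do these effects live (searchlight mapping with
  group-level permutation inference)?

The pipeline ingests per-run condition patterns directly (e.g., first-level
t-maps of each condition against the implicit baseline). First-level GLM
estimation is out of scope; input patterns are treated as opaque vectors,
which keeps every downstream statistic invariant to whether the user
supplies beta maps or t-maps.

## Data model and conventions

A `pattern_dataset` holds a `volume_grid` (dimensions, voxel size in mm,
origin), a logical mask, and a V × runs × conditions array of in-mask
pattern values. One convention is used everywhere: **voxels are ordered by
ascending flat (column-major, x-fastest) index**. RSM construction, ROI
extraction, searchlight spheres and the regression stack all rely on that
single ordering, so matrices built independently always align.

Contrasts are per-run differences between a condition's pattern and a
control condition's pattern (`"rest"` denotes the zero baseline). Because
both conditions come from the same run, any run-shared nuisance component
cancels exactly in the difference. No pooled-error t statistic is formed at
this stage — the analyses need the pattern geometry, not within-run
inferential scaling.

## RSA with cell exclusion and Kendall's tau-a

The neural RSM contains Pearson correlations between every pair of
(condition, run) items. Binary model RSMs encode a similarity hypothesis —
for example *self = other* — as 1 on cross-run (self, partner) cells and 0
elsewhere. Three exclusion rules define which cells enter the model fit:

1. the diagonal;
2. **all same-run pairs** — within-run correlations are inflated by shared
   physiological noise, regardless of condition;
3. **all same-condition pairs** — cross-run reliability of a single
   condition is not evidence about between-condition similarity.

Each hypothesis additionally drops the conditions irrelevant to it (the
*self = introspection* model, for instance, keeps only self, semantic,
introspection and categorization), so similarities involving irrelevant
conditions cannot influence the fit. With five runs this leaves 60 valid
cells (20 of them "similar") for the three-condition model and 120 (20
similar) for the four-condition models.

Fit is Kendall's tau-a: over all unordered pairs of valid cells,
(concordant − discordant) / (n(n−1)/2). The all-pairs denominator is the
correct choice against tied (binary) model values: tied pairs contribute
zero to the numerator but full weight to the denominator, so tau-a is a
conservative, comparable-across-models statistic. It is computed by direct
O(n²) pair enumeration — valid-cell counts are a few hundred at most, and
the enumeration *is* the definition, leaving no room for a tie-correction
mismatch.

A single-run design leaves zero valid cells (everything is same-run); the
fit raises an informative error rather than returning a vacuous value.

## Classifier-based MVPA

Pattern discriminability uses a linear support vector machine with cost
c = 1 (the LIBSVM default, via `e1071`) under leave-one-run-out
cross-validation: train on the patterns of all runs but one (one pattern
per class per run, labels ±1), test on the held-out run's two patterns,
average the per-fold accuracies. Chance is 50%. No feature scaling is
applied beyond optional sphere-mean removal — rescaling would change the
margins relative to the procedure being modelled.

Sphere-mean removal subtracts each pattern's own spatial mean so that a
uniform activation difference cannot drive classification. Whether to apply
it outside searchlights is exposed as an explicit `center` flag: the
package defaults to `TRUE` inside searchlight spheres and `FALSE` for
ROI-level classification, and either choice is one argument away.

Degenerate folds (identical training vectors in both classes) have no
separating direction; the fold deterministically predicts class a (the
lower label index), scores 0.5, and is flagged in the result, keeping every
fold bit-reproducible.

A median-split helper relabels blocks into "short"/"long" classes by a
per-block score (e.g., response time); ties at the median go to "short", a
fixed documented rule.

## Searchlight mapping

Spheres have a 3-voxel radius by default (123 voxels in the interior, fewer
at mask edges; a configurable minimum size defaults to 1). Membership is
decided on squared integer distances (d² ≤ r²), so there is no
floating-point boundary ambiguity. The driver evaluates an arbitrary pure
per-sphere statistic (tau-a against a model RSM, cross-validated accuracy,
or any user function) at every in-mask center and writes the scalar to the
center voxel; a failing statistic yields NaN at that center with a summary
warning instead of aborting the map.

## Group-level inference

Subject statistic maps are smoothed (4 mm FWHM by default, configurable),
centred at the null value (0 for tau maps, 0.5 for accuracy maps), and
tested with a one-sample t statistic per voxel. The cluster-forming
threshold is the parametric t quantile at the voxel-level p (df = n − 1),
with a dual threshold supported: a looser p inside a preregistered ROI
(default 0.005) and a stricter one outside (default 0.001). Cluster-extent
familywise error is controlled by the permutation distribution of the
maximum cluster size under per-subject sign flips, with
p = (1 + #{max ≥ observed}) / (1 + n_perm). When 2^n_subjects does not
exceed the requested permutation count the full set of sign assignments is
enumerated exactly. Plain t (not variance-smoothed pseudo-t) is a
deliberate simplification of nonparametric-mapping practice; it keeps the
cluster-forming rule transparent and testable. Connectivity is
face-adjacency (6-neighbour) by default, configurable to 18 or 26.

Conjunction questions use `overlap_map()`: a voxelwise AND across
thresholded maps with small components removed.

## Cross-run pattern regression, noise ceiling, commonality analysis

The regression stack asks how much of the self > semantic contrast pattern
is explained by the other > semantic (O), introspection > categorization
(I) and memory > knowledge (M) patterns. Ordinary least squares with
intercept is fitted across ROI voxels for every **ordered pair of distinct
runs** — dependent pattern from run a, predictors from run b — so
dependent and independent variables never share a run and run-shared noise
cannot inflate the fit. Five runs give 20 fits; betas, R² and adjusted R²
(n = voxels, p = predictors) are averaged across pairs.

The noise ceiling appends the dependent contrast's own pattern *from the
predictor run* as an extra predictor: it estimates how much variance any
model could explain given run-to-run measurement noise. The explainable
variance percentage is the subject-wise ratio of full-model to ceiling
adjusted R², averaged over subjects with a positive ceiling (nonpositive
ceilings make the ratio undefined; such subjects are excluded with a
warning).

Commonality analysis fits the seven sub-models (O, I, M, OI, OM, IM, OIM)
over the same pair set, averages each sub-model's **raw** R² across pairs,
and applies the inclusion–exclusion formulas to produce three unique,
three pairwise-common and one all-common portion. The portions sum to the
full-model R² as an algebraic identity. Raw (not adjusted) R² is used in
the portion algebra because inclusion–exclusion requires additivity, which
the nonlinear adjustment penalty breaks; adjusted R² is reported alongside
for the full and ceiling models. Negative portions (suppressor structure)
are mathematically meaningful and reported as-is, never clipped.

## Smoothness-matched voxel-shuffle permutation null

Because the dependent (self > semantic) and one predictor (other >
semantic) share the semantic control condition, naive permutation schemes
would break that shared-control structure and bias the null. The package's
null therefore shuffles **only the self-condition (vs rest) pattern**: one
voxel permutation per iteration, applied identically to the self pattern of
every run (preserving the cross-run reliability the statistic relies on),
after which the self > control contrast and the statistic are recomputed.
Everything involving the control and the predictors stays intact.

Shuffling destroys spatial autocorrelation, which by itself would distort
the null. The shuffled patterns are therefore re-smoothed with a Gaussian
kernel whose standard deviation (voxel units) is calibrated so that the
Moran's I of shuffled-then-smoothed maps best matches the observed map's:
for every candidate sd on a grid (default 0 to 2 in steps of 0.02; the
grid is dimensionless and read in voxel units, where a sub-voxel sd is
physically sensible at 3 mm resolution) the sum of squared I-differences
over shuffle replicates is accumulated, and the argmin wins (ties to the
smaller sd). Moran's I uses inverse-Euclidean-distance weights with zero
diagonal; an optional distance cutoff truncates the O(V²) weight matrix for
large ROIs. Fresh permutations are drawn for every (sd, replicate) pair
from a single seeded stream.

For an i.i.d. observed map the calibrated sd is *essentially* zero rather
than exactly zero: discrete Gaussians with sd below roughly half a voxel
are near-identity kernels, so the SSE curve is flat there and the observed
map's own sampling variability picks among equivalent candidates. Tests
assert the near-identity regime, not literal zero.

P-values are right-tailed with the add-one rule, so they are never zero;
hypotheses about explained variance are directional, and a two-sided option
exists. Only the dependent pattern changes across iterations, so the
per-predictor-run least-squares operators are precomputed once
(`runpair_statistic()`), making thousand-iteration nulls cheap.

## The synthetic-data generator

`generator_spec()` draws per-run, per-condition patterns as

    pattern(r, c) = Σ_k loading[c, k] · s_k  +  run_noise_sd · η_r  +  obs_noise_sd · ε

where the latent component fields s_k are unit-variance spatially smoothed
Gaussian fields **fixed across runs** (a participant's condition geometry is
stable), η_r is a fresh smoothed field per run shared by all conditions of
that run (emulating within-run shared physiological noise — exactly the
structure the RSA same-run exclusion and the cross-run regression design
defend against), and ε is i.i.d. noise. Defaults mirror the block design
the package models: 7 conditions, 5 runs, 2 blocks per condition per run
(14 blocks, pseudorandomized with no condition repeated back-to-back,
via rejection sampling with a 10,000-shuffle cap), 3 mm isotropic voxels,
6 mm FWHM component smoothness. Generation is bit-reproducible given the
spec's seed, and the generator restores the caller's RNG state.

`planted_vpa_spec()` is the calibrated workhorse: its loading matrix plants
a component shared by self, other, introspection and memory (gain 1.5 on
the predictors), a self–other-only component, predictor-unique components
(amplitude 0.7), a self-unique component, and per-task baseline fields that
cancel in every contrast, with `obs_noise_sd = 0.5`. Solving the population
covariance algebra for these amplitudes puts the variance partition of the
self > semantic contrast at exactly `unique_O = 0.100` and
`common_OIM = 0.150` with a full-model R² of 0.319 — known ground truth
against which the whole regression/VPA stack is validated by parameter
recovery. One subtlety the closed form must include: within the predictor
run, the noise-ceiling replicate shares the semantic control's observation
noise with the O predictor, which adds 0.25 to their covariance.

What the generator does *not* emulate: HRF convolution or any time-series
structure, motion artifacts, physiological noise spectra,
between-subject anatomical variability, or non-Gaussian signal. Passing
parameter-recovery tests therefore demonstrates that the estimators are
correct for data satisfying the model's covariance assumptions — not that
real fMRI data satisfy them.

## Numerical choices

* **Smoothing** is separable Gaussian convolution, truncated at 4 sd. At
  the *volume* boundary the truncated kernel is renormalised to unit mass,
  so constant volumes are exactly preserved; at *mask* edges values outside
  the mask are zeroed before convolution and the output is re-masked
  (zero-padding), so smoothed values near a mask edge are attenuated toward
  zero rather than silently renormalised. Kernels given in mm are converted
  per axis by the grid's voxel sizes — anisotropic voxels get per-axis
  standard deviations, never an average.
* **Pearson correlations** use the standard n − 1 denominators;
  correlation is scale-invariant so the choice is cosmetic, but it is
  fixed.
* **Sphere membership** compares squared integer distances.
* **Zero-variance patterns** raise explicit errors in RSM construction and
  regression (never silent NaN).
* **Rank-deficient predictor matrices** abort with the predictor names.
* **Ties**: tau-a ties follow the all-pairs definition; the median split
  sends ties to "short"; calibration SSE ties go to the smaller sd; an SVM
  decision value of exactly 0 goes to class b.

## Problem sizes used by the test-suite simulations

Statistical properties are verified at deliberately chosen desk scales:
parameter recovery at V = 10,000 voxels with 20 simulated subjects;
chance-level classification over 200 signal-free datasets of 300 voxels;
null calibration of the voxel-shuffle test over 200 replicates of a
216-voxel ROI with 200 permutations each; Moran's I null expectation over
500 draws of 300-voxel maps; block-schedule invariants over 1,000 seeds.
Smaller grids (5³–10³) exercise the searchlight, group-statistics and I/O
paths where the quantity under test is exact rather than statistical.

## Known limitations

* The permutation-null design assumes the shuffled condition's pattern is
  exchangeable across voxels after smoothness matching; gross
  inhomogeneities (e.g., strong anatomical gradients within the ROI) are
  matched only through their global Moran's I.
* Cluster-forming uses plain t, not variance-smoothed pseudo-t; at small n
  the two can select different cluster-forming sets.
* The Moran's I weight matrix is dense; ROIs beyond a few thousand voxels
  should use the distance cutoff.
* Inference for regression betas is delegated entirely to the permutation
  null; no spatial-autocorrelation-adjusted parametric standard errors are
  provided.
* Multi-ROI analyses emit uncorrected p-values; apply `p.adjust()` across
  ROIs as appropriate.
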