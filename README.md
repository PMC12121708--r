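# mvpatterns

Multivoxel pattern similarity, searchlight mapping, and variance
partitioning for condition-rich block-design fMRI.

## What problem this solves

Experiments that probe self-referential thought (and condition-rich designs
generally) collect one activation pattern per condition per scanner run —
e.g., seven conditions (self, other, semantic, introspection,
categorization, memory, knowledge) across five runs. The scientific
questions are about the geometry of these patterns within a region such as
the medial prefrontal cortex: which conditions evoke *similar* patterns,
which remain *discriminable*, and how much of one condition's pattern is
explained — uniquely or jointly — by the others. `mvpatterns` implements
that full analysis stack for researchers who have per-run condition
patterns (first-level t- or beta-maps) and a mask, plus a calibrated
synthetic-data generator so every stage can be validated by parameter
recovery without any scanner data.

## What it computes

* **RSA with cell exclusion** — neural representational similarity matrix
  of Pearson correlations r(pattern_i, pattern_j) over (condition, run)
  items; binary model RSMs (self = other, self = introspection,
  self = memory) with validity masks that exclude the diagonal, all
  same-run pairs (shared physiological noise) and all same-condition
  pairs; model fit by Kendall's tau-a,
  τ_a = (n_con − n_dis) / (n(n−1)/2), the all-pairs form appropriate for
  tied binary models.
* **Classifier MVPA** — linear SVM (LIBSVM via `e1071`, cost c = 1, no
  scaling) with leave-one-run-out cross-validation; optional sphere-mean
  removal; chance = 50%.
* **Searchlight mapping** — 3-voxel-radius spheres (123 voxels in the
  interior) carrying any per-sphere statistic into whole-volume maps.
* **Group inference** — sign-flip permutation test with parametric
  cluster-forming t thresholds (dual in/out-of-ROI voxel p), cluster-extent
  FWE p = (1 + #{max-cluster ≥ observed})/(1 + n_perm), and n-way overlap
  (conjunction) maps.
* **Cross-run pattern regression + commonality analysis** — OLS of the
  self > semantic pattern on the other > semantic (O),
  introspection > categorization (I) and memory > knowledge (M) patterns
  over all 20 ordered pairs of distinct runs; a noise-ceiling model that
  adds the dependent pattern from the predictor run; decomposition of the
  full-model R² into seven commonality portions (unique_O, unique_I,
  unique_M, common_OI, common_OM, common_IM, common_OIM) that sum to R²
  exactly; explainable variance = 100 · adjR²_full / adjR²_ceiling.
* **Smoothness-matched permutation null** — voxel-shuffle null that
  permutes only the self-condition map (identically across runs),
  re-smooths at a Gaussian sd calibrated by matching Moran's I
  (inverse-Euclidean-distance weights) over a 0–2 sd grid, and recomputes
  the regression/VPA statistics.

## Worked example

Simulate one subject with planted signal structure and run the core
analyses:

```r
library(mvpatterns)
grid <- volume_grid(c(10, 10, 10))          # 1,000 voxels at 3 mm
ds <- generate_pattern_dataset(planted_vpa_spec(grid, seed = 3))

nr <- build_neural_rsm(ds)
for (m in c("self_other", "self_introspection", "self_memory"))
  cat(sprintf("%-20s tau-a = %6.3f\n", m,
      kendall_tau_a(nr, build_model_rsm(m, ds$n_runs))))

dc <- default_contrasts()
loro_cv_accuracy(compute_contrast(ds, dc$self_gt_semantic),
                 compute_contrast(ds, dc$other_gt_semantic))

variance_partition(ds)
cat(sprintf("explainable variance: %.1f%%\n",
    explainable_variance_pct(fit_runpair_regressions(ds),
                             fit_noise_ceiling(ds))))
```

Output:

```
self_other           tau-a =  0.445
self_introspection   tau-a =  0.056
self_memory          tau-a =  0.056
cv_result: mean accuracy 1.000 over 5 folds (1.00, 1.00, 1.00, 1.00, 1.00)
vpa_result: full R2 0.2944 (adj 0.2923), 20 run pairs
  unique_O   unique_I   unique_M  common_OI  common_OM  common_IM common_OIM
    0.1165     0.0009     0.0007     0.0201     0.0330     0.0004     0.1228
explainable variance: 87.7%
```

Reading this: the self = other model fits the neural RSM far better than
the other two models (the generator plants a self–other-only component on
top of a component shared by all four tasks), yet the self and other
patterns remain perfectly discriminable — similarity and discriminability
are not opposites. The variance partition recovers the planted structure:
at this single-subject size the portion unique to the other-predictor
(0.117) and the portion common to all three predictors (0.123) estimate
their population values of 0.100 and 0.150, and the seven portions sum to
the full-model R² exactly. The generator's documented ground truth for the
explainable-variance share is 88.5%.

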