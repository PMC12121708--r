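Package: mvpatterns
Title: Multivoxel Pattern Similarity, Searchlight Mapping, and Variance
    Partitioning for Condition-Rich fMRI Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing per-run, per-condition voxel activation
    patterns from block-design fMRI experiments: representational
    similarity analysis with binary model matrices, cell-exclusion rules
    and Kendall tau-a model fits; linear support-vector-machine pattern
    discriminability with leave-one-run-out cross-validation; volumetric
    searchlight mapping; sign-flip permutation group inference with
    cluster-extent familywise-error correction; cross-run multivariate
    pattern regression with a noise-ceiling model; commonality analysis
    (variance partitioning) over three predictors; and a spatial-
    smoothness-matched voxel-shuffle permutation null calibrated by
    Moran's I. A synthetic-data generator plants known shared and unique
    signal components so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
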