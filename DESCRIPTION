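Package: sharedrep
Title: Shared Neural Representation Analysis for Multivariate fMRI Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify shared versus modality-specific neural
    representations with multivariate pattern analysis of fMRI condition
    images. Trains whole-brain linear support-vector decoders with repeated
    ten-fold cross-validation and forced-choice evaluation, tests
    cross-modality generalization, maps reliable decoder weights by
    bootstrap resampling with FDR and cluster-extent thresholding, compares
    weight maps with permutation-based spatial-similarity tests and octant
    joint-weight summaries, runs spherical-searchlight cross-prediction, and
    measures pattern-expression transfer to independent graded-intensity
    data. A synthetic-data generator with planted ground-truth patterns
    makes every stage testable without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
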