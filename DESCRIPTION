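Package: submvpa
Title: Subsequent-Memory Multivoxel Pattern Analysis on Simulated BOLD Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for trial-wise decoding of subsequent-memory outcomes
    from fMRI BOLD data: generation of fast-mapping / explicit-encoding
    event schedules, simulation of 4D BOLD runs with class-dependent
    multivoxel patterns, baseline-referenced preprocessing and peak-window
    trial extraction, linear support-vector-machine classification with
    nested ANOVA-F feature selection under run-wise and subject-wise
    cross-validation, dataset-wise label-permutation inference,
    region-of-interest restricted decoding, and spherical searchlight
    information mapping with binomial above-chance thresholding.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
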