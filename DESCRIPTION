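Package: microstates
Title: Resting-State EEG Microstate Segmentation, Backfitting and Group Statistics
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for resting-state EEG microstate analysis: polarity-invariant
    modified k-means clustering of topographies at global field power peaks with
    meta-criterion selection of the number of maps, two-stage (subject then group)
    segmentation, winner-takes-all backfitting with temporal smoothing and
    small-segment rejection, temporal parameters (global explained variance,
    mean duration, time coverage, occurrence rate), a Laplacian-weighted
    minimum-norm (LORETA-style) distributed inverse on a spherical head model
    with microstate-gated source averaging, group statistics (one-way ANOVA from
    raw data or printed summary statistics, FDR-corrected pairwise tests,
    Cohen's d, Amsterdam Resting-State Questionnaire domain scoring), and a
    synthetic-EEG generator with planted microstate structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, signal, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
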