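Package: cervseq
Title: Sequence of Segmental Contributions in Cervical Spine Fluoroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the quality of cervical spine motion in
    dynamic flexion-extension fluoroscopy. Tracks the rigid pose of
    vertebrae C4 to C7 across an image sequence, converts poses into
    segmental rotation series, builds sequence-of-segmental-contribution
    (SSC) curves against cumulative C4-C7 rotation, and classifies each
    recording for the presence of the cranial-to-caudal extension
    sequence (C4-C5, then C5-C6, then C6-C7). Also computes segmental
    and total range of motion, Cobb-angle sagittal alignment from
    endplate landmarks, eligibility screening, and the reliability and
    correlation statistics used for cohort analysis (absolute-agreement
    average-measures intraclass correlation, exact permutation Spearman
    tests, coefficients of variation). A synthetic-motion module
    generates ground-truth kinematics and rendered lateral-view phantom
    image stacks so the whole pipeline can be validated without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
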