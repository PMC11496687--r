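Package: seqhorizon
Title: Multistep Anticipation Horizons from fMRI Pattern Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying how circular environment
    sequences are represented during multistep anticipation with
    multivoxel fMRI pattern similarity. Provides construction and
    validation of two-path circular map designs and trial schedules,
    across-participant environment-template estimation with
    leave-one-subject-out reliability mapping and conjunction ROIs,
    cue-centered ordered pattern-similarity profiles with a
    different-map baseline, asymmetric-Gaussian profile fitting with
    L2 regularization and permutation inference, searchlight mapping
    of fit parameters with posterior-anterior gradient and hierarchy
    statistics, brain-behavior linking of suppression to response-time
    costs, and a synthetic multivoxel data generator with known ground
    truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
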