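Package: locokit
Title: Hindlimb Kinematics, EMG, and Optogenetic Response Analysis for
    Rodent Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of rodent locomotor recovery after spinal cord
    injury: sagittal-plane hindlimb joint kinematics with knee
    triangulation, gait-cycle normalization (512 bins) and swing-phase
    coefficient-of-variation variability, circular phase coupling of
    joints and limbs, swim-stroke segmentation, EMG motor-spike
    extraction and burst/step-cycle segmentation, phase-dependent
    classification of photostimulation-evoked motor responses,
    open-field locomotor-initiation metrics, and a normality-gated
    statistical decision policy. Includes seeded synthetic-data
    generators with full ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    emmeans,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
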