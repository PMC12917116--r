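Package: lumbarplan
Title: Lumbar Spine MRI Scan-Plane Planning, Disc Labeling and Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational core of an automated lumbar spine MRI planning
    pipeline. Generates parametric synthetic lumbar localizer volumes with
    analytic ground truth (vertebrae, intervertebral discs, spinal canal,
    spinous processes, psoas muscles, optional planted stenosis or disc
    herniation); builds Gaussian keypoint heatmaps and extracts candidate
    disc centers; assigns anatomical disc labels by template sequence
    matching; plans per-disc transverse scan planes via principal component
    analysis, least-squares sagittal/coronal planes and anterior saturation
    bands with a spacing-based quality factor; and computes a lumbar
    morphometry suite (canal diameter, lateral recess height and angle,
    foraminal and disc heights, psoas cross-sectional area, facet joint
    angles, disc herniation ratio and MSU grade/zone) with configurable
    diagnostic thresholds. Includes focal loss, heatmap mean squared error
    and Dice coefficient utilities, NIfTI and JSON/CSV input/output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
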