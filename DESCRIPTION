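Package: colliscope
Title: Two-Photon Calcium Imaging Analysis for the Auditory Midbrain
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for two-photon calcium imaging of the
    mouse inferior colliculus. Builds tone and amplitude-modulated noise
    stimulus grids and randomized presentation schedules; extracts
    neuropil-corrected delta-F/F traces from image stacks and ImageJ ROI
    sets; flags responsive cells by inter-trial Pearson correlation and
    quantifies responses by area under the curve; derives best tone and
    modulation frequencies, receptive-field sums, and spectral/temporal
    modulation and bimodal response indices; quantifies tonotopic gradients
    by binned geometric-mean regression; detects spontaneous calcium events
    in stimulus-free recordings; and renders pseudocolor cell maps with ROC
    validation of the flagging method. A ground-truthed synthetic-data
    generator makes every stage testable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    tiff,
    MASS
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'stimulus_design.R'
    'imagej_roi.R'
    'synthetic_data.R'
    'signal_extraction.R'
    'responsiveness.R'
    'modulation_indices.R'
    'tonotopy.R'
    'spontaneous_activity.R'
    'reporting_validation.R'
    'pipeline.R'
    'colliscope-package.R'
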