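Package: imnpheno
Title: Single-Cell Phenotyping, Longitudinal Tracking and Bioenergetics of
    Induced Motor Neuron Cultures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Image-based single-cell analysis of directly converted induced
    motor neuron (iMN) cultures: seeded-watershed segmentation of
    fluorescence micrographs, three-class morphological cell classification
    (iMN / non-iMN / dead), neurite skeleton morphometry, nuclear versus
    cytoplasmic TDP-43 partitioning, per-cell mitochondrial segmentation
    (TMRM), kymograph-based mitochondrial motility scoring, greedy
    multi-object tracking of iMN across long-term time-lapse imaging with
    MOTA evaluation and conversion of tracks to start-end-censor survival
    records, Kaplan-Meier / logrank / Cox proportional-hazards survival
    statistics, Dunnett-style many-to-one comparisons for per-cell
    phenotypes, and extracellular-flux (OCR/ECAR) trace correction with
    mito-stress-test parameter extraction. A synthetic-microscopy and
    synthetic-cohort generator produces every input the pipeline consumes,
    with ground truth, so the whole pipeline is testable without imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    survival,
    multcomp,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: CellBiology, Neuroscience, Software, SingleCell, Survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
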