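Package: romnet
Title: Cervical Range-of-Motion Kinematics, Polygon-Area Mobility Scores and
    Neural-Network Recovery Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing active cervical range-of-motion assessments in
    whiplash-associated disorders. Segments self-paced oscillatory neck-angle
    recordings into repetitions and summarises each movement as mean range of
    motion, repetition-to-repetition coefficient of variation and speed to
    peak; combines the normalized main ranges into a single polygon-area
    mobility percentage (NFHAS) via Heron's formula and stages its severity;
    assembles 18 z-scored kinematic predictors with scaled-MAD outlier
    exclusion; trains feed-forward regression networks with a
    Levenberg-Marquardt optimizer written from first principles; selects the
    architecture by Monte-Carlo cross-validation (optionally after PCA); and
    evaluates predicted versus real mobility change with regression R,
    quadrant agreement and paired pre/post tests. A synthetic-cohort
    generator with a known ground-truth recovery model supports
    parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'ann.R'
    'cohort.R'
    'evaluation.R'
    'io.R'
    'kinematics.R'
    'nfhas.R'
    'normative.R'
    'pipeline.R'
    'preprocessing.R'
    'romnet-package.R'
    'selection.R'
    'synthetic.R'
    'utils.R'
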