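Package: MechanoATP
Title: Quantitative Analysis of Mechanically Stimulated ATP Release from Bone Cells
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for single-cell studies of mechanically stimulated
    ATP release from osteoblasts and osteocytes: parameterization of ratiometric
    Fura-2 calcium transients (amplitude, 10-90% activation time, exponential
    decay constant, activation rate, secondary responsiveness of neighboring
    cells), calibrated luciferin-luciferase ATP quantification with
    instantaneous-plane-source diffusion fitting of single-cell release,
    detection of vesicular exocytosis events in time-lapse image stacks by
    temporal reversal, classification of membrane injury from dye-leakage
    traces, and bracketing of membrane lesion radius from tracer permeability.
    Includes synthetic-data generators with embedded ground truth for every
    input the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CellBiology, Software, TimeCourse, CellBasedAssays
RoxygenNote: 7.3.3
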