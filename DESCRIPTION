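Package: tismorph
Title: Label-Free Morpho-Molecular Quantification of Therapy-Induced Senescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for label-free detection of
    therapy-induced senescence (TIS) in cancer cell cultures from multimodal
    nonlinear-optical (NLO) microscopy and quantitative phase imaging (QPI).
    Provides raw-image corrections (1-pixel outlier median filtering,
    serpentine scan-shift correction, stimulated Raman gain normalization),
    per-field mitochondrial and lipid-droplet metrics (TPEF area fraction,
    aggregation index, circularity-filtered droplet analysis), pixel-frequency
    Manders colocalization with a Costes randomization control, refractive
    index tomogram morphometrics (volume, thickness, dry mass, lipid content),
    nonparametric time-course statistics, and a seeded synthetic-data
    generator with ground truth emulating control and senescent phenotypes so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
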