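Package: phytosense
Title: In Vivo Biosensor and Image-Based Drought-Stress Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for drought-stress experiments that combine an
    in-planta organic electrochemical transistor (bioristor) with multi-view
    image-based phenotyping and manual physiology. Computes the sensor
    response R = (Ids - Ids0)/Ids0 and its stressed/control normalization NR,
    segments the NR trajectory into drought phases by BIC-selected piecewise
    linear regression, detects stress onset from windowed slope tests, derives
    digital biovolume, height, compactness, green index and NIR hydration
    index from RGB/NIR plant images, computes relative water content, relative
    SPAD and stomatal-conductance fold changes, and integrates all modalities
    through per-timepoint tests, Pearson correlations and PCA biplots. A
    seeded synthetic-data generator emulates the greenhouse experiments so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
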