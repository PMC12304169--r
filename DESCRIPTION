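Package: benthoscan
Title: Seafloor Image Survey Analysis: Enhancement, Habitats, Abundance and Spatial Ecology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for towed-camera (OFOS-style) seafloor photo
    surveys: batch colour correction of underwater images, unsupervised
    habitat clustering from image features, conversion of per-image taxon
    detections into area-standardised abundances on fixed-length along-track
    sampling units, local Moran (LISA) hotspot and coldspot detection, and
    multivariate community analysis (Bray-Curtis, UPGMA, ANOSIM, SIMPER,
    Shannon diversity, non-metric multidimensional scaling with environmental
    vector fitting). Includes a synthetic survey generator with known ground
    truth so every stage can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    EBImage,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    ape,
    mclust,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
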