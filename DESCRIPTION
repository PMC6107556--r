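Package: somitedyn
Title: Quantitative Analysis of Somite Morphogenesis from 4D Membrane-Labelled Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify cellular dynamics in developing somites from
    time-lapse 3D (multi-photon) image stacks of membrane-labelled tissue.
    Implements somite volume growth measurement via a sphere model and its
    decomposition into proliferation versus cell-size growth, pixel-wise
    image-correlation measures of morphological change, detection of rounded
    dividing cells by size and circularity gating, spot detection with simple
    linear-assignment (LAP) cell tracking and circular directionality
    statistics, and membrane-based 3D seeded-watershed cell counting in
    medial/lateral domain boxes. A ground-truthed synthetic 4D membrane-image
    generator provides testable oracles for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    mclust,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
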