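Package: strokecbv
Title: Perfusion-CT Blood Volume Analysis for the Rat MCA Occlusion Stroke Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for detecting inadvertent anterior choroidal artery (AChA)
    occlusion on perfusion-CT cerebral blood volume (CBV) maps in the rat
    intraluminal middle cerebral artery occlusion (MCAo) stroke model, and for
    linking the AChA call to 24 h infarct volume. Provides a parametric
    coronal territory atlas, a seeded synthetic-cohort generator (CBV maps and
    histology infarct traces), the large-vessel and contralateral-mean CBV
    thresholding classifier, edema-corrected infarct volumetry with
    cortical/subcortical partitioning and infarct probability maps, and the
    cohort inference chain (D'Agostino-Pearson normality, two-sample t-tests,
    Pearson screening, standardized multiple regression), orchestrated by a
    reproducible end-to-end study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
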