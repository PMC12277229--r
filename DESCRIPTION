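Package: tubewellrisk
Title: Groundwater Quality and Children's Health Risk Assessment for
    Tubewell Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the drinking-water quality of school
    tubewells and the associated non-carcinogenic health risk to
    schoolchildren.  Implements multi-authority guideline compliance
    accounting (WHO, US EPA, Bangladesh standards), chronic daily intake,
    hazard quotient and hazard index computation for iron and arsenic,
    safe daily water-intake limits at a target hazard quotient of one,
    correlation / principal-component / depth-regression diagnostics, a
    seeded synthetic cohort generator with realistic correlation
    structure and field-kit quantization, and a feed-forward surrogate
    model of the safe-intake limit with regularized gradient training,
    k-fold cross-validation and exact Shapley attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
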