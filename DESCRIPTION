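Package: cranioshape
Title: Three-Dimensional Craniofacial Asymmetry Analysis for Unilateral
    Lambdoid Synostosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Landmark-based craniometrics, watertight-mesh volumetry with
    plane partitioning, tragi-centered radial composite heat maps, and the
    triplicate/two-rater cohort comparison protocol used to quantify anterior
    craniofacial asymmetry in unilateral lambdoid craniosynostosis. Includes
    a synthetic skull-phantom generator that realizes target craniometric
    values and region volumes geometrically, so every measurement operator
    can be exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
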