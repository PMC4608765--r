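Package: cephtmj
Title: Cephalometric Morphometrics and Condylar Osseous Classification
    for TMJ Osteoarthrosis Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Landmark-based cephalometric measurement in a rotated
    cranial-base coordinate system (X-axis 7 degrees inferior to the
    sella-nasion line), rule-based three-tier condylar osseous diagnosis
    with worst-side patient aggregation and cohort tabulation,
    measurement reliability via the Dahlberg method error and paired t
    tests, and three-group comparison of cephalometric variables with
    one-way ANOVA, variance-homogeneity routing to Fisher LSD or Dunnett
    T3 pairwise tests, and compact letter displays.  A synthetic cohort
    generator draws measurement vectors from group-conditional normal
    distributions and inverts the measurement geometry exactly, so every
    pipeline stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
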