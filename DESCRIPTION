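Package: boreff
Title: Boron-Deficiency Tolerance Screening Analytics for Plant Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for soil-substrate boron (B) deficiency screens of
    Brassica napus panels: boron-efficiency-index (BEI) scoring and
    classification from endpoint dry-weight and leaf-length measurements,
    trait extraction from segmented top-view plant images (projected area,
    border length, convex hull, colour means), windowed relative growth
    rates with growth-arrest detection, root-elongation cessation analysis
    (daily depth gain, slope coefficients), root-system-architecture
    metrics from traced polylines, replicate-mean aggregation with PCA and
    treatment-separation scoring, and a seeded synthetic-data generator
    that emulates the screen design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    stats,
    grDevices,
    tools,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
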