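Package: hhindex
Title: Global Hidden Hunger Indices from Country-Level Micronutrient Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs composite hidden hunger indices from country-level
    micronutrient deficiency data. Harmonizes national prevalence estimates of
    stunting, anemia, low serum retinol and low urinary iodine among children
    (anemia-to-iron-deficiency-anemia conversion with malaria adjustment,
    GDP-based vitamin A assumptions, development-index exclusion rules and
    population-weighted regional imputation), computes the prevalence-based
    index with its four-level severity scale and the burden-based indices from
    disability-adjusted life years attributed to iron, zinc and vitamin A
    deficiency, and provides rank-correlation and top-k overlap analyses,
    categorical choropleth maps, population-scaled letter scatter plots, and a
    seeded synthetic country-cohort generator so the full pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
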