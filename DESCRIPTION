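Package: traitfilter
Title: Environmental Filtering of Pollinator Functional Traits Along
    Elevation Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of functional-trait composition in bee
    and fly communities sampled with pan-trap ("pollinator cup") arrays along
    a montane elevation gradient.  Provides specimen morphometrics from
    three-view images (ellipsoid body volume and median body darkness on a
    0-222 scale), community-weighted means and trait ranges per cup sample,
    a richness-conditioned null model yielding standardized effect sizes of
    trait ranges (sesRange) with an environmental-filtering classification,
    zone-level one-way ANOVA with Tukey HSD, and intraspecific trend tests.
    A fully parameterized synthetic-data generator emulates the sampling
    design (life zones, sites, habitats, cup arrays, seasons) and the trait
    structure of the regional species pools, so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
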