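Package: soilmultifun
Title: Plant Diversity Effects on Soil Ecosystem Multifunctionality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing biodiversity effects on multiple
    soil functions in a factorial grassland experiment crossing sown plant
    species richness with elevated CO2 and nitrogen enrichment. Converts raw
    assay measurements (hourly O2-consumption series, wet-sieving masses) to
    four soil functions; computes taxonomic diversity and evenness as well as
    distance-based functional-diversity indices (FRic, FEve, FDiv, FDis) from
    covers and traits; quantifies ecosystem multifunctionality by the
    averaging and multiple-threshold approaches and by the evenness of
    standardized functions; and fits the study's statistical layer:
    split-plot Type III ANOVA with the whole-plot factor tested against
    ring-within-CO2 variation, Pearson correlation structure among functions,
    and a recursive path model linking species richness, functional
    dispersion, evenness of functions, and multifunctionality. A synthetic
    data generator emulates the 364-plot split-plot design and its reported
    effect structure so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ape,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
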