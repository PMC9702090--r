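Package: envmet
Title: Envirotyping-Based Mega-Environment Delineation and Multi-Trait
    Stability Selection for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for dissecting genotype-by-environment interaction in
    multi-environment trials using long-term daily weather data. Derives
    environmental covariables (thermal time, vapour pressure deficit,
    reference evapotranspiration, solar geometry) from raw weather series,
    builds an envirotype descriptor matrix and enviromic kernel, delineates
    mega-environments by hierarchical clustering, and characterises trials
    with quantile-based environmental typologies. Fits crossed random-effects
    models by REML to partition phenotypic variance and estimate broad-sense
    heritability, computes Wricke's ecovalence as a year-to-year stability
    measure, combines mean performance and stability into a weighted 0-100
    index (MPS), and ranks genotypes with a factor-analytic multi-trait index
    (MTMPS) measuring distance to an ideotype. Includes a synthetic-data
    generator that emulates the weather and phenotype structure the analysis
    assumes, so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
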