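Package: flordyn
Title: Functional Diversity Dynamics of Sown Flower-Strip Plant Communities
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design, measurement and inference tools for sown herbaceous plant
    communities followed over several years. Builds seed assemblages that cross
    species richness with functional diversity, computes trait-based community
    metrics on mixed-type Gower distances (functional dispersion, Rao quadratic
    entropy, functional redundancy, Simpson diversity and evenness,
    community-weighted means, regeneration-strategy cover shares), generates
    name-shuffling null distributions with standardized effect sizes, and fits
    temporal trends by AIC-based multimodel inference with full model averaging
    over nested mixed models. A mechanistic succession simulator (species loss
    moderated by redundancy, dominance shifts toward high-LDMC species,
    invasion declining with sown dispersion) provides end-to-end synthetic
    benchmarks for every stage.
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
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
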