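Package: traitpart
Title: Variance Partitioning and Trait-Space Analysis for Plant Trait Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for biome-scale analyses of plant functional trait
    variation assembled from heterogeneous trait databases. Provides a
    hierarchical error-risk procedure for cleaning multi-contributor trait
    tables (within-dataset duplicate removal and staged outlier screening at
    the trait, dataset and species level), nested variance partitioning of
    trait variation into functional-group, species and within-species
    components by restricted maximum likelihood, a geographic-scale
    accumulation analysis that tracks variance sources and species richness
    as sites are pooled by proximity (with segmented one-breakpoint fits),
    and principal-component analysis of species-mean log traits. A
    synthetic trait-database generator with known hierarchical variance
    structure, planted trait-space axes, spatial species turnover, and
    injected duplicates and outliers supplies ground truth for testing
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
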