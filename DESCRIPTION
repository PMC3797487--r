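Package: redlistrf
Title: Random-Forest Classification of Species Rarity and Decline from
    Trait Attributes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for trait-based classification of species
    rarity and decline as assessed in national Red Lists.  Raw traits and
    grid-cell distribution data are engineered into categorical attributes
    (dummy expansion, five-level ordinal binning, group-equalized phi
    preference coefficients, habitat specialization, commonness), missing
    values are imputed from random-forest proximities, and random forests
    of classification trees are grown and evaluated out-of-bag with Type I
    and Type II error probabilities.  Includes the indicator-group transfer
    analysis in which a forest fitted on a well-studied taxon (e.g. birds)
    classifies its enclosing taxonomic group, with a prevalence-corrected
    expected correct-classification rate, replicate confidence intervals,
    and attribute-importance overlap.  A synthetic-data generator with
    planted informative attributes, nested taxonomic groups, nested
    attribute-availability tiers and known Bayes accuracy supports testing
    every pipeline stage without access to the original survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
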