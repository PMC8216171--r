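Package: cyanoquant
Title: Quantitative Genetics of Biosynthesized Cyanogenic Toxicity in
    Heliconius Butterflies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pedigree-based quantitative-genetic and field-survey analysis of
    de novo biosynthesized cyanogenic glucoside (linamarin + lotaustralin)
    concentrations in Heliconius erato. Provides a synthetic-data generator
    for full-sib/half-sib common-garden breeding designs and gradient field
    surveys, construction of the additive (numerator) relationship matrix,
    restricted maximum likelihood (REML) animal models with an optional
    maternal-identity random effect, broad-sense heritability and mean-scaled
    evolvability, brood repeatability (ICC) with parametric bootstrap,
    parent-offspring regressions and Falconer maternal-effect coefficients,
    compound selection-response projections with maternal transmission, and
    population-comparison statistics (square-root ANOVA, Tukey HSD, Hedges'
    g, zero-truncated weighted kernel densities).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
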