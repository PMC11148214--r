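Package: gdmliver
Title: Liver Biomarkers and Gestational Diabetes: Cohort Models and Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to study early-pregnancy liver biomarkers (ALT, AST, GGT,
    ALP, AST/ALT ratio, hepatic steatosis index) and the risk of gestational
    diabetes mellitus (GDM) and its OGTT-defined subtypes. The cohort arm
    provides exclusion filtering, GDM diagnosis and subtyping, quartile
    logistic models with median-assigned trend tests, restricted cubic spline
    nonlinearity testing with piecewise follow-up, multinomial subtype models,
    overweight-stratified reruns, and multiplicative crossover interaction
    analysis with lipids. The Mendelian randomization arm provides instrument
    selection, LD clumping, allele harmonization, instrument-strength
    diagnostics, and IVW, MR-Egger, weighted-median, MR-PRESSO and
    multivariable MR estimators for GWAS summary statistics. Seeded synthetic
    generators emulate both arms' inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
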