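Package: sporefit
Title: Fitness Analysis of Cooperator-Cheater Competitions from
    Dilution-Plate Spore Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for starvation-induced sporulation
    competition assays in social bacteria such as Myxococcus xanthus.
    Estimates viable spore populations from dilution-plate colony counts
    by pooled Poisson maximum likelihood, resolves strain mixtures from
    selective versus nonselective plating, applies a detection-limit
    imputation rule to zero-count samples, and computes log-ratio social
    fitness statistics: the one-way mixing effect C_i(j) and the relative
    fitness in mixture W_ij. Includes the accompanying testing battery
    (one-sample and Welch t tests, Holm step-down adjustment, Dunnett
    many-to-one comparisons by seeded Monte Carlo, Tukey HSD, exact
    binomial sign test), classification of social phenotypes (defector,
    cheater, social exploitation, complementation) and their cheating and
    defection-phenotype ranges, and a seeded synthetic plate-count
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
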