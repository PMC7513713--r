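Package: matechoice
Title: Genetic Mate-Choice Analysis for Group-Housed Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing genetic mate-choice hypotheses in group-housed
    conservation breeding programs. Computes standardized multilocus
    heterozygosity and an allele-sharing pair-similarity statistic from
    genome-wide SNP and multi-allelic (e.g. MHC-linked microsatellite)
    genotype panels; tests the "advantage of dissimilar mates" and "optimum
    genetic distance" hypotheses against a structured randomization null,
    per enclosure-year and pooled across strata; fits breeding-success and
    offspring-count regressions with 2-SD predictor standardization,
    all-subsets AICc model selection and full model averaging; and generates
    complete synthetic studies with configurable mate-choice mechanisms so
    every stage of the pipeline can be validated without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    lme4,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
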