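Package: founderseek
Title: Pedigree-Aware Rare-Variant Discovery in Founder Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and characterising recessive
    loss-of-function genotypes in founder populations: rare-genotype
    prioritization from family whole-genome data (dominant, homozygous
    recessive and compound-heterozygous inheritance models with trio
    phasing and segregation checks), genealogy-based genotype imputation
    with a variance-ratio informativeness score, recessive-model
    case-control and quantitative-trait association (likelihood-ratio
    tests, Firth fallback, rank-based inverse-normal standardization,
    impact-weighted Bonferroni thresholds), Hardy-Weinberg founder
    arithmetic (carrier fractions, expected homozygote counts,
    genotype-based prevalence), and dihydrorhodamine oxidative-burst
    stimulation indices. Includes a synthetic-population generator
    (genealogy simulation, gene dropping, phenotype and flow-cytometry
    event simulation) that emulates the statistical structure the
    analysis assumes, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
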