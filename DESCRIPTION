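Package: fbatv
Title: Family-Based Association Tests for Rare Variants with Weighting Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based association test for rare variants (FBAT-v) for
    quantitative traits in pedigree cohorts, with five per-variant weighting
    schemes: an allele-frequency baseline, genotype risk value, log odds
    ratio, an optimal weight built from founder trait/genotype correlations,
    and functional-prediction scores. The test conditions on parental
    genotypes under additive Mendelian transmission, decomposes extended
    pedigrees into nuclear families, and uses an empirical variance over
    independent pedigrees so that type I error is controlled in the presence
    of linkage. Includes a synthetic pedigree-cohort simulator (gene-dropped
    genotypes, heritable polygenic traits, covariates, repeated exams,
    functional-score tables) and a replicate-level evaluation harness for
    empirical type I error and power with binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
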