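Package: megs
Title: Microbiome-Enabled Genomic Selection and Microbial Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction for plant phenotypes that augments ridge
    regression BLUP with rhizosphere microbiome covariates. Provides genotype
    quality control (missingness and minor-allele-frequency filters, sliding
    window linkage-disequilibrium pruning, marker subsampling, VanRaden
    additive relationship matrices, genotype principal components), microbiome
    table preparation (log relative abundance, taxonomic aggregation,
    repeatability scoring, within-treatment shuffling nulls), single- and
    two-variance-component linear mixed models with plug-in variance
    estimation, genotype-disjoint cross-validation with shuffled-microbiome
    control arms, a genome-wide mediation scan treating microbes as
    intermediates between host genotype and phenotype, and a synthetic
    hologenome generator emulating a split-plot nitrogen field trial for
    power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    vcfR
Config/testthat/edition: 3
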