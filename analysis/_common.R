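# Shared settings for the analysis drivers: one study-condition simulation
# configuration (reduced scale) and the output location. Every driver
# re-derives the same dataset from MASTER_SEED, so the scripts can be run
# independently or in order.

library(megs)

MASTER_SEED <- 2019L  # field season of the emulated trial
RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# LN-dominant scenario at reduced scale: 100 genotypes in the 2x2 split-plot
# layout (~360 plots after 10% dropout), 2,000 pruned-and-sampled SNPs,
# 200 ASVs in 20 groups / 8 classes, microbial effects active under LN only.
study_config <- function(seed = MASTER_SEED) {
  sim_config(n_genotypes = 100, n_snps = 2000, n_asvs = 200,
             n_groups = 20, n_classes = 8,
             n_causal_asvs = 25, n_mediators = 8, n_heritable_asvs = 16,
             asv_h2 = 0.3, h2_snp = 0.4, var_share_asv = 0.3,
             treatment_specific = TRUE, plot_missing_rate = 0.1,
             seed = seed)
}

study_dataset <- function(seed = MASTER_SEED) {
  holo <- simulate_hologenome(study_config(seed))
  list(holo = holo,
       data = megs_data(holo$geno, holo$design, holo$microbiome,
                        holo$phenotype))
}
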