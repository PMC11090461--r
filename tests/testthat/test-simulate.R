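test_that("config invariants are enforced", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(h2_snp = 0.7, var_share_asv = 0.3), "residual")
  expect_error(sim_config(n_causal_asvs = 5, n_mediators = 6), "n_mediators")
  expect_error(sim_config(plot_missing_rate = 1), "missing_rate")
  expect_error(sim_config(asv_h2 = 1), "asv_h2")
  # defaults mirror the emulated field study
  cfg <- sim_config()
  expect_equal(cfg$n_genotypes, 230)
  expect_equal(cfg$n_asvs, 3626)
  expect_equal(cfg$n_groups, 154)
  expect_equal(cfg$n_classes, 19)
  expect_equal(c(cfg$n_treatments, cfg$n_blocks, cfg$n_splitplots,
                 cfg$n_splitplotblocks), c(2, 2, 4, 3))
  expect_equal(cfg$n_snps, 50000)
})

test_that("genotype simulation is seed-deterministic with Binomial-like frequencies", {
  cfg <- sim_config_demo(n_genotypes = 4, n_snps = 3,
                         maf_range = c(0.5, 0.5), seed = 20)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_true(all(g1$dosages %in% 0:2))
  # at maf 0.5 the allele-count distribution over many markers is Binomial(8, .5)
  cfg_big <- sim_config_demo(n_genotypes = 4, n_snps = 4000, ld_block_size = 1,
                             maf_range = c(0.5, 0.5), seed = 21)
  gb <- simulate_genotypes(cfg_big)
  counts <- colSums(gb$dosages)
  expect_equal(mean(counts), 4, tolerance = 0.05)
  expect_equal(var(counts), 8 * 0.25, tolerance = 0.15)
})

test_that("ld_block_size = 1 yields independent markers; blocks are correlated", {
  cfg <- sim_config_demo(n_genotypes = 2000, n_snps = 60, ld_block_size = 1,
                         seed = 22)
  g <- simulate_genotypes(cfg)
  cc <- cor(g$dosages)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.03)

  cfg_ld <- sim_config_demo(n_genotypes = 500, n_snps = 60, ld_block_size = 5,
                            ld_rho = 0.9, seed = 23)
  gl <- simulate_genotypes(cfg_ld)
  cl <- cor(gl$dosages)
  within <- cl[1:5, 1:5][upper.tri(diag(5))]
  across <- cl[1:5, 6:10]
  expect_gt(mean(within), 0.5)
  expect_lt(mean(abs(across)), 0.1)
})

test_that("design has the split-plot layout, dropout and quadrants", {
  cfg <- sim_config(n_genotypes = 230, n_snps = 10, n_asvs = 5,
                    n_groups = 2, n_classes = 1, n_causal_asvs = 2,
                    n_mediators = 1, plot_missing_rate = 0, seed = 24)
  des <- simulate_design(cfg)
  expect_equal(nrow(des), 230 * 2 * 2)
  expect_equal(nlevels(des$treatment), 2)
  expect_equal(nlevels(des$block), 2)
  expect_equal(nlevels(des$splitplot), 4)
  expect_equal(nlevels(des$splitplotblock), 3)
  # each genotype once per treatment x block
  tab <- table(des$genotype, des$treatment, des$block)
  expect_true(all(tab == 1))
  # quadrant is the block x split-plot cell
  expect_identical(as.character(des$quadrant),
                   paste(des$block, des$splitplot, sep = ":"))

  # expected plot count under the default dropout matches the field study
  cfg2 <- sim_config(n_genotypes = 230, n_snps = 10, n_asvs = 5,
                     n_groups = 2, n_classes = 1, n_causal_asvs = 2,
                     n_mediators = 1, seed = 25)
  counts <- vapply(1:30, function(s) nrow(simulate_design(cfg2, seed = s)),
                   numeric(1))
  expect_equal(mean(counts), 795, tolerance = 0.01)
})

test_that("full-scale taxonomy preset collapses 3626 -> 154 -> 19", {
  cfg <- sim_config(n_genotypes = 5, n_snps = 10, n_asvs = 3626,
                    n_causal_asvs = 2, n_mediators = 1, n_heritable_asvs = 2,
                    asv_h2 = 0, plot_missing_rate = 0, seed = 26)
  geno <- simulate_genotypes(cfg)
  des <- simulate_design(cfg)
  mic <- simulate_microbiome(geno, des, cfg)$microbiome
  expect_equal(ncol(mic$values), 3626)
  expect_equal(ncol(aggregate_taxa(mic, "group")$values), 154)
  expect_equal(ncol(aggregate_taxa(mic, "class")$values), 19)
})

test_that("asv_h2 = 0 leaves no genotype signal in the microbiome", {
  cfg <- sim_config(n_genotypes = 100, n_snps = 50, n_asvs = 40,
                    n_groups = 4, n_classes = 2, n_causal_asvs = 5,
                    n_mediators = 2, n_heritable_asvs = 5, asv_h2 = 0,
                    plot_missing_rate = 0, seed = 27)
  geno <- simulate_genotypes(cfg)
  des <- simulate_design(cfg)
  mic <- simulate_microbiome(geno, des, cfg)
  scores <- asv_repeatability(mic$microbiome, des)
  expect_lt(mean(scores), 0.1)
  expect_true(all(vapply(mic$truth$true_B, is.null, logical(1))))
})

test_that("phenotype variance decomposition matches the configured shares", {
  shares <- t(vapply(1:10, function(s) {
    cfg <- sim_config(n_genotypes = 100, n_snps = 100, n_asvs = 50,
                      n_groups = 5, n_classes = 2, n_causal_asvs = 10,
                      n_mediators = 3, n_heritable_asvs = 6,
                      h2_snp = 0.5, var_share_asv = 0.2,
                      plot_missing_rate = 0.1, seed = 100 + s)
    holo <- simulate_hologenome(cfg)
    comp <- holo$truth$components
    tot <- var(comp$genetic) + var(comp$microbial) + var(comp$residual)
    c(var(comp$genetic), var(comp$microbial), var(comp$residual)) / tot
  }, numeric(3)))
  expect_equal(colMeans(shares), c(0.5, 0.2, 0.3), tolerance = 0.05)
})

test_that("realized shares converge at large n", {
  cfg <- sim_config(n_genotypes = 1300, n_snps = 120, n_asvs = 40,
                    n_groups = 4, n_classes = 2, n_causal_asvs = 10,
                    n_mediators = 3, n_heritable_asvs = 6,
                    h2_snp = 0.5, var_share_asv = 0.2,
                    plot_missing_rate = 0.03, seed = 28)
  holo <- simulate_hologenome(cfg)
  expect_gte(nrow(holo$design), 5000)
  comp <- holo$truth$components
  tot <- var(comp$genetic) + var(comp$microbial) + var(comp$residual)
  expect_equal(var(comp$genetic) / tot, 0.5, tolerance = 0.02)
  expect_equal(var(comp$microbial) / tot, 0.2, tolerance = 0.02)
})

test_that("mediators and only mediators carry both paths", {
  b <- demo_bundle(seed = 29)
  truth <- b$holo$truth
  has_B <- names(truth$true_B)[!vapply(truth$true_B, is.null, logical(1))]
  has_gamma <- names(truth$true_gamma)[truth$true_gamma != 0]
  both <- intersect(has_B, has_gamma)
  expect_setequal(both, truth$mediator_ids)
  expect_true(all(truth$mediator_ids %in% truth$causal_ids))
  expect_true(all(truth$mediator_ids %in% truth$heritable_ids))
})

test_that("var_share_asv = 0 makes the phenotype microbiome-independent", {
  cfg <- sim_config_demo(n_genotypes = 80, n_snps = 150, n_asvs = 40,
                         n_causal_asvs = 0, n_mediators = 0,
                         var_share_asv = 0, seed = 30)
  holo <- simulate_hologenome(cfg)
  expect_true(all(holo$truth$true_gamma == 0))
  expect_true(all(holo$truth$components$microbial == 0))
})

test_that("LN-specific effects create LN-dominant phenotype-ASV correlations", {
  cfg <- sim_config(n_genotypes = 150, n_snps = 100, n_asvs = 60,
                    n_groups = 6, n_classes = 3, n_causal_asvs = 10,
                    n_mediators = 3, n_heritable_asvs = 6,
                    h2_snp = 0.3, var_share_asv = 0.3,
                    treatment_specific = TRUE, plot_missing_rate = 0,
                    seed = 31)
  holo <- simulate_hologenome(cfg)
  causal <- holo$truth$causal_ids
  ln <- holo$design$treatment == "LN"
  cor_ln <- abs(cor(holo$microbiome$values[ln, causal], holo$phenotype[ln]))
  cor_hn <- abs(cor(holo$microbiome$values[!ln, causal], holo$phenotype[!ln]))
  expect_gt(mean(cor_ln), mean(cor_hn))
  expect_true(all(holo$truth$components$microbial[!ln] == 0))
})

test_that("the whole simulated dataset is byte-identical on rerun", {
  cfg <- sim_config_demo(n_genotypes = 30, n_snps = 100, n_asvs = 30,
                         n_causal_asvs = 5, n_mediators = 2, seed = 32)
  expect_identical(simulate_hologenome(cfg), simulate_hologenome(cfg))
})
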