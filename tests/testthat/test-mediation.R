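med_bundle <- function(seed, ...) {
  args <- list(n_genotypes = 80, n_snps = 120, n_asvs = 120,
               n_groups = 10, n_classes = 4, n_causal_asvs = 8,
               n_mediators = 8, n_heritable_asvs = 16,
               asv_h2 = 0.4, n_qtl_per_asv = 20,
               h2_snp = 0.2, var_share_asv = 0.4,
               plot_missing_rate = 0.05, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  cfg <- do.call(sim_config, args)
  holo <- simulate_hologenome(cfg)
  list(holo = holo,
       data = megs_data(holo$geno, holo$design, holo$microbiome,
                        holo$phenotype))
}

test_that("confounder matrix has the expected 11 columns under defaults", {
  b <- med_bundle(70)
  Q <- build_confounder_matrix(b$data$design, b$data$pcs)
  # intercept + 3 PCs + (2-1) + (2-1) + (4-1) + (3-1) dummies
  expect_equal(ncol(Q), 11)
  expect_equal(qr(Q)$rank, 11)
  expect_true(all(c("PC1", "PC2", "PC3") %in% colnames(Q)))
  # dropping the PCs reduces Q to the design coding
  Q0 <- build_confounder_matrix(b$data$design, NULL)
  expect_equal(ncol(Q0), 8)
  expect_false(any(grepl("^PC", colnames(Q0))))
})

test_that("mediator model recovers a pure SNP-determined ASV", {
  b <- med_bundle(71)
  d <- b$data
  set.seed(1)
  b_true <- numeric(ncol(d$Z)); b_true[sample(ncol(d$Z), 5)] <- c(2, -1, 1.5, 1, -2)
  M_pure <- drop(d$Z %*% b_true)  # deterministic function of 5 SNPs
  res <- fit_mediator_model(M_pure, d$design, d$pcs, d$Z,
                            n_perm = 199, seed = 2)
  expect_gt(res$genetic_share, 0.95)
  expect_lte(res$p_genetic, 2 / 200)
  expect_error(fit_mediator_model(rep(1, nrow(d$design)), d$design, d$pcs,
                                  d$Z), "constant")
})

test_that("generator round-trip: genetic variance share is recovered", {
  cfg <- sim_config(n_genotypes = 150, n_snps = 120, n_asvs = 60,
                    n_groups = 6, n_classes = 3, n_causal_asvs = 10,
                    n_mediators = 10, n_heritable_asvs = 30,
                    asv_h2 = 0.4, n_qtl_per_asv = 20,
                    plot_missing_rate = 0, seed = 72)
  holo <- simulate_hologenome(cfg)
  d <- megs_data(holo$geno, holo$design, holo$microbiome, holo$phenotype)
  Q <- build_confounder_matrix(d$design, d$pcs)
  Mc <- sweep(d$microbiome$values, 2, colMeans(d$microbiome$values))
  her <- holo$truth$heritable_ids
  shares <- megs:::batch_genetic_share(Mc[, her, drop = FALSE], Q,
                                       tcrossprod(d$Z))
  expect_lt(abs(median(shares) - 0.4), 0.1)
})

test_that("genetic-path p-values are uniform for non-heritable ASVs", {
  # each null ASV tested with its own permutation stream so the p-values
  # are independent draws; KS against uniform
  b <- med_bundle(73, n_asvs = 220, n_heritable_asvs = 16)
  d <- b$data
  Qd <- build_confounder_matrix(d$design, NULL)
  Mc <- sweep(d$microbiome$values, 2, colMeans(d$microbiome$values))
  null_ids <- setdiff(colnames(Mc), b$holo$truth$heritable_ids)
  genos <- as.character(d$design$genotype)
  gi <- as.integer(factor(genos, levels = unique(genos)))
  first <- match(unique(genos), genos)
  K_geno <- tcrossprod(d$Z[first, , drop = FALSE])
  K_geno <- K_geno / mean(diag(K_geno))
  pcs_geno <- d$pcs[match(unique(genos), rownames(d$pcs)), , drop = FALSE]
  p_null <- vapply(seq_along(null_ids), function(i) {
    megs:::genetic_path_test(Mc[, null_ids[i], drop = FALSE], Qd, pcs_geno,
                             K_geno, gi, n_perm = 199, seed = 1000 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p_null, "punif"))
  expect_gt(ks$p.value, 0.01)
  # while heritable ASVs concentrate at small p
  ms <- mediation_scan(d$y, d$design, d$pcs, d$Z, d$microbiome,
                       n_perm = 199, seed = 4)
  p_her <- ms$p_genetic[ms$asv_id %in% b$holo$truth$heritable_ids]
  expect_lt(median(p_her), 0.05)
})

test_that("phenotype-path p-values are uniform when y is independent of M given Z", {
  b <- med_bundle(74, var_share_asv = 0, n_causal_asvs = 0, n_mediators = 0,
                  n_heritable_asvs = 16)
  d <- b$data
  Q <- build_confounder_matrix(d$design, d$pcs)
  Mc <- sweep(d$microbiome$values, 2, colMeans(d$microbiome$values))
  out <- fit_outcome_model(d$y, Q, d$Z, Mc, d$design$treatment,
                           n_perm = 199, seed = 5)
  ks <- suppressWarnings(ks.test(out$p_phenotype, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a constructed residual-matching ASV dominates the outcome model", {
  b <- med_bundle(75)
  d <- b$data
  Q <- build_confounder_matrix(d$design, d$pcs)
  Mc <- sweep(d$microbiome$values, 2, colMeans(d$microbiome$values))
  snp_fit <- reml_single_component(d$y, Q, Z = d$Z)
  resid <- d$y - predict(snp_fit, X = Q, Z = NULL) -
    drop(d$Z %*% snp_fit$random$u)
  M_aug <- cbind(Mc, planted = resid - mean(resid))
  out <- fit_outcome_model(d$y, Q, d$Z, M_aug, d$design$treatment,
                           n_perm = 99, seed = 6)
  expect_identical(names(which.max(abs(out$c))), "planted")
})

test_that("outcome model reproduces the two-component prediction fit", {
  b <- med_bundle(76)
  d <- b$data
  Q <- build_confounder_matrix(d$design, d$pcs)
  Mc <- sweep(d$microbiome$values, 2, colMeans(d$microbiome$values))
  out <- fit_outcome_model(d$y, Q, d$Z, Mc, d$design$treatment,
                           n_perm = 9, seed = 7)
  # same plug-in scheme, same matrices -> identical coefficients
  snp_fit <- reml_single_component(d$y, Q, Z = d$Z)
  asv_fit <- reml_single_component(d$y, Q, Z = Mc)
  joint <- fit_two_component(d$y, Q, d$Z, Mc,
                             var_snp = snp_fit$varcomp[["sigma2_u"]],
                             var_asv = asv_fit$varcomp[["sigma2_u"]],
                             var_e = snp_fit$varcomp[["sigma2_e"]])
  expect_equal(out$c, joint$random$gamma, tolerance = 1e-10)
  expect_equal(out$a, joint$random$alpha, tolerance = 1e-10)
  expect_equal(out$v, joint$fixed, tolerance = 1e-10)
})

test_that("single-path ASVs are not called mediators (MaxP rule)", {
  b <- med_bundle(77, var_share_asv = 0, n_causal_asvs = 0, n_mediators = 0,
                  n_heritable_asvs = 30, asv_h2 = 0.6)
  d <- b$data
  ms <- mediation_scan(d$y, d$design, d$pcs, d$Z, d$microbiome,
                       n_perm = 199, seed = 8)
  # heritable ASVs have a genetic path only; none should be called
  expect_false(any(ms$mediator))
  her <- ms[ms$asv_id %in% b$holo$truth$heritable_ids, ]
  expect_true(all(her$p_joint >= her$p_genetic))
})

test_that("scan output is invariant to ASV column order", {
  b <- med_bundle(78, n_asvs = 60, n_heritable_asvs = 10, n_causal_asvs = 6,
                  n_mediators = 4)
  d <- b$data
  ms1 <- mediation_scan(d$y, d$design, d$pcs, d$Z, d$microbiome,
                        n_perm = 99, seed = 9)
  perm <- sample(ncol(d$microbiome$values))
  micro_perm <- microbiome_table(d$microbiome$values[, perm, drop = FALSE],
                                 d$microbiome$taxonomy[perm, ])
  ms2 <- mediation_scan(d$y, d$design, d$pcs, d$Z, micro_perm,
                        n_perm = 99, seed = 9)
  ord1 <- ms1[order(ms1$asv_id), c("asv_id", "genetic_share", "c_estimate")]
  ord2 <- ms2[order(ms2$asv_id), c("asv_id", "genetic_share", "c_estimate")]
  expect_equal(ord1, ord2, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("omitting the PC confounders inflates mediator calls under structure", {
  # population structure driving both microbiome and phenotype: the PCs in Q
  # are what protects the scan from spurious mediators
  set.seed(80)
  n_g <- 120
  pop <- rep(0:1, each = n_g / 2)  # two subpopulations
  d0 <- sapply(runif(150, 0.1, 0.5), function(p)
    rbinom(n_g, 2, pmin(0.95, p + 0.35 * pop)))
  rownames(d0) <- sprintf("G%03d", seq_len(n_g))
  geno <- geno_matrix(d0, rep("chr1", 150), seq(1, by = 5000, length.out = 150))
  cfg <- sim_config(n_genotypes = n_g, n_snps = 150, n_asvs = 80,
                    n_groups = 8, n_classes = 4, n_causal_asvs = 0,
                    n_mediators = 0, n_heritable_asvs = 0,
                    plot_missing_rate = 0, seed = 81)
  des <- simulate_design(cfg)
  mic <- simulate_microbiome(geno, des, cfg)$microbiome
  gi <- match(as.character(des$genotype), rownames(d0))
  vals <- mic$values + 1.5 * pop[gi]  # structure drives all ASVs
  mic2 <- microbiome_table(vals, mic$taxonomy)
  y <- 2 * pop[gi] + rnorm(nrow(des), 0, 1)  # structure drives the phenotype
  dat <- megs_data(geno, des, mic2, setNames(y, des$plot_id))
  with_pcs <- mediation_scan(dat$y, dat$design, dat$pcs, dat$Z, mic2,
                             n_perm = 199, seed = 82)
  no_pcs <- mediation_scan(dat$y, dat$design, NULL, dat$Z, mic2,
                           n_perm = 199, seed = 82)
  # no true mediators exist; the PC-adjusted scan stays (near) clean while
  # the unadjusted scan lights up
  expect_gt(sum(no_pcs$p_joint < 0.05), sum(with_pcs$p_joint < 0.05))
  expect_lt(sum(with_pcs$mediator), sum(no_pcs$mediator) + 1)
})
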