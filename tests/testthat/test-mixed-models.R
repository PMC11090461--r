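test_that("REML with zero true variance lands at the boundary and matches OLS", {
  set.seed(40)
  n <- 120
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  Z <- matrix(rbinom(n * 50, 2, 0.3), n, 50)
  Z <- scale(Z, scale = FALSE)
  y <- drop(X %*% c(2, 0.5)) + rnorm(n)
  fit <- reml_single_component(y, X, Z = Z)
  expect_true(fit$meta$boundary)
  expect_lt(fit$varcomp[["sigma2_u"]] * mean(diag(tcrossprod(Z))),
            0.01 * fit$varcomp[["sigma2_e"]])
  ols <- coef(lm(y ~ 0 + X))
  expect_equal(unname(fit$fixed), unname(ols), tolerance = 1e-3)
})

test_that("REML matches lme4 on a grouped random-intercept model", {
  skip_if_not_installed("lme4")
  set.seed(41)
  g <- gl(40, 5)
  Zg <- model.matrix(~ g - 1)
  y <- rnorm(200) + rep(rnorm(40, 0, 1.2), each = 5) + 3
  fit <- reml_single_component(y, matrix(1, 200, 1,
                                         dimnames = list(NULL, "(Intercept)")),
                               Z = Zg)
  lf <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$varcomp[["sigma2_u"]], vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$varcomp[["sigma2_e"]], vc$vcov[2], tolerance = 1e-5)
  expect_equal(unname(fit$fixed), unname(lme4::fixef(lf)), tolerance = 1e-6)
})

test_that("REML profile is a bracketed local maximum at the optimum", {
  set.seed(42)
  n <- 100
  Z <- scale(matrix(rbinom(n * 80, 2, 0.4), n, 80), scale = FALSE)
  u <- rnorm(80, 0, 0.1)
  y <- 1 + drop(Z %*% u) + rnorm(n)
  fit <- reml_single_component(y, matrix(1, n, 1, dimnames = list(NULL, "mu")),
                               Z = Z)
  prof <- fit$meta$reml_profile
  lt <- fit$meta$log_theta
  ll_opt <- prof(lt)
  expect_gte(ll_opt, prof(lt - 0.05))
  expect_gte(ll_opt, prof(lt + 0.05))
  # profile increases towards the optimum from both ends of the bracket
  grid_left <- vapply(seq(-10, lt, length.out = 8), prof, numeric(1))
  grid_right <- vapply(seq(lt, 10, length.out = 8), prof, numeric(1))
  expect_true(all(diff(grid_left) > -1e-6))
  expect_true(all(diff(grid_right) < 1e-6))
})

test_that("rank-deficient fixed effects are reduced with an aliasing report", {
  set.seed(43)
  n <- 60
  X <- cbind(`(Intercept)` = 1, a = rnorm(n))
  X <- cbind(X, dup = X[, "a"])
  Z <- scale(matrix(rbinom(n * 30, 2, 0.3), n, 30), scale = FALSE)
  y <- rnorm(n)
  fit <- reml_single_component(y, X, Z = Z)
  expect_identical(fit$meta$aliased, "dup")
  expect_error(reml_single_component(c(y[-1], NA), X, Z = Z), "finite")
})

test_that("two-component MME equals generalized ridge on random instances", {
  set.seed(44)
  for (rep in 1:5) {
    n <- sample(30:80, 1)
    p <- sample(20:60, 1); q <- sample(10:40, 1)
    X <- cbind(`(Intercept)` = 1, x = rnorm(n))
    Z <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("s", 1:p)))
    M <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("a", 1:q)))
    va <- runif(1, 0.05, 2); vg <- runif(1, 0.05, 2); ve <- runif(1, 0.2, 2)
    y <- rnorm(n)
    fk <- fit_two_component(y, X, Z, M, va, vg, ve, method = "kernel")
    fc <- fit_two_component(y, X, Z, M, va, vg, ve, method = "columns")
    expect_equal(fk$fixed, fc$fixed, tolerance = 1e-8)
    expect_equal(fk$random$alpha, fc$random$alpha, tolerance = 1e-8)
    expect_equal(fk$random$gamma, fc$random$gamma, tolerance = 1e-8)
    # direct penalty-rescaled ridge oracle
    W <- cbind(X, Z * sqrt(va), M * sqrt(vg))
    sol <- solve(crossprod(W) + diag(c(0, 0, rep(ve, p + q))), crossprod(W, y))
    expect_equal(unname(fk$random$alpha), unname(sol[2 + (1:p)]) * sqrt(va),
                 tolerance = 1e-8)
    expect_equal(unname(fk$random$gamma),
                 unname(sol[2 + p + (1:q)]) * sqrt(vg), tolerance = 1e-8)
  }
})

test_that("shrinking the ASV variance collapses the joint fit to SNP-only", {
  set.seed(45)
  n <- 80
  X <- cbind(`(Intercept)` = 1)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Z <- scale(matrix(rbinom(n * 60, 2, 0.4), n, 60), scale = FALSE)
  colnames(Z) <- paste0("s", 1:60)
  M <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("a", 1:20)))
  y <- 1 + drop(Z %*% rnorm(60, 0, 0.2)) + rnorm(n)
  base <- fit_two_component(y, X, Z, NULL, 0.05, 0, 1)
  prev <- Inf
  for (vg in 0.05 * c(1e-2, 1e-4, 1e-6)) {
    f <- fit_two_component(y, X, Z, M, 0.05, vg, 1)
    dmax <- max(abs(f$meta$fitted - base$meta$fitted))
    expect_lt(dmax, prev + 1e-12)
    prev <- dmax
  }
  expect_lt(prev, 1e-4)
})

test_that("permuting marker columns permutes effects and leaves predictions fixed", {
  set.seed(46)
  n <- 60
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Z <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, paste0("s", 1:40)))
  y <- rnorm(n)
  f1 <- fit_two_component(y, X, Z, NULL, 0.3, 0, 1)
  perm <- sample(40)
  f2 <- fit_two_component(y, X, Z[, perm], NULL, 0.3, 0, 1)
  expect_equal(unname(f2$random$alpha), unname(f1$random$alpha[perm]),
               tolerance = 1e-10)
  expect_equal(f1$meta$fitted, f2$meta$fitted, tolerance = 1e-10)
})

test_that("plug-in MEGS fit recovers planted variance structure directions", {
  b <- demo_bundle(seed = 47)
  d <- b$data
  Mc <- sweep(d$microbiome$values, 2, colMeans(d$microbiome$values))
  fit <- fit_megs(d$y, d$design, d$Z, Mc, d$pcs)
  expect_true(all(fit$varcomp >= 0))
  expect_gt(fit$varcomp[["sigma2_e"]], 0)
  expect_gt(cor(fit$meta$fitted, d$y), 0.8)
  # SNP-only reduction
  f0 <- fit_megs(d$y, d$design, d$Z, include_asv = FALSE)
  expect_length(f0$random$gamma, 0)
})

test_that("ASV-only REML recovers the planted microbial variance share", {
  shares <- vapply(1:4, function(s) {
    cfg <- sim_config(n_genotypes = 100, n_snps = 200, n_asvs = 80,
                      n_groups = 8, n_classes = 4, n_causal_asvs = 20,
                      n_mediators = 5, n_heritable_asvs = 10,
                      h2_snp = 0.4, var_share_asv = 0.2,
                      plot_missing_rate = 0.05, seed = 400 + s)
    holo <- simulate_hologenome(cfg)
    d <- megs_data(holo$geno, holo$design, holo$microbiome, holo$phenotype)
    Mc <- sweep(d$microbiome$values, 2, colMeans(d$microbiome$values))
    f <- estimate_asv_variance(d$y, d$design, d$pcs, Mc)
    # implied phenotypic variance of the ASV component, as a share of var(y)
    f$varcomp[["sigma2_u"]] * mean(diag(tcrossprod(Mc))) / var(d$y)
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.2), 0.05)

  # microbiome-independent phenotype: the share collapses to ~0
  cfg0 <- sim_config(n_genotypes = 100, n_snps = 200, n_asvs = 80,
                     n_groups = 8, n_classes = 4, n_causal_asvs = 0,
                     n_mediators = 0, n_heritable_asvs = 0,
                     h2_snp = 0.4, var_share_asv = 0,
                     plot_missing_rate = 0.05, seed = 499)
  holo0 <- simulate_hologenome(cfg0)
  d0 <- megs_data(holo0$geno, holo0$design, holo0$microbiome, holo0$phenotype)
  Mc0 <- sweep(d0$microbiome$values, 2, colMeans(d0$microbiome$values))
  f0 <- estimate_asv_variance(d0$y, d0$design, d0$pcs, Mc0)
  expect_lt(f0$varcomp[["sigma2_u"]] * mean(diag(tcrossprod(Mc0))) / var(d0$y),
            0.01)
})

test_that("unseen factor levels fall back to the reference with a warning", {
  b <- demo_bundle(seed = 52)
  d <- b$data
  fit <- fit_megs(d$y, d$design, d$Z, include_asv = FALSE)
  new_design <- d$design[1:4, ]
  levels(new_design$block) <- c(levels(new_design$block), "B9")
  new_design$block[1] <- "B9"
  expect_warning(
    pred <- predict(fit, design = new_design, Z = d$Z[1:4, , drop = FALSE]),
    "unseen")
  ref_design <- d$design[1:4, ]
  ref_design$block[1] <- levels(d$design$block)[1]
  pred_ref <- predict(fit, design = ref_design, Z = d$Z[1:4, , drop = FALSE])
  expect_equal(pred, pred_ref, tolerance = 1e-12)
})

test_that("GBLUP with identity A reduces to scalar shrinkage of residuals", {
  set.seed(48)
  n_g <- 50
  des <- toy_design(paste0("G", 1:n_g))
  gvals <- rnorm(n_g, 0, 1)
  y <- 2 + gvals + rnorm(n_g, 0, 0.5)
  A <- diag(n_g)
  dimnames(A) <- list(paste0("G", 1:n_g), paste0("G", 1:n_g))
  grm <- structure(list(matrix = A, individual_ids = paste0("G", 1:n_g)),
                   class = "grm")
  fit <- fit_gblup_genotype(y, des, grm)
  sg <- fit$varcomp[["sigma2_g"]]; se <- fit$varcomp[["sigma2_e"]]
  shrink <- sg / (sg + se)
  resid <- y - mean(fit$meta$kept == "(Intercept)") * fit$fixed[["(Intercept)"]]
  resid <- y - fit$fixed[["(Intercept)"]]
  expect_equal(unname(fit$random$g[as.character(des$genotype)]),
               unname(shrink * resid), tolerance = 1e-6)
})

test_that("duplicated-genotype rows receive equal BLUPs", {
  set.seed(49)
  n_g <- 30
  genos <- rep(paste0("G", 1:n_g), each = 2)
  des <- toy_design(genos, block = rep(c("B1", "B2"), n_g))
  ids <- paste0("G", 1:n_g)
  W <- matrix(rnorm(n_g * 100), n_g, 100)
  A <- tcrossprod(scale(W, scale = FALSE)) / 100
  dimnames(A) <- list(ids, ids)
  grm <- structure(list(matrix = A, individual_ids = ids), class = "grm")
  y <- rnorm(length(genos)) + rep(rnorm(n_g), each = 2)
  fit <- fit_gblup_genotype(y, des, grm)
  blup_by_row <- fit$random$g[genos]
  expect_equal(blup_by_row[seq(1, 59, 2)], blup_by_row[seq(2, 60, 2)],
               tolerance = 1e-12, ignore_attr = TRUE)
  # unknown genotype rejected
  des_bad <- des; levels(des_bad$genotype)[1] <- "GX"
  expect_error(fit_gblup_genotype(y, des_bad, grm), "GX")
})

test_that("predictions reproduce training fits and are shift-equivariant", {
  b <- demo_bundle(seed = 50)
  d <- b$data
  Mc <- sweep(d$microbiome$values, 2, colMeans(d$microbiome$values))
  fit <- fit_megs(d$y, d$design, d$Z, Mc, d$pcs)
  pred <- predict(fit, design = d$design, Z = d$Z, M = Mc)
  expect_equal(pred, fit$meta$fitted, tolerance = 1e-10)
  fit2 <- fit_megs(d$y + 5, d$design, d$Z, Mc, d$pcs)
  pred2 <- predict(fit2, design = d$design, Z = d$Z, M = Mc)
  expect_equal(pred2, pred + 5, tolerance = 1e-6)
})

test_that("held-out predictions equal the closed-form ridge oracle", {
  set.seed(51)
  n <- 70; p <- 50; q <- 15
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  Z <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("s", 1:p)))
  M <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("a", 1:q)))
  y <- rnorm(n)
  tr <- 1:50; te <- 51:70
  va <- 0.4; vg <- 0.6; ve <- 1.2
  fit <- fit_two_component(y[tr], X[tr, ], Z[tr, ], M[tr, ], va, vg, ve)
  pred <- predict(fit, X = X[te, ], Z = Z[te, ], M = M[te, ])
  W <- cbind(X[tr, ], Z[tr, ] * sqrt(va), M[tr, ] * sqrt(vg))
  sol <- solve(crossprod(W) + diag(c(0, 0, rep(ve, p + q))),
               crossprod(W, y[tr]))
  oracle <- drop(cbind(X[te, ], Z[te, ] * sqrt(va), M[te, ] * sqrt(vg)) %*% sol)
  expect_equal(pred, oracle, tolerance = 1e-8)
})
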