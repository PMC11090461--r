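#' Confounder matrix for the mediation models
#'
#' Column-binds an intercept, the first genotype principal components and
#' reference-coded dummies for nitrogen treatment, block, split plot and
#' split-plot block. With the default field layout (3 PCs; 2/2/4/3 factor
#' levels) this yields 11 model columns. The matrix is reduced to full
#' column rank if the coding introduces aliasing, with the dropped columns
#' recorded in the `aliased` attribute.
#'
#' @param design plot design table.
#' @param pcs genotype PC scores (individuals x s) or `NULL` to use the
#'   design factors only.
#' @return numeric matrix `Q` (observations x columns).
#' @export
build_confounder_matrix <- function(design, pcs = NULL) {
  check_design(design)
  X <- fixed_effects_matrix(design)
  if (!is.null(pcs)) {
    pc <- pcs[match(as.character(design$genotype), rownames(pcs)), ,
              drop = FALSE]
    assert_that(!anyNA(pc), "PC scores missing for some design genotypes")
    Q <- cbind(X[, 1, drop = FALSE], pc, X[, -1, drop = FALSE])
  } else {
    Q <- X
  }
  fr <- full_rank_basis(Q)
  out <- fr$X
  attr(out, "aliased") <- fr$dropped
  attr(out, "xlev") <- attr(X, "xlev")
  out
}

## Shared machinery of the per-ASV genetic-path test: residualize the ASV
## matrix on the confounders and compare the kernel quadratic-form score
## against genotype label permutations. Two subtleties keep the test exactly
## symmetric between observed and permuted draws:
## * the kernel depends on plots only through their genotype, so
##   r' K r = rg' K_geno rg with rg the per-genotype residual sums, and the
##   permutation loop runs at genotype scale;
## * the PC confounders are themselves functions of the genotypes, so under
##   a genotype-label permutation the PC columns are permuted together with
##   the kernel before residualization.
genetic_path_test <- function(M, Q_design, pcs_geno, K_geno, geno_index,
                              n_perm, seed) {
  base_resid <- function(A)
    A - Q_design %*% solve(crossprod(Q_design), crossprod(Q_design, A))
  R0 <- base_resid(M)
  n_geno <- nrow(K_geno)
  stat_for <- function(pg) {
    R <- R0
    if (!is.null(pcs_geno)) {
      Pb <- base_resid(pcs_geno[pg[geno_index], , drop = FALSE])
      R <- R0 - Pb %*% solve(crossprod(Pb), crossprod(Pb, R0))
    }
    Rg <- rowsum(R, geno_index)          # n_geno x p (rows ordered 1..n_geno)
    colSums(Rg * (K_geno[pg, pg] %*% Rg)) / colSums(R^2)
  }
  s_obs <- stat_for(seq_len(n_geno))
  set.seed(seed)
  exceed <- integer(ncol(M))
  for (b in seq_len(n_perm)) {
    s_b <- stat_for(sample.int(n_geno))
    exceed <- exceed + (s_b >= s_obs)
  }
  list(stat = s_obs, p = (1 + exceed) / (n_perm + 1))
}

#' Mediator model for one ASV
#'
#' Fits `M_j = Q A_j + Z B_j + e_j` with `A_j` by GLS, `B_j` as ridge-shrunk
#' random SNP coefficients (single-component REML), and tests the genetic
#' path `H0: Var(Z B_j) = 0` with a kernel score statistic calibrated by
#' permutation of genotype labels.
#'
#' @param M_j numeric vector of one ASV's log abundance (plot level).
#' @param design plot design table (defines confounders and the genotype
#'   label permutation).
#' @param pcs genotype PC scores (individuals x s) or `NULL`.
#' @param Z plot-level centered SNP matrix.
#' @param n_perm permutations for the path test (>= 200 recommended).
#' @param seed integer seed.
#' @return list: `A_j` (GLS confounder coefficients), `B_j` (SNP BLUPs),
#'   `sigma2_j` (residual variance), `genetic_share` (genotype-attributable
#'   variance fraction), `p_genetic`.
#' @export
fit_mediator_model <- function(M_j, design, pcs, Z, n_perm = 200, seed = 1L) {
  assert_that(sd(M_j) > 0, "constant ASV abundance; mediator model undefined")
  check_design(design)
  Q <- build_confounder_matrix(design, pcs)
  fit <- reml_single_component(M_j, Q, Z = Z)
  share <- fit$varcomp[["sigma2_u"]] * fit$meta$kernel_scale /
    (fit$varcomp[["sigma2_u"]] * fit$meta$kernel_scale +
       fit$varcomp[["sigma2_e"]])
  genotype <- as.character(design$genotype)
  gi <- as.integer(factor(genotype, levels = unique(genotype)))
  first <- match(unique(genotype), genotype)
  K_geno <- tcrossprod(Z[first, , drop = FALSE])
  K_geno <- K_geno / mean(diag(K_geno))
  pcs_geno <- if (!is.null(pcs))
    pcs[match(unique(genotype), rownames(pcs)), , drop = FALSE]
  Qd <- build_confounder_matrix(design, NULL)
  gt <- genetic_path_test(cbind(M_j), Qd, pcs_geno, K_geno, gi, n_perm, seed)
  list(A_j = fit$fixed, B_j = fit$random$u,
       sigma2_j = fit$varcomp[["sigma2_e"]],
       genetic_share = unname(share), p_genetic = unname(gt$p))
}

#' Outcome model with SNPs and microbe mediators
#'
#' Fits `y = Q v + Z a + M c + e` with `a` and `c` as ridge-shrunk random
#' components whose variances are plugged in from single-component fits
#' (SNP-only and ASV-only, each with `Q` fixed), mirroring the plug-in
#' scheme of the prediction model. Per-ASV phenotype-path significance for
#' `c_j` is a score-type permutation test: the path statistic is the ridge
#' coefficient evaluated at the null (no-mediator) variance structure,
#' `|M_j' V0^-1 (y - Q v0)|` with `V0` from the SNP-only fit, and the
#' microbiome rows are permuted within nitrogen treatment (jointly across
#' ASVs, preserving their correlation) with the weight vector frozen.
#' Evaluating the score under the null model is the standard score-test
#' construction, keeps each permutation an `O(n p)` cross product (so
#' permutation counts large enough to resolve genome-wide FDR thresholds
#' stay cheap), and its calibration is verified by null simulation in the
#' test suite. The reported `c` estimates remain the joint-fit BLUPs.
#'
#' @param y phenotype vector.
#' @param Q confounder matrix.
#' @param Z plot-level centered SNP matrix.
#' @param M plot-level centered ASV matrix.
#' @param treatment treatment factor per plot (permutation stratum).
#' @param n_perm permutations (>= 200 recommended).
#' @param seed integer seed.
#' @return list: `v`, `a`, `c`, `sigma2`, `p_phenotype` (per ASV),
#'   `plugin` variances.
#' @export
fit_outcome_model <- function(y, Q, Z, M, treatment, n_perm = 200, seed = 1L) {
  n <- length(y)
  snp_fit <- reml_single_component(y, Q, Z = Z)
  var_a <- snp_fit$varcomp[["sigma2_u"]]
  var_e <- snp_fit$varcomp[["sigma2_e"]]
  asv_fit <- reml_single_component(y, Q, Z = M)
  var_c <- asv_fit$varcomp[["sigma2_u"]]
  joint <- fit_two_component(y, Q, Z_snp = Z, M_asv = M,
                             var_snp = var_a, var_asv = var_c, var_e = var_e,
                             method = "kernel")
  ## a boundary (exactly zero) variance collapses that component in the
  ## joint fit; report zero coefficients for it
  c_obs <- joint$random$gamma
  if (!length(c_obs)) c_obs <- setNames(rep(0, ncol(M)), colnames(M))
  a_obs <- joint$random$alpha
  if (!length(a_obs)) a_obs <- setNames(rep(0, ncol(Z)), colnames(Z))
  ## score-form path statistic: per-ASV ridge coefficient evaluated at the
  ## null (no-mediator) variance structure, |M_j' V0^-1 (y - Q v0)|, with
  ## V0 from the SNP-only fit. The weights are frozen across permutations,
  ## and the statistic is defined whether or not the joint fit retained the
  ## ASV component.
  V0 <- diag(var_e, n) + var_a * tcrossprod(Z)
  Qr <- full_rank_basis(Q)$X
  u0 <- drop(chol_solve(V0, y - drop(Qr %*% snp_fit$fixed)))
  s_obs <- abs(drop(crossprod(M, u0)))
  set.seed(seed)
  strata <- as.character(treatment)
  exceed <- integer(length(c_obs))
  for (b in seq_len(n_perm)) {
    pb <- seq_len(n)
    for (tr in unique(strata)) {
      rows <- which(strata == tr)
      if (length(rows) > 1L) pb[rows] <- rows[sample.int(length(rows))]
    }
    s_b <- abs(drop(crossprod(M[pb, , drop = FALSE], u0)))
    exceed <- exceed + (s_b >= s_obs)
  }
  list(v = joint$fixed, a = a_obs, c = c_obs,
       sigma2 = var_e,
       p_phenotype = setNames((1 + exceed) / (n_perm + 1), names(c_obs)),
       plugin = c(sigma2_a = var_a, sigma2_c = var_c, sigma2_e = var_e))
}

#' Genome-wide mediation scan over all ASVs
#'
#' Treats every ASV as a candidate intermediate on the path genotype ->
#' microbe -> phenotype. The genetic path is tested per ASV by the
#' permutation-calibrated kernel score of the mediator model; the phenotype
#' path by the permutation test on the outcome-model ridge coefficients. An
#' ASV's joint p-value is the larger of the two (joint-significance / MaxP
#' rule: both paths must be individually significant), adjusted by
#' Benjamini-Hochberg; mediators are the ASVs with `q <= fdr`.
#'
#' @param y phenotype vector aligned with `design`.
#' @param design plot design table.
#' @param pcs genotype PC scores (individuals x s).
#' @param Z plot-level centered SNP matrix.
#' @param micro a [microbiome_table()] (or plain matrix of log abundances).
#' @param fdr false discovery rate for the mediator call (default 0.05).
#' @param n_perm permutations per path test (default 200).
#' @param seed integer seed.
#' @return data.frame of class `mediation_result`, one row per ASV:
#'   asv_id, group, class, genetic_share, p_genetic, c_estimate,
#'   p_phenotype, p_joint, q_value, mediator.
#' @export
mediation_scan <- function(y, design, pcs, Z, micro, fdr = 0.05,
                           n_perm = 200, seed = 1L) {
  check_design(design)
  M_raw <- if (inherits(micro, "microbiome_table")) micro$values else micro
  taxonomy <- if (inherits(micro, "microbiome_table")) micro$taxonomy else
    data.frame(asv_id = colnames(M_raw), group = NA_character_,
               class = NA_character_, stringsAsFactors = FALSE)
  assert_that(length(y) == nrow(design) && nrow(M_raw) == nrow(design),
              "y, design and microbiome must be row-aligned")
  Q <- build_confounder_matrix(design, pcs)
  Mc <- sweep(M_raw, 2L, colMeans(M_raw), "-")

  ok <- apply(Mc, 2L, sd) > 0
  status <- ifelse(ok, "ok", "constant")

  genotype <- as.character(design$genotype)
  gi <- as.integer(factor(genotype, levels = unique(genotype)))
  first <- match(unique(genotype), genotype)
  K_geno <- tcrossprod(Z[first, , drop = FALSE])
  K_geno <- K_geno / mean(diag(K_geno))
  seeds <- derive_seeds(seed, 2L)

  ## genetic path: shared eigenbasis REML (variance share) + permutation p
  p_gen <- share <- rep(NA_real_, ncol(Mc))
  Qd <- build_confounder_matrix(design, NULL)
  pcs_geno <- if (!is.null(pcs))
    pcs[match(unique(genotype), rownames(pcs)), , drop = FALSE]
  gt <- genetic_path_test(Mc[, ok, drop = FALSE], Qd, pcs_geno, K_geno, gi,
                          n_perm, seeds[1])
  p_gen[ok] <- gt$p
  share[ok] <- batch_genetic_share(Mc[, ok, drop = FALSE], Q,
                                   K_geno[gi, gi])

  ## phenotype path
  out <- fit_outcome_model(y, Q, Z, Mc[, ok, drop = FALSE],
                           treatment = design$treatment,
                           n_perm = n_perm, seed = seeds[2])
  c_est <- p_phe <- rep(NA_real_, ncol(Mc))
  c_est[ok] <- out$c
  p_phe[ok] <- out$p_phenotype

  p_joint <- pmax(p_gen, p_phe)
  q <- rep(NA_real_, length(p_joint))
  q[ok] <- p.adjust(p_joint[ok], method = "BH")
  res <- data.frame(asv_id = colnames(M_raw),
                    group = taxonomy$group[match(colnames(M_raw), taxonomy$asv_id)],
                    class = taxonomy$class[match(colnames(M_raw), taxonomy$asv_id)],
                    genetic_share = share, p_genetic = p_gen,
                    c_estimate = c_est, p_phenotype = p_phe,
                    p_joint = p_joint, q_value = q,
                    mediator = !is.na(q) & q <= fdr,
                    status = status, stringsAsFactors = FALSE)
  res <- res[order(res$p_joint, res$asv_id), ]
  rownames(res) <- NULL
  class(res) <- c("mediation_result", "data.frame")
  attr(res, "fdr") <- fdr
  attr(res, "n_perm") <- n_perm
  res
}

## REML genotype-attributable variance share for every ASV, using one
## eigendecomposition of the projected kernel shared across ASVs.
batch_genetic_share <- function(M, Q, K_plot) {
  n <- nrow(M)
  fr <- full_rank_basis(Q)
  q <- ncol(fr$X)
  Tb <- qr.Q(qr(fr$X), complete = TRUE)[, (q + 1L):n, drop = FALSE]
  Kn <- K_plot / mean(diag(K_plot))
  eg <- eigen(crossprod(Tb, Kn %*% Tb), symmetric = TRUE)
  xi <- pmax(eg$values, 0)
  Eta <- crossprod(eg$vectors, crossprod(Tb, M))
  nq <- n - q
  vapply(seq_len(ncol(M)), function(j) {
    eta2 <- Eta[, j]^2
    nll <- function(lt) {
      d <- exp(lt) * xi + 1
      s2e <- sum(eta2 / d) / nq
      0.5 * (nq * log(2 * pi * s2e) + sum(log(d)) + nq)
    }
    lt <- optimize(nll, c(-10, 10), tol = 1e-8)$minimum
    th <- exp(lt)
    th / (th + 1)
  }, numeric(1))
}
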