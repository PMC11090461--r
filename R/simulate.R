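#' Simulation configuration for the synthetic hologenome generator
#'
#' Assembles and validates the parameters of the genotype -> microbiome ->
#' phenotype generator. Defaults describe the emulated field study: 230 maize
#' genotypes grown under 2 nitrogen treatments x 2 blocks with 4 split plots
#' and 3 split-plot blocks, roughly 13.6% of plots lost (so ~795 of 920
#' remain), and 3,626 ASVs clustered into 154 taxonomic groups spanning 19
#' classes. Variance shares not dictated by the emulated study are fixed at
#' values realistic for a heritable vegetation-index trait.
#'
#' @param n_genotypes number of host genotypes.
#' @param n_snps number of bi-allelic markers.
#' @param n_asvs number of ASVs.
#' @param maf_range length-2 numeric in (0, 0.5]; population minor-allele
#'   frequencies are drawn uniformly from this interval.
#' @param ld_block_size number of adjacent markers per LD block (latent
#'   Gaussian copula, within-block correlation `ld_rho`).
#' @param ld_rho within-block latent correlation.
#' @param n_chrom number of synthetic chromosomes.
#' @param n_treatments,n_blocks,n_splitplots,n_splitplotblocks design
#'   cardinalities (defaults 2/2/4/3).
#' @param plot_missing_rate i.i.d. Bernoulli probability that a plot is lost.
#' @param h2_snp fraction of phenotypic variance from additive SNP effects.
#' @param var_share_asv fraction of phenotypic variance from ASV effects.
#' @param n_causal_asvs number of ASVs with nonzero phenotype effects.
#' @param n_mediators number of planted mediators (nonzero genetic path AND
#'   phenotype path); must not exceed `n_causal_asvs`.
#' @param n_heritable_asvs number of ASVs with a nonzero genetic path
#'   (mediators plus genetic-path-only ASVs); default covers the mediators
#'   plus an equal number of genetic-only ASVs.
#' @param asv_h2 fraction of log-abundance variance attributable to host
#'   genotype for heritable ASVs, in [0, 1).
#' @param n_qtl_per_asv SNPs with nonzero effect per heritable ASV.
#' @param gamma_magnitude `NULL` (default) draws causal-ASV phenotype
#'   effects from N(0, 1); a positive number plants effects of that fixed
#'   magnitude with random signs (equal-effect design for power studies).
#' @param treatment_specific if `TRUE`, ASV phenotype effects act only in the
#'   low-nitrogen treatment (the LN-dominant scenario).
#' @param n_groups,n_classes taxonomy cardinalities (groups nest in classes).
#' @param seed master seed; every stage derives its own stream from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 230, n_snps = 50000, n_asvs = 3626,
                       maf_range = c(0.05, 0.5), ld_block_size = 10,
                       ld_rho = 0.9, n_chrom = 10,
                       n_treatments = 2, n_blocks = 2, n_splitplots = 4,
                       n_splitplotblocks = 3,
                       plot_missing_rate = 1 - 795 / 920,
                       h2_snp = 0.5, var_share_asv = 0.1,
                       n_causal_asvs = 50, n_mediators = 10,
                       n_heritable_asvs = NULL,
                       asv_h2 = 0.3, n_qtl_per_asv = 5,
                       gamma_magnitude = NULL,
                       treatment_specific = FALSE,
                       n_groups = 154, n_classes = 19, seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_heritable_asvs <- n_heritable_asvs %||%
    min(n_asvs, 2L * n_mediators)
  assert_that(n_genotypes >= 2 && n_snps >= 1 && n_asvs >= 1,
              "n_genotypes >= 2, n_snps >= 1 and n_asvs >= 1 required")
  assert_that(length(maf_range) == 2 && maf_range[1] <= maf_range[2] &&
                maf_range[1] > 0 && maf_range[2] <= 0.5,
              "maf_range must lie within (0, 0.5]")
  assert_that(plot_missing_rate >= 0 && plot_missing_rate < 1,
              "plot_missing_rate must be in [0, 1)")
  assert_that(h2_snp >= 0 && var_share_asv >= 0 &&
                h2_snp + var_share_asv < 1,
              "h2_snp + var_share_asv must be < 1 (residual variance > 0)")
  assert_that(n_mediators <= n_causal_asvs && n_causal_asvs <= n_asvs,
              "need n_mediators <= n_causal_asvs <= n_asvs")
  assert_that(cfg$n_heritable_asvs >= n_mediators &&
                cfg$n_heritable_asvs <= n_asvs,
              "need n_mediators <= n_heritable_asvs <= n_asvs")
  assert_that(asv_h2 >= 0 && asv_h2 < 1, "asv_h2 must be in [0, 1)")
  assert_that(n_groups >= n_classes, "groups must be at least as many as classes")
  class(cfg) <- "sim_config"
  cfg
}

#' Reduced-scale demonstration preset
#'
#' A small configuration (100 genotypes, 2,000 SNPs, 500 ASVs) used by the
#' worked examples and drivers; overridable through `...`.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_demo <- function(...) {
  args <- list(n_genotypes = 100, n_snps = 2000, n_asvs = 500,
               n_groups = 25, n_classes = 8,
               n_causal_asvs = 25, n_mediators = 10,
               plot_missing_rate = 0.1)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Simulate genotypes with block LD
#'
#' Draws per-marker population minor-allele frequencies uniformly from
#' `maf_range`, then generates two gametes per individual from a latent
#' Gaussian copula: markers within an LD block share an exchangeable latent
#' correlation (`ld_rho`), blocks are independent. Thresholding the latent
#' variable at the allele-frequency quantile yields allele indicators whose
#' sum is the dosage. Markers are laid on a synthetic coordinate grid:
#' within-block spacing 100 bp, a 20 kb gap between blocks, `n_chrom`
#' chromosomes of equal marker count.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return a [geno_matrix()].
#' @export
simulate_genotypes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seeds(seed %||% config$seed, 1L))
  n <- config$n_genotypes; m <- config$n_snps
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  L <- max(1L, as.integer(config$ld_block_size))
  block <- rep(seq_len(ceiling(m / L)), each = L)[seq_len(m)]
  rho <- if (L > 1L) config$ld_rho else 0
  thr <- qnorm(maf, lower.tail = FALSE)  # latent > thr => minor allele
  dos <- matrix(0L, n, m)
  for (gam in 1:2) {
    zs <- matrix(rnorm(n * max(block)), n, max(block))[, block, drop = FALSE]
    zi <- matrix(rnorm(n * m), n, m)
    z <- sqrt(rho) * zs + sqrt(1 - rho) * zi
    dos <- dos + (z > matrix(thr, n, m, byrow = TRUE))
  }
  storage.mode(dos) <- "double"
  rownames(dos) <- sprintf("G%03d", seq_len(n))
  colnames(dos) <- sprintf("snp%06d", seq_len(m))
  per_chr <- ceiling(m / config$n_chrom)
  chr_idx <- rep(seq_len(config$n_chrom), each = per_chr)[seq_len(m)]
  pos <- integer(m)
  for (cc in unique(chr_idx)) {
    sel <- chr_idx == cc
    b <- block[sel]; b <- b - b[1] + 1L
    within <- sequence(rle(b)$lengths) - 1L
    pos[sel] <- 1L + (b - 1L) * 20000L + within * 100L
  }
  geno_matrix(dos, chrom = paste0("chr", chr_idx), pos = pos)
}

#' Simulate the split-plot field design
#'
#' One plot per genotype per (treatment x block) before dropout. Within each
#' (treatment, block) cell, genotypes are randomized to a linear field order;
#' split plots cut that order into `n_splitplots` contiguous chunks and
#' split-plot blocks cut each split plot into `n_splitplotblocks` chunks
#' (spatial nesting). The quadrant label is the (block x split plot) cell.
#' Plots are then dropped i.i.d. at `plot_missing_rate`.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return a data.frame with columns plot_id, genotype, treatment, block,
#'   splitplot, splitplotblock, quadrant (factors except plot_id).
#' @export
simulate_design <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seeds(seed %||% config$seed, 2L)[2])
  n <- config$n_genotypes
  treatments <- c("HN", "LN")[seq_len(config$n_treatments)]
  blocks <- paste0("B", seq_len(config$n_blocks))
  rows <- list(); k <- 0L
  for (tr in treatments) for (bl in blocks) {
    ord <- sample(rownames_for_genotypes(n))
    idx <- seq_len(n)
    sp <- ceiling(idx * config$n_splitplots / n)
    spb <- integer(n)
    for (u in unique(sp)) {
      j <- which(sp == u)
      spb[j] <- ceiling(seq_along(j) * config$n_splitplotblocks / length(j))
    }
    k <- k + 1L
    rows[[k]] <- data.frame(genotype = ord, treatment = tr, block = bl,
                            splitplot = paste0("SP", sp),
                            splitplotblock = paste0("SPB", spb),
                            stringsAsFactors = FALSE)
  }
  des <- do.call(rbind, rows)
  des$quadrant <- paste(des$block, des$splitplot, sep = ":")
  keep <- runif(nrow(des)) >= config$plot_missing_rate
  des <- des[keep, , drop = FALSE]
  des$plot_id <- sprintf("P%04d", seq_len(nrow(des)))
  for (v in c("genotype", design_factor_cols, "quadrant"))
    des[[v]] <- factor(des[[v]])
  rownames(des) <- NULL
  check_design(des[c("plot_id", "genotype", design_factor_cols, "quadrant")])
}

rownames_for_genotypes <- function(n) sprintf("G%03d", seq_len(n))

#' Simulate ASV log abundances over the field design
#'
#' Each ASV's plot-level log relative abundance is an intercept plus
#' treatment, block and split-plot microenvironment effects, a genetic
#' component `Z B_j` for heritable ASVs (a sparse set of SNP effects, scaled
#' so the genotype-attributable variance fraction equals `asv_h2`), and
#' i.i.d. noise. Abundances are generated directly on the log scale.
#' Mediator ASVs are a subset of the heritable set; their phenotype path is
#' planted later by [simulate_phenotype()].
#'
#' @param geno a [geno_matrix()] containing every genotype in `design`.
#' @param design a design table from [simulate_design()].
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list with `microbiome` (a [microbiome_table()]) and `truth`
#'   (partial truth bundle: true_B, heritable_ids, mediator_ids, taxonomy).
#' @export
simulate_microbiome <- function(geno, design, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_design(design)
  assert_that(all(as.character(design$genotype) %in% rownames(geno$dosages)),
              "design references genotypes absent from the genotype matrix")
  set.seed(derive_seeds(seed %||% config$seed, 3L)[3])
  n_obs <- nrow(design); p <- config$n_asvs
  asv_ids <- sprintf("asv%05d", seq_len(p))

  ## taxonomy: groups nested in classes, ASVs spread over groups
  grp_of_class <- rep(seq_len(config$n_classes), length.out = config$n_groups)
  grp <- sort(rep(seq_len(config$n_groups), length.out = p))
  taxonomy <- data.frame(asv_id = asv_ids,
                         group = sprintf("g%03d", grp),
                         class = sprintf("c%02d", grp_of_class[grp]),
                         stringsAsFactors = FALSE)

  heritable <- sort(sample.int(p, config$n_heritable_asvs))
  mediators <- sort(sample(heritable, config$n_mediators))

  ## microenvironment effect draws, per ASV
  tr_lev <- levels(design$treatment); bl_lev <- levels(design$block)
  sp_lev <- levels(design$splitplot); spb_lev <- levels(design$splitplotblock)
  ## microenvironment effects are kept modest relative to plot noise so the
  ## genotype-attributable fraction is comparable whether or not the design
  ## factors are conditioned out
  eff <- function(nlev, sd) matrix(rnorm(nlev * p, 0, sd), nlev, p)
  e_tr <- eff(length(tr_lev), 0.2); e_bl <- eff(length(bl_lev), 0.1)
  e_sp <- eff(length(sp_lev), 0.1); e_spb <- eff(length(spb_lev), 0.1)
  mu <- rnorm(p, log(1 / p), 1)

  V <- matrix(rnorm(n_obs * p, 0, 0.5), n_obs, p)  # plot-level noise
  V <- V + rep(mu, each = n_obs) +
    e_tr[as.integer(design$treatment), ] + e_bl[as.integer(design$block), ] +
    e_sp[as.integer(design$splitplot), ] + e_spb[as.integer(design$splitplotblock), ]

  ## genetic component for heritable ASVs
  Zc <- centered_dosages(geno)
  gidx <- match(as.character(design$genotype), rownames(geno$dosages))
  true_B <- vector("list", p); names(true_B) <- asv_ids
  if (config$asv_h2 > 0 && length(heritable) > 0) {
    for (j in heritable) {
      qtl <- sample.int(ncol(Zc), min(config$n_qtl_per_asv, ncol(Zc)))
      b <- rnorm(length(qtl))
      g_geno <- drop(Zc[, qtl, drop = FALSE] %*% b)
      g_plot <- g_geno[gidx]
      v_env <- var(V[, j]); v_g <- var(g_plot)
      if (v_g > 0) {
        sc <- sqrt(config$asv_h2 / (1 - config$asv_h2) * v_env / v_g)
        V[, j] <- V[, j] + g_plot * sc
        true_B[[j]] <- data.frame(marker_id = colnames(Zc)[qtl],
                                  effect = b * sc)
      }
    }
  }
  rownames(V) <- as.character(design$plot_id)
  colnames(V) <- asv_ids
  micro <- microbiome_table(V, taxonomy)
  list(microbiome = micro,
       truth = list(true_B = true_B,
                    heritable_ids = asv_ids[heritable],
                    mediator_ids = asv_ids[mediators]))
}

#' Simulate the phenotype and complete the truth bundle
#'
#' Assembles `y = mu + design fixed effects + Z alpha + M gamma + e` with
#' `alpha ~ N(0, sigma_alpha^2)` over all SNPs and sparse `gamma` over the
#' causal ASV set. Components are rescaled so the realized sample-variance
#' shares equal `h2_snp` and `var_share_asv` exactly; the residual takes the
#' remainder. Causal ASVs comprise the planted mediators plus
#' `n_causal_asvs - n_mediators` non-heritable ASVs, so that mediators -- and
#' only mediators -- carry both a genetic and a phenotype path. When
#' `treatment_specific` is set, the ASV term acts only on low-nitrogen plots.
#'
#' @param geno a [geno_matrix()].
#' @param microbiome output element `microbiome` of [simulate_microbiome()].
#' @param design the design table (row-aligned with `microbiome`).
#' @param config a [sim_config()].
#' @param truth partial truth bundle from [simulate_microbiome()].
#' @param seed optional override of `config$seed`.
#' @return list with `phenotype` (data.frame plot_id, y) and `truth`
#'   (complete truth bundle: true_alpha, true_gamma, true_B, mediator_ids,
#'   causal_ids, heritable_ids, variance_shares, components).
#' @export
simulate_phenotype <- function(geno, microbiome, design, config,
                               truth = list(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_design(design); check_alignment(design, microbiome)
  set.seed(derive_seeds(seed %||% config$seed, 4L)[4])
  n_obs <- nrow(design)
  asv_ids <- colnames(microbiome$values)
  p <- length(asv_ids)

  ## design fixed effects (LN depresses the trait; small spatial effects)
  fe <- c(HN = 0, LN = -0.5)[as.character(design$treatment)]
  for (v in c("block", "splitplot", "splitplotblock")) {
    lev <- levels(design[[v]])
    ev <- setNames(c(0, rnorm(length(lev) - 1, 0, 0.2)), lev)
    fe <- fe + ev[as.character(design[[v]])]
  }

  ## SNP polygenic component
  Zc <- centered_dosages(geno)
  gidx <- match(as.character(design$genotype), rownames(geno$dosages))
  alpha <- rnorm(ncol(Zc))
  g_plot <- drop(Zc %*% alpha)[gidx]
  scale_g <- if (config$h2_snp > 0 && sd(g_plot) > 0)
    sqrt(config$h2_snp) / sd(g_plot) else 0
  g_plot <- g_plot * scale_g
  alpha <- alpha * scale_g

  ## ASV component: mediators + extra causal from the non-heritable pool
  mediators <- truth$mediator_ids %||% character(0)
  heritable <- truth$heritable_ids %||% character(0)
  pool <- setdiff(asv_ids, heritable)
  extra <- sample(pool, min(config$n_causal_asvs - length(mediators), length(pool)))
  causal <- sort(c(mediators, extra))
  gamma <- setNames(numeric(p), asv_ids)
  gamma[causal] <- if (is.null(config$gamma_magnitude)) {
    rnorm(length(causal))
  } else {
    ## equal-effect design: each causal ASV contributes the same phenotypic
    ## variance (effects scaled by the ASV's abundance spread), random sign
    sds <- apply(microbiome$values[, causal, drop = FALSE], 2L, sd)
    config$gamma_magnitude * sample(c(-1, 1), length(causal), replace = TRUE) /
      pmax(sds, .Machine$double.eps)
  }
  Mc <- sweep(microbiome$values, 2L, colMeans(microbiome$values), "-")
  m_plot <- drop(Mc %*% gamma)
  if (isTRUE(config$treatment_specific))
    m_plot[design$treatment != "LN"] <- 0
  scale_m <- if (config$var_share_asv > 0 && sd(m_plot) > 0)
    sqrt(config$var_share_asv) / sd(m_plot) else 0
  m_plot <- m_plot * scale_m
  gamma <- gamma * scale_m

  resid_share <- 1 - config$h2_snp - config$var_share_asv
  e <- rnorm(n_obs)
  e <- e / sd(e) * sqrt(resid_share)

  y <- 1 + fe + g_plot + m_plot + e
  truth_out <- list(
    true_alpha = setNames(alpha, colnames(Zc)),
    true_gamma = gamma,
    true_B = truth$true_B %||% NULL,
    mediator_ids = mediators,
    causal_ids = causal,
    heritable_ids = heritable,
    treatment_specific = isTRUE(config$treatment_specific),
    variance_shares = c(snp = config$h2_snp, asv = config$var_share_asv,
                        residual = resid_share),
    components = data.frame(plot_id = as.character(design$plot_id),
                            fixed = fe, genetic = g_plot,
                            microbial = m_plot, residual = e))
  list(phenotype = data.frame(plot_id = as.character(design$plot_id), y = y,
                              stringsAsFactors = FALSE),
       truth = truth_out)
}

#' Simulate a complete hologenome dataset
#'
#' Runs [simulate_genotypes()], [simulate_design()], [simulate_microbiome()]
#' and [simulate_phenotype()] with seeds derived from `config$seed`, and
#' returns everything downstream modules need.
#'
#' @param config a [sim_config()].
#' @return list with `geno`, `design`, `microbiome`, `phenotype` (numeric
#'   vector aligned with design rows), `truth` and `config`.
#' @export
simulate_hologenome <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  design <- simulate_design(config)
  mic <- simulate_microbiome(geno, design, config)
  phe <- simulate_phenotype(geno, mic$microbiome, design, config,
                            truth = mic$truth)
  list(geno = geno, design = design, microbiome = mic$microbiome,
       phenotype = setNames(phe$phenotype$y, phe$phenotype$plot_id),
       truth = phe$truth, config = config)
}
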