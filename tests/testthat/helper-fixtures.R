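# Small in-code fixtures and independent brute-force oracles shared by the
# unit tests. Oracles are deliberately naive (enumeration / direct formulas)
# and never call the implementation paths they check.

# tiny genotype matrix with explicit dosages
tiny_geno <- function(dosages, chrom = NULL, pos = NULL) {
  m <- ncol(dosages)
  geno_matrix(dosages,
              chrom = chrom %||% rep("chr1", m),
              pos = pos %||% seq(1L, by = 1000L, length.out = m))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# exhaustive O(m^2) LD pruner: walk markers left to right per chromosome;
# drop marker j if any surviving earlier marker closer than window_bp has
# r^2 > threshold (monomorphic pairs count as r^2 = 0)
brute_prune <- function(geno, window_bp = 10000, r2_threshold = 0.1) {
  d <- geno$dosages
  if (anyNA(d)) {
    cm <- colMeans(d, na.rm = TRUE)
    for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- cm[j]
  }
  keep <- rep(TRUE, ncol(d))
  for (chr in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == chr)
    for (jj in seq_along(idx)) {
      j <- idx[jj]
      if (jj == 1L) next
      for (ii in seq_len(jj - 1L)) {
        i <- idx[ii]
        if (!keep[i]) next
        if (geno$map$pos[j] - geno$map$pos[i] >= window_bp) next
        if (sd(d[, i]) == 0 || sd(d[, j]) == 0) next
        if (cor(d[, i], d[, j])^2 > r2_threshold) { keep[j] <- FALSE; break }
      }
    }
  }
  colnames(geno$dosages)[keep]
}

# Spearman rho via the rank-based Pearson formula (handles ties by midranks)
brute_spearman <- function(x, y) cor(rank(x), rank(y))

# Kruskal-Wallis H with tie correction, direct from the definition
brute_kruskal_h <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  groups <- split(r, g)
  h <- 12 / (n * (n + 1)) * sum(vapply(groups, function(ri)
    length(ri) * (mean(ri) - (n + 1) / 2)^2, numeric(1)))
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# design table for hand-built examples
toy_design <- function(genotype, treatment = "HN", block = "B1",
                       splitplot = "SP1", splitplotblock = "SPB1") {
  n <- length(genotype)
  data.frame(plot_id = sprintf("P%04d", seq_len(n)),
             genotype = factor(genotype),
             treatment = factor(rep_len(treatment, n)),
             block = factor(rep_len(block, n)),
             splitplot = factor(rep_len(splitplot, n)),
             splitplotblock = factor(rep_len(splitplotblock, n)),
             quadrant = factor(paste(rep_len(block, n), rep_len(splitplot, n),
                                     sep = ":")))
}

# reduced-scale simulated bundle used by several test files
demo_bundle <- function(seed = 42, ...) {
  cfg <- sim_config_demo(n_genotypes = 60, n_snps = 300, n_asvs = 100,
                         n_causal_asvs = 15, n_mediators = 5, seed = seed, ...)
  holo <- simulate_hologenome(cfg)
  list(holo = holo,
       data = megs_data(holo$geno, holo$design, holo$microbiome,
                        holo$phenotype))
}
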