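#' Filter markers by missingness and minor allele frequency
#'
#' Retains markers whose missing fraction is at most `max_missing` and whose
#' minor allele frequency (computed on non-missing calls) is at least
#' `min_maf`. Defaults are the conventional 0.3 / 0.05 thresholds. Markers
#' with all calls missing are dropped (counted under the missingness rule).
#' Marker order is preserved and provenance counts are attached.
#'
#' @param geno a [geno_matrix()].
#' @param max_missing maximum tolerated per-marker missing fraction.
#' @param min_maf minimum minor allele frequency.
#' @return a filtered `geno_matrix` with attribute `provenance`
#'   (input, dropped_missing, dropped_maf, retained).
#' @export
filter_variants <- function(geno, max_missing = 0.3, min_maf = 0.05) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- geno$dosages
  assert_that(ncol(d) > 0, "empty genotype matrix")
  miss <- colMeans(is.na(d))
  all_missing <- miss == 1
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[all_missing] <- NA_real_
  fail_miss <- miss > max_missing | all_missing
  fail_maf <- !fail_miss & (is.na(maf) | maf < min_maf)
  keep <- !fail_miss & !fail_maf
  out <- subset_markers(geno, which(keep))
  attr(out, "provenance") <- c(input = ncol(d),
                               dropped_missing = sum(fail_miss),
                               dropped_maf = sum(fail_maf),
                               retained = sum(keep))
  out
}

#' Sliding-window LD pruning
#'
#' Greedy left-to-right pruning per chromosome: windows of `window_bp`
#' (half-open on 1-based physical coordinates) advance by `step_bp` from the
#' chromosome's first marker; within each window every surviving pair is
#' checked, and when the squared Pearson correlation of dosages exceeds
#' `r2_threshold` the later marker (larger position; tie broken towards the
#' larger column index) is removed. Removed markers never re-enter.
#' Correlations against monomorphic markers are treated as 0 and never cause
#' removal. Missing dosages are mean-imputed for the correlation only.
#'
#' With the default 10 bp step and 10 kb window this is effectively an
#' exhaustive check of all pairs less than `window_bp` apart; a larger
#' `step_bp` trades fidelity for speed.
#'
#' @param geno a [geno_matrix()].
#' @param window_bp window length in bp (default 10 kb).
#' @param step_bp window advance in bp (default 10 bp).
#' @param r2_threshold squared-correlation threshold (default 0.1).
#' @return a pruned `geno_matrix` with attribute `provenance`.
#' @export
ld_prune <- function(geno, window_bp = 10000, step_bp = 10, r2_threshold = 0.1) {
  stopifnot(inherits(geno, "geno_matrix"))
  assert_that(window_bp > 0 && step_bp > 0, "window_bp and step_bp must be positive")
  d <- geno$dosages
  if (anyNA(d)) {
    cm <- colMeans(d, na.rm = TRUE)
    for (j in which(colSums(is.na(d)) > 0L)) d[is.na(d[, j]), j] <- cm[j]
  }
  keep <- rep(TRUE, ncol(d))
  for (chr in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == chr)
    pos <- geno$map$pos[idx]
    if (length(idx) < 2L) next
    starts <- seq(from = min(pos), to = max(pos), by = step_bp)
    prev_members <- integer(0)
    for (st in starts) {
      members <- idx[pos >= st & pos < st + window_bp]
      members <- members[keep[members]]
      if (length(members) < 2L || identical(members, prev_members)) {
        prev_members <- members
        next
      }
      prev_members <- members
      ## members are in (pos, column) order already
      for (a in seq_len(length(members) - 1L)) {
        i <- members[a]
        if (!keep[i]) next
        for (b in (a + 1L):length(members)) {
          j <- members[b]
          if (!keep[j]) next
          if (dosage_r2(d[, i], d[, j]) > r2_threshold) keep[j] <- FALSE
        }
      }
      prev_members <- members[keep[members]]
    }
  }
  out <- subset_markers(geno, which(keep))
  attr(out, "provenance") <- c(input = ncol(d), removed = sum(!keep),
                               retained = sum(keep))
  out
}

#' Random marker subsample
#'
#' Uniform sample of `n` markers without replacement; output preserves
#' genomic order. Companion presets of 10k/25k/50k markers are conventional
#' for prediction at reduced computational cost.
#'
#' @param geno a [geno_matrix()].
#' @param n number of markers to keep (default 50,000).
#' @param seed integer seed.
#' @return a `geno_matrix` of `n` markers.
#' @export
sample_markers <- function(geno, n = 50000, seed = 1L) {
  stopifnot(inherits(geno, "geno_matrix"))
  m <- ncol(geno$dosages)
  if (n > m)
    abort_megs(sprintf("requested %d markers but only %d available", n, m))
  set.seed(seed)
  subset_markers(geno, sort(sample.int(m, n)))
}

#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' `A = W W' / (2 * sum p_k (1 - p_k))` with `W` the mean-imputed,
#' column-centered dosage matrix and `p_k` the allele frequencies. Under
#' Hardy-Weinberg equilibrium the mean diagonal is close to 1.
#'
#' @param geno a [geno_matrix()].
#' @return list of class `grm` with `matrix` (symmetric, labelled) and
#'   `individual_ids`.
#' @export
additive_relationship <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  W <- centered_dosages(geno)
  p <- attr(W, "p")
  poly <- p > 0 & p < 1
  assert_that(any(poly), "no polymorphic markers; GRM undefined")
  W <- W[, poly, drop = FALSE]
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  A <- tcrossprod(W) / denom
  A <- (A + t(A)) / 2
  dimnames(A) <- list(rownames(geno$dosages), rownames(geno$dosages))
  structure(list(matrix = A, individual_ids = rownames(geno$dosages)),
            class = "grm")
}

#' Principal components of the genotype matrix
#'
#' Top-`k` principal-component scores of the mean-imputed, column-centered
#' dosage matrix, ordered by explained variance. Sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param geno a [geno_matrix()].
#' @param k number of components (default 3, the usual genomic-background
#'   control in the downstream models).
#' @return matrix of scores (individuals x k) with rownames, columns
#'   `PC1..PCk`; attribute `sdev` carries the component standard deviations.
#' @export
genotype_pcs <- function(geno, k = 3) {
  stopifnot(inherits(geno, "geno_matrix"))
  W <- centered_dosages(geno)
  n <- nrow(W)
  maxk <- min(n - 1L, ncol(W))
  if (k > maxk)
    abort_megs(sprintf("k = %d exceeds the available rank (%d)", k, maxk))
  sv <- svd(W, nu = k, nv = k)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(geno$dosages), paste0("PC", seq_len(k)))
  attr(scores, "sdev") <- sv$d[seq_len(k)] / sqrt(max(1, n - 1))
  scores
}

#' Run the genotype preparation pipeline
#'
#' Filters, LD-prunes and subsamples in that fixed order, recording the
#' marker count after every stage.
#'
#' @inheritParams filter_variants
#' @inheritParams ld_prune
#' @param n_sample markers to keep after pruning (`NULL` to skip sampling).
#' @param seed seed for the marker subsample.
#' @return a `geno_matrix`; attribute `pipeline` holds per-stage counts.
#' @export
prep_genotypes <- function(geno, max_missing = 0.3, min_maf = 0.05,
                           window_bp = 10000, step_bp = 10,
                           r2_threshold = 0.1, n_sample = NULL, seed = 1L) {
  g1 <- filter_variants(geno, max_missing, min_maf)
  g2 <- ld_prune(g1, window_bp, step_bp, r2_threshold)
  counts <- c(input = ncol(geno$dosages), filtered = ncol(g1$dosages),
              pruned = ncol(g2$dosages))
  out <- g2
  if (!is.null(n_sample) && n_sample < ncol(g2$dosages)) {
    out <- sample_markers(g2, n_sample, seed)
    counts <- c(counts, sampled = ncol(out$dosages))
  }
  attr(out, "pipeline") <- counts
  out
}
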