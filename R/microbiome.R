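#' Log relative abundance from a count table
#'
#' Divides each observation's counts by its total, applies a pseudocount
#' policy to zeros, and takes the natural log. The default policy replaces
#' zero relative abundances with half the smallest nonzero relative abundance
#' in the table, so zeros map to a finite value strictly below every observed
#' nonzero log abundance.
#'
#' @param counts nonnegative matrix, observations x ASVs; rownames are
#'   observation ids.
#' @param taxonomy data.frame (asv_id, group, class) for the output table.
#' @param pseudocount `"half_min_nonzero"` (default), `"none"` (zeros are an
#'   error), or a positive number used as the replacement relative abundance.
#' @return a [microbiome_table()] of log relative abundances.
#' @export
log_relative_abundance <- function(counts, taxonomy,
                                   pseudocount = "half_min_nonzero") {
  assert_that(is.matrix(counts) && all(counts >= 0, na.rm = TRUE),
              "counts must be a nonnegative matrix")
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    bad <- rownames(counts)[which(tot == 0)[1]] %||% which(tot == 0)[1]
    abort_megs(sprintf("observation '%s' has all-zero counts", bad))
  }
  rel <- counts / tot
  zero <- rel == 0
  if (any(zero)) {
    repl <- if (identical(pseudocount, "half_min_nonzero")) {
      min(rel[!zero]) / 2
    } else if (is.numeric(pseudocount) && pseudocount > 0) {
      pseudocount
    } else {
      abort_megs("zero counts present but pseudocount policy is 'none'")
    }
    rel[zero] <- repl
  }
  microbiome_table(log(rel), taxonomy)
}

#' Aggregate ASVs to taxonomic group or class resolution
#'
#' ASVs sharing a label are combined by summing their relative abundances
#' (i.e. on the exponentiated scale) before re-applying the log, so a group's
#' value is the log composite relative abundance of its members.
#' `level = "asv"` is the identity.
#'
#' @param micro a [microbiome_table()].
#' @param level `"asv"`, `"group"` or `"class"`.
#' @return a `microbiome_table` whose columns are the distinct labels at the
#'   requested level (taxonomy collapsed accordingly).
#' @export
aggregate_taxa <- function(micro, level = c("asv", "group", "class")) {
  stopifnot(inherits(micro, "microbiome_table"))
  level <- match.arg(level)
  if (level == "asv") return(micro)
  lab <- micro$taxonomy[[level]]
  assert_that(!anyNA(lab), sprintf("missing taxonomy at level '%s'", level))
  rel <- exp(micro$values)
  agg <- t(rowsum(t(rel), group = lab))  # observations x labels
  agg <- agg[, sort(unique(lab)), drop = FALSE]
  vals <- log(agg)
  if (level == "group") {
    g2c <- unique(micro$taxonomy[c("group", "class")])
    tax <- data.frame(asv_id = colnames(vals),
                      group = colnames(vals),
                      class = g2c$class[match(colnames(vals), g2c$group)],
                      stringsAsFactors = FALSE)
  } else {
    tax <- data.frame(asv_id = colnames(vals), group = colnames(vals),
                      class = colnames(vals), stringsAsFactors = FALSE)
  }
  microbiome_table(vals, tax)
}

#' Repeatability of ASV abundances across genotype replicates
#'
#' For each treatment separately, fits the one-way genotype-random
#' decomposition of log abundance by the ANOVA method of moments and returns
#' the variance-ratio score `sigma2_genotype / (sigma2_genotype +
#' sigma2_residual)`, clipped to the unit interval -- a heritability-like measure of how
#' strongly host genotype determines an ASV's abundance. Treatments without
#' genotype replication yield `NA` scores.
#'
#' @param micro a [microbiome_table()] row-aligned with `design`.
#' @param design the plot design table.
#' @return matrix ASVs x treatments of repeatability scores.
#' @export
asv_repeatability <- function(micro, design) {
  stopifnot(inherits(micro, "microbiome_table"))
  check_design(design); check_alignment(design, micro)
  treatments <- levels(design$treatment)
  out <- matrix(NA_real_, ncol(micro$values), length(treatments),
                dimnames = list(colnames(micro$values), treatments))
  for (tr in treatments) {
    rows <- which(design$treatment == tr)
    V <- micro$values[rows, , drop = FALSE]
    g <- droplevels(design$genotype[rows])
    N <- length(rows); I <- nlevels(g)
    if (N <= I) next  # no replication within this treatment
    n_i <- as.vector(table(g))
    G <- rowsum(V, g)                      # genotype sums, I x p
    ss_within <- colSums(V^2) - colSums(G^2 / n_i)
    ss_between <- colSums(G^2 / n_i) - colSums(V)^2 / N
    msb <- ss_between / (I - 1)
    msw <- ss_within / (N - I)
    kbar <- (N - sum(n_i^2) / N) / (I - 1)
    sg <- (msb - msw) / kbar
    score <- sg / (sg + msw)
    score[!is.finite(score)] <- NA_real_
    out[, tr] <- pmin(1, pmax(0, score))
  }
  out
}

#' Shuffle microbiome rows within design strata
#'
#' Randomly permutes the rows of the abundance matrix within each stratum --
#' either nitrogen treatment, or treatment x quadrant -- by sampling row ids
#' without replacement (identity assignments are allowed, i.e. the
#' permutation is uniform over each stratum's permutations). The per-stratum
#' multiset of rows is exactly preserved; taxonomy, phenotype and design are
#' untouched. This is the null control used against the real microbiome in
#' cross-validation.
#'
#' @param micro a [microbiome_table()] row-aligned with `design`.
#' @param design the plot design table.
#' @param strategy `"within_treatment"` or `"within_treatment_quadrant"`.
#' @param seed integer seed.
#' @return a `microbiome_table` with permuted rows (row names keep the
#'   original plot order so alignment with the design is unchanged).
#' @export
shuffle_microbiome <- function(micro, design,
                               strategy = c("within_treatment",
                                            "within_treatment_quadrant"),
                               seed = 1L) {
  stopifnot(inherits(micro, "microbiome_table"))
  strategy <- match.arg(strategy)
  check_design(design); check_alignment(design, micro)
  key <- if (strategy == "within_treatment") {
    as.character(design$treatment)
  } else {
    paste(design$treatment, design$quadrant, sep = "|")
  }
  set.seed(seed)
  perm <- seq_len(nrow(micro$values))
  for (gkey in unique(key)) {
    rows <- which(key == gkey)
    if (length(rows) > 1L) perm[rows] <- rows[sample.int(length(rows))]
  }
  vals <- micro$values[perm, , drop = FALSE]
  rownames(vals) <- rownames(micro$values)
  out <- microbiome_table(vals, micro$taxonomy, micro$annotations)
  attr(out, "permutation") <- perm
  out
}
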