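#' Assemble an analysis-ready data bundle
#'
#' Validates mutual alignment of genotype matrix, design table, microbiome
#' table and phenotype, and precomputes what the evaluation and mediation
#' layers reuse: mean-imputed centered dosages, their plot-level expansion,
#' and the top genotype principal components.
#'
#' @param geno a [geno_matrix()].
#' @param design plot design table.
#' @param microbiome a [microbiome_table()] row-aligned with `design`.
#' @param phenotype named numeric vector (names = plot ids) or numeric
#'   vector aligned with `design` rows.
#' @param n_pcs genotype principal components to carry (default 3).
#' @return list of class `megs_data`.
#' @export
megs_data <- function(geno, design, microbiome, phenotype, n_pcs = 3) {
  check_design(design)
  check_alignment(design, microbiome)
  if (!is.null(names(phenotype))) {
    assert_that(all(as.character(design$plot_id) %in% names(phenotype)),
                "phenotype is missing some design plots")
    phenotype <- phenotype[as.character(design$plot_id)]
  }
  assert_that(length(phenotype) == nrow(design),
              "phenotype length must match design rows")
  Zg <- centered_dosages(geno)
  gidx <- match(as.character(design$genotype), rownames(geno$dosages))
  assert_that(!anyNA(gidx), "design references unknown genotypes")
  pcs <- genotype_pcs(geno, k = n_pcs)
  structure(list(geno = geno, design = design, microbiome = microbiome,
                 y = unname(phenotype), Z_geno = Zg, geno_index = gidx,
                 Z = Zg[gidx, , drop = FALSE], pcs = pcs),
            class = "megs_data")
}

#' Genotype-disjoint cross-validation folds
#'
#' Genotypes are randomly partitioned into `k` near-equal folds and every
#' plot inherits its genotype's fold, so the same genotype never appears in
#' both a training and a held-out fold (randomization is at the plot level,
#' grouping at the genotype level).
#'
#' @param design plot design table.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold ids per design row; attribute
#'   `genotype_fold` is the named genotype-level assignment.
#' @export
make_folds <- function(design, k = 5, seed = 1L) {
  check_design(design)
  gens <- unique(as.character(design$genotype))
  if (k > length(gens))
    abort_megs(sprintf("k = %d exceeds the %d distinct genotypes", k, length(gens)))
  set.seed(seed)
  shuffled <- sample(gens)
  gf <- setNames(rep(seq_len(k), length.out = length(gens)), shuffled)
  fold <- unname(gf[as.character(design$genotype)])
  attr(fold, "genotype_fold") <- gf
  fold
}

star_label <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**"
  else if (p <= 0.05) "*" else "ns"
}

#' Relative improvement of prediction accuracy
#'
#' `(r_full - r_base) / r_base`; undefined (`NA`) when the baseline accuracy
#' is zero.
#'
#' @param r_full accuracy of the augmented model.
#' @param r_base accuracy of the baseline model.
#' @return fraction (vectorized).
#' @export
relative_improvement <- function(r_full, r_base) {
  out <- (r_full - r_base) / r_base
  out[r_base == 0] <- NA_real_
  out
}

#' Cross-validated prediction accuracy of one model arm
#'
#' Runs `n_repeats` randomized `k`-fold genotype-disjoint cross-validations
#' of a model arm and records the Pearson correlation between predicted and
#' observed phenotype over each held-out fold's plots. Variance components
#' are re-estimated inside every training fold (no leakage). Arms:
#' \describe{
#'   \item{`snp`}{ridge-regression BLUP on SNPs only.}
#'   \item{`snp+asv`}{joint SNP + ASV model with plug-in variances.}
#'   \item{`snp+shuffled-asv`}{as `snp+asv` but the microbiome rows are
#'     shuffled within treatment (or treatment x quadrant) once per repeat --
#'     the dummy-covariate null control. Fold seeds are shared with the
#'     unshuffled arms, so comparisons are paired.}
#' }
#' A held-out fold with zero phenotypic variance yields `NA` accuracy and is
#' excluded from summaries.
#'
#' Two genotype-level baseline arms are also available: `gblup`
#' (conventional G-BLUP with the VanRaden relationship matrix; held-out
#' genotypes are predicted through their relatives) and `gblup+asv` (the
#' same fit with the microbiome abundances at the chosen resolution as an
#' additional identity-covariance random component, treating microbes as
#' microenvironmental covariates).
#'
#' @param data a [megs_data()] bundle.
#' @param arm model arm (see above).
#' @param resolution microbiome resolution: `"asv"`, `"group"` or `"class"`.
#' @param scope `"all"`, or one treatment (`"HN"` / `"LN"`) to restrict all
#'   fitting and evaluation to that treatment's plots.
#' @param k folds per repeat (default 5).
#' @param n_repeats repeats (default 20).
#' @param seed master seed; repeat `r` uses a seed derived from `(seed, r)`,
#'   identically across arms.
#' @param shuffle_strategy stratification of the shuffled-arm permutation.
#' @return object of class `cv_result`: `accuracy` data.frame
#'   (repeat, fold, accuracy) plus the scheme metadata.
#' @export
cross_validate <- function(data,
                           arm = c("snp", "snp+asv", "snp+shuffled-asv",
                                   "gblup", "gblup+asv"),
                           resolution = c("asv", "group", "class"),
                           scope = c("all", "HN", "LN"),
                           k = 5, n_repeats = 20, seed = 1L,
                           shuffle_strategy = "within_treatment") {
  stopifnot(inherits(data, "megs_data"))
  arm <- match.arg(arm)
  resolution <- match.arg(resolution)
  scope <- match.arg(scope)

  rows <- if (scope == "all") seq_len(nrow(data$design)) else
    which(data$design$treatment == scope)
  design_s <- droplevels(data$design[rows, , drop = FALSE])
  y_s <- data$y[rows]
  Z_s <- data$Z[rows, , drop = FALSE]
  micro <- aggregate_taxa(data$microbiome, resolution)
  genotype_level <- arm %in% c("gblup", "gblup+asv")
  grm <- if (genotype_level) additive_relationship(data$geno)

  use_asv <- arm %in% c("snp+asv", "snp+shuffled-asv", "gblup+asv")
  res <- vector("list", n_repeats)
  seeds <- derive_seeds(seed, n_repeats)
  for (r in seq_len(n_repeats)) {
    micro_r <- micro
    if (arm == "snp+shuffled-asv")
      micro_r <- shuffle_microbiome(micro, data$design,
                                    strategy = shuffle_strategy,
                                    seed = seeds[r] + 1L)
    M_s <- micro_r$values[rows, , drop = FALSE]
    M_s <- sweep(M_s, 2L, colMeans(M_s), "-")
    fold <- make_folds(design_s, k = k, seed = seeds[r])
    acc <- rep(NA_real_, k)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      if (genotype_level) {
        fit <- fit_gblup_genotype(y_s[tr], design_s[tr, , drop = FALSE], grm,
                                  asv_groups = if (use_asv)
                                    M_s[tr, , drop = FALSE])
        pred <- predict(fit, design = design_s[te, , drop = FALSE],
                        M = if (use_asv) M_s[te, , drop = FALSE])
      } else {
        fit <- fit_megs(y_s[tr], design_s[tr, , drop = FALSE],
                        Z = Z_s[tr, , drop = FALSE],
                        M = if (use_asv) M_s[tr, , drop = FALSE],
                        pcs = data$pcs, include_asv = use_asv)
        pred <- predict(fit, design = design_s[te, , drop = FALSE],
                        Z = Z_s[te, , drop = FALSE],
                        M = if (use_asv) M_s[te, , drop = FALSE])
      }
      if (sd(y_s[te]) > 0 && sd(pred) > 0) acc[f] <- cor(pred, y_s[te])
    }
    res[[r]] <- data.frame(rep = r, fold = seq_len(k), accuracy = acc)
  }
  structure(list(accuracy = do.call(rbind, res),
                 scheme = list(k = k, n_repeats = n_repeats, seed = seed,
                               grouping = "genotype", arm = arm,
                               resolution = resolution, scope = scope)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$scheme
  cat(sprintf("cv_result: %s | %s | %s — %d x %d-fold, mean accuracy %.3f\n",
              s$arm, s$resolution, s$scope, s$n_repeats, s$k,
              mean(x$accuracy$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' Mean cross-validated accuracy
#'
#' @param cv a `cv_result`.
#' @param by `"overall"` (mean over all fold-level accuracies) or
#'   `"repeat"` (mean per repeat).
#' @return numeric.
#' @export
cv_accuracy <- function(cv, by = c("overall", "repeat")) {
  by <- match.arg(by)
  if (by == "overall") return(mean(cv$accuracy$accuracy, na.rm = TRUE))
  tapply(cv$accuracy$accuracy, cv$accuracy$rep, mean, na.rm = TRUE)
}

#' Paired comparison of two cross-validation results
#'
#' Two-sided paired test on the fold-level accuracy differences of two arms
#' run under the same scheme (same folds, repeats and seed). Significance is
#' summarized with the conventional star labels: ns, * (0.01 < p <= 0.05),
#' ** (0.001 < p <= 0.01), *** (1e-4 < p <= 0.001), **** (p <= 1e-4).
#'
#' @param cv_a,cv_b `cv_result` objects with identical schemes.
#' @param method `"t"` (paired t-test, default) or `"wilcoxon"` (signed rank).
#' @return list: `statistic`, `p_value`, `stars`, `mean_diff` (a - b), `n`.
#' @export
compare_models <- function(cv_a, cv_b, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  sa <- cv_a$scheme; sb <- cv_b$scheme
  same <- identical(sa[c("k", "n_repeats", "seed", "grouping", "scope")],
                    sb[c("k", "n_repeats", "seed", "grouping", "scope")])
  assert_that(same, "cross-validation schemes differ; comparison is unpaired")
  a <- cv_a$accuracy$accuracy; b <- cv_b$accuracy$accuracy
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  if (all(abs(d) < .Machine$double.eps^0.75)) {
    return(list(statistic = 0, p_value = 1, stars = "ns",
                mean_diff = 0, n = sum(ok)))
  }
  tst <- if (method == "t") t.test(d) else wilcox.test(d, exact = FALSE)
  list(statistic = unname(tst$statistic), p_value = tst$p.value,
       stars = star_label(tst$p.value), mean_diff = mean(d), n = sum(ok))
}

#' Full model-arm x resolution x treatment-scope experiment grid
#'
#' Runs cross-validation for every combination of arm, microbiome resolution
#' and treatment scope, then summarizes each (resolution, scope) cell: mean
#' accuracy per arm, paired significance of each augmented arm against the
#' SNP-only baseline, and the relative accuracy improvement of the true-ASV
#' arm.
#'
#' @param data a [megs_data()] bundle.
#' @param arms character subset of the three model arms.
#' @param resolutions character subset of asv/group/class.
#' @param scopes character subset of all/HN/LN.
#' @inheritParams cross_validate
#' @return list with `accuracy` (tidy fold-level data.frame), `summary`
#'   (one row per arm x resolution x scope) and `cv` (the raw `cv_result`s).
#' @export
run_megs_experiment <- function(data, arms = c("snp", "snp+asv", "snp+shuffled-asv"),
                                resolutions = "asv", scopes = "all",
                                k = 5, n_repeats = 20, seed = 1L,
                                shuffle_strategy = "within_treatment") {
  cvs <- list(); acc <- list(); summ <- list()
  for (resn in resolutions) for (sc in scopes) {
    cell <- list()
    for (arm in arms) {
      cv <- cross_validate(data, arm = arm, resolution = resn, scope = sc,
                           k = k, n_repeats = n_repeats, seed = seed,
                           shuffle_strategy = shuffle_strategy)
      cell[[arm]] <- cv
      cvs[[paste(arm, resn, sc, sep = "|")]] <- cv
      acc[[length(acc) + 1L]] <- cbind(arm = arm, resolution = resn,
                                       scope = sc, cv$accuracy)
    }
    base <- cell[["snp"]]
    for (arm in arms) {
      r <- cv_accuracy(cell[[arm]])
      cmpr <- if (arm != "snp" && !is.null(base)) compare_models(cell[[arm]], base)
      summ[[length(summ) + 1L]] <- data.frame(
        arm = arm, resolution = resn, scope = sc, mean_accuracy = r,
        improvement_vs_snp = if (!is.null(base))
          relative_improvement(r, cv_accuracy(base)) else NA_real_,
        p_vs_snp = if (!is.null(cmpr)) cmpr$p_value else NA_real_,
        stars = if (!is.null(cmpr)) cmpr$stars else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  list(accuracy = do.call(rbind, acc), summary = do.call(rbind, summ),
       cv = cvs)
}
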