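#' Effect table from a fitted prediction model
#'
#' Extracts per-feature random-effect estimates (BLUP coefficients) from a
#' joint fit as a tidy table, joining ASV taxonomy when available. Effect
#' "size" downstream means the absolute value of these coefficients.
#'
#' @param fit a `megs_fit` from [fit_megs()] / [fit_two_component()].
#' @param component `"gamma"` (ASV effects) or `"alpha"` (SNP effects).
#' @param taxonomy optional taxonomy data.frame (asv_id, group, class).
#' @param context optional named list (trait, date, treatment scope) copied
#'   into the table.
#' @return data.frame: feature_id, effect, abs_effect (+ taxonomy, context).
#' @export
effect_table <- function(fit, component = c("gamma", "alpha"),
                         taxonomy = NULL, context = NULL) {
  stopifnot(inherits(fit, "megs_fit"))
  component <- match.arg(component)
  eff <- fit$random[[component]]
  assert_that(length(eff) > 0, sprintf("fit has no '%s' component", component))
  out <- data.frame(feature_id = names(eff), effect = unname(eff),
                    abs_effect = abs(unname(eff)), stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    i <- match(out$feature_id, taxonomy$asv_id)
    out$group <- taxonomy$group[i]
    out$class <- taxonomy$class[i]
  }
  if (!is.null(context)) for (nm in names(context)) out[[nm]] <- context[[nm]]
  assert_that(all(is.finite(out$effect)), "non-finite effect estimates")
  out
}

#' Top fraction of features by absolute effect
#'
#' The `ceiling(fraction * n)` features with largest `|effect|`; boundary
#' ties are broken deterministically by feature id.
#'
#' @param effects an effect table (from [effect_table()] or any data.frame
#'   with `feature_id` and `effect`).
#' @param fraction fraction of features to keep, in (0, 1]; default 0.01
#'   (the "top 1%" convention).
#' @return character vector of selected feature ids.
#' @export
top_fraction <- function(effects, fraction = 0.01) {
  assert_that(nrow(effects) > 0, "empty effect table")
  assert_that(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  n_top <- ceiling(fraction * nrow(effects))
  ord <- order(-abs(effects$effect), effects$feature_id)
  effects$feature_id[ord][seq_len(n_top)]
}

#' Kruskal-Wallis test of effect sizes across taxonomic groups
#'
#' Tests whether absolute effect sizes are exchangeable across taxonomic
#' groups (tie-corrected rank test) -- a disproportionate enrichment of
#' large-effect ASVs within certain groups shows up as a small p-value.
#'
#' @param effects effect table with a `group` column (or supply `taxonomy`).
#' @param taxonomy optional taxonomy to join on `feature_id`.
#' @return list: `statistic` (H), `df`, `p_value`.
#' @export
effect_group_test <- function(effects, taxonomy = NULL) {
  if (!is.null(taxonomy))
    effects$group <- taxonomy$group[match(effects$feature_id, taxonomy$asv_id)]
  assert_that(!is.null(effects$group), "no taxonomic group labels available")
  g <- factor(effects$group)
  assert_that(nlevels(g) >= 2, "need at least two taxonomic groups")
  x <- abs(effects$effect)
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, df = nlevels(g) - 1L, p_value = 1))
  kt <- kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Compare an annotation between top-effect features and the rest
#'
#' Wilcoxon rank-sum test of a per-feature annotation (e.g. an ASV
#' heritability or selection score) between a selected feature set and all
#' other features. Features with missing annotations are dropped (counted).
#'
#' @param top_ids feature ids of the selected (e.g. top 1%) set.
#' @param annotations data.frame with `feature_id` and the annotation column.
#' @param column annotation column name.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (top set vs rest).
#' @return list: `statistic` (W), `p_value`, `n_top`, `n_rest`, `n_dropped`.
#' @export
annotation_compare <- function(top_ids, annotations, column,
                               alternative = "two.sided") {
  assert_that(column %in% names(annotations),
              sprintf("annotation column '%s' not found", column))
  x <- annotations[[column]]
  keep <- !is.na(x)
  n_dropped <- sum(!keep)
  ann <- annotations[keep, , drop = FALSE]
  in_top <- ann$feature_id %in% top_ids
  assert_that(any(in_top) && any(!in_top),
              "both the top set and the rest must be non-empty")
  wt <- wilcox.test(ann[[column]][in_top], ann[[column]][!in_top],
                    alternative = alternative, exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_top = sum(in_top), n_rest = sum(!in_top), n_dropped = n_dropped)
}

#' Spearman correlation between an ASV's abundance and the phenotype
#'
#' Tie-corrected Spearman rank correlation within a treatment scope.
#'
#' @param abundance numeric vector of one ASV's (log) abundance per plot.
#' @param phenotype numeric phenotype per plot.
#' @param scope optional logical/integer index restricting the plots
#'   (e.g. one nitrogen treatment).
#' @return list: `rho`, `p_value`, `n`.
#' @export
abundance_phenotype_correlation <- function(abundance, phenotype,
                                            scope = NULL) {
  if (!is.null(scope)) {
    abundance <- abundance[scope]
    phenotype <- phenotype[scope]
  }
  assert_that(length(abundance) >= 3, "need at least 3 paired observations")
  assert_that(sd(abundance) > 0 && sd(phenotype) > 0,
              "constant input; correlation undefined")
  ct <- suppressWarnings(cor.test(abundance, phenotype, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n = length(abundance))
}
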