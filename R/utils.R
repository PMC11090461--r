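`%||%` <- function(x, y) if (is.null(x)) y else x

abort_megs <- function(msg, class = "megs_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort_megs(msg)
  invisible(TRUE)
}

#' Reduce a design matrix to a full-rank column basis
#'
#' Rank-deficient fixed-effect matrices (e.g. after subsetting a treatment
#' scope so a factor becomes constant) are reduced to a pivoted full-rank
#' basis; dropped (aliased) columns are recorded.
#'
#' @param X numeric matrix.
#' @return list with `X` (full-rank), `kept`, `dropped` column names.
#' @keywords internal
full_rank_basis <- function(X) {
  qrX <- qr(X)
  r <- qrX$rank
  keep <- qrX$pivot[seq_len(r)]
  keep <- sort(keep)
  list(X = X[, keep, drop = FALSE],
       kept = colnames(X)[keep],
       dropped = setdiff(colnames(X), colnames(X)[keep]))
}

design_factor_cols <- c("treatment", "block", "splitplot", "splitplotblock")

#' Fixed-effect design matrix for the split-plot field factors
#'
#' Builds the intercept + treatment + block + split plot + split-plot block
#' dummy matrix used as the fixed part of all prediction models. Treatment
#' contrasts with the first level as reference. Factor levels can be pinned
#' (for predicting new rows with the training coding); unseen levels fall
#' back to the reference level with a warning.
#'
#' @param design a design table (see [simulate_design()]).
#' @param xlev optional named list of factor levels from a training fit.
#' @param drop_constant drop factors with a single observed level (used when
#'   fitting within one treatment scope).
#' @return numeric matrix with an `xlev` attribute.
#' @export
fixed_effects_matrix <- function(design, xlev = NULL, drop_constant = TRUE) {
  stopifnot(all(design_factor_cols %in% names(design)))
  df <- design[design_factor_cols]
  for (v in design_factor_cols) {
    x <- df[[v]]
    if (!is.null(xlev) && !is.null(xlev[[v]])) {
      lev <- xlev[[v]]
      bad <- !(as.character(x) %in% lev)
      if (any(bad)) {
        warning(sprintf("%d rows of '%s' have unseen levels; using reference level", sum(bad), v))
        x <- as.character(x)
        x[bad] <- lev[1L]
      }
      df[[v]] <- factor(as.character(x), levels = lev)
    } else {
      df[[v]] <- droplevels(factor(x))
    }
  }
  use <- vapply(df, function(x) nlevels(x) >= 2L, logical(1))
  if (!drop_constant && is.null(xlev)) use[] <- TRUE
  use_vars <- design_factor_cols[use]
  if (length(use_vars) == 0L) {
    X <- matrix(1, nrow(design), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    fml <- stats::as.formula(paste("~", paste(use_vars, collapse = " + ")))
    X <- stats::model.matrix(fml, df)
  }
  attr(X, "xlev") <- lapply(df[use_vars], levels)
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  X
}

## Derive a stream of distinct 32-bit-safe seeds from one master seed.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed %% 100000L) * 10000L + 7L * seq_len(n)) %% .Machine$integer.max
}

## Pearson r^2 between two dosage vectors; 0 when either is constant.
dosage_r2 <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x, y)^2
}
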