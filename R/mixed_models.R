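## Solve V x = B for symmetric positive-definite V via Cholesky.
chol_solve <- function(V, B) {
  R <- tryCatch(chol(V), error = function(e)
    abort_megs(sprintf("coefficient matrix is singular or indefinite (rcond ~ %.2e)",
                       1 / kappa(V))))
  backsolve(R, backsolve(R, B, transpose = TRUE))
}

new_megs_fit <- function(fixed, random, varcomp, meta) {
  structure(list(fixed = fixed, random = random, varcomp = varcomp,
                 meta = meta), class = "megs_fit")
}

#' @export
print.megs_fit <- function(x, ...) {
  cat(sprintf("megs_fit (%s): n = %d\n", x$meta$method %||% "?", x$meta$n))
  cat("  variance components:",
      paste(sprintf("%s = %.4g", names(x$varcomp), x$varcomp), collapse = ", "),
      "\n")
  cat("  random components:",
      paste(sprintf("%s[%d]", names(x$random), lengths(x$random)),
            collapse = ", "), "\n")
  invisible(x)
}

#' REML for a single random component (EMMA-style spectral search)
#'
#' Fits `y = X beta + Z u + e`, `u ~ N(0, sigma2_u I)` (or, via `K`,
#' `g ~ N(0, sigma2_u K)`), by restricted maximum likelihood. The model is
#' rotated onto an orthonormal basis of the complement of `col(X)`, the
#' covariance kernel eigendecomposed once, and the variance ratio optimized
#' on a log scale over `[-10, 10]` (a bracketed golden-section/parabolic 1-D
#' search, tolerance 1e-8); the kernel is normalized to unit mean diagonal
#' internally so the search range covers the usual span of heritabilities.
#' Fixed effects are then estimated by GLS and random effects by BLUP at the
#' optimum. A rank-deficient `X` is reduced to a full-rank basis and the
#' aliased columns reported.
#'
#' @param y numeric response (no missing values).
#' @param X fixed-effect design matrix (with intercept).
#' @param Z random-effect design matrix (columns get i.i.d. variance
#'   `sigma2_u`); supply either `Z` or `K`.
#' @param K covariance kernel of the observation-level random effect
#'   (`Var = sigma2_u K`), e.g. `Z A Z'` for a genomic relationship `A`.
#' @param bounds search interval for the log variance ratio.
#' @return a `megs_fit` with elements `fixed` (GLS estimates), `random`
#'   (`u` BLUPs when `Z` given, `genetic_values` when only `K`), `varcomp`
#'   (`sigma2_u`, `sigma2_e`), `meta` (log-ratio, boundary flag, restricted
#'   log-likelihood profile, aliasing report).
#' @export
reml_single_component <- function(y, X, Z = NULL, K = NULL,
                                  bounds = c(-10, 10)) {
  assert_that(all(is.finite(y)), "y contains non-finite values")
  n <- length(y)
  if (is.null(K)) {
    assert_that(!is.null(Z) && ncol(Z) > 0, "supply Z or K")
    K <- tcrossprod(Z)
  }
  fr <- full_rank_basis(as.matrix(X))
  Xr <- fr$X; q <- ncol(Xr)
  assert_that(n > q, "need more observations than fixed-effect rank")
  cscale <- mean(diag(K))
  assert_that(cscale > 0, "degenerate (zero) covariance kernel")
  Kn <- K / cscale

  Qfull <- qr.Q(qr(Xr), complete = TRUE)
  Tb <- Qfull[, (q + 1L):n, drop = FALSE]
  eg <- eigen(crossprod(Tb, Kn %*% Tb), symmetric = TRUE)
  xi <- pmax(eg$values, 0)
  eta <- drop(crossprod(eg$vectors, crossprod(Tb, y)))
  nq <- n - q

  restricted_ll <- function(log_theta) {
    d <- exp(log_theta) * xi + 1
    s2e <- sum(eta^2 / d) / nq
    -0.5 * (nq * log(2 * pi * s2e) + sum(log(d)) + nq)
  }
  opt <- optimize(function(lt) -restricted_ll(lt),
                  interval = bounds, tol = 1e-8)
  lt <- opt$minimum
  boundary <- min(abs(lt - bounds)) < 1e-3
  ## a solution at the lower bracket end is a boundary maximum at zero
  ## variance; report it as exactly zero rather than exp(bounds[1])
  theta <- if (abs(lt - bounds[1]) < 1e-3) 0 else exp(lt)
  d <- theta * xi + 1
  sigma2_e <- sum(eta^2 / d) / nq
  sigma2_u <- theta * sigma2_e / cscale

  H <- theta * Kn + diag(n)
  Hi_y <- chol_solve(H, cbind(y, Xr))
  XtHiX <- crossprod(Xr, Hi_y[, -1, drop = FALSE])
  beta <- drop(solve(XtHiX, crossprod(Xr, Hi_y[, 1])))
  names(beta) <- fr$kept
  r <- y - drop(Xr %*% beta)
  Hir <- drop(chol_solve(H, r))
  random <- if (!is.null(Z)) {
    u <- drop(crossprod(Z, Hir)) * sigma2_u / sigma2_e
    names(u) <- colnames(Z)
    list(u = u)
  } else {
    list(genetic_values = drop(K %*% Hir) * sigma2_u / sigma2_e)
  }
  new_megs_fit(
    fixed = beta, random = random,
    varcomp = c(sigma2_u = sigma2_u, sigma2_e = sigma2_e),
    meta = list(method = "reml_single", n = n, log_theta = lt,
                theta = theta, boundary = boundary,
                reml_loglik = restricted_ll(lt),
                reml_profile = restricted_ll,
                kernel_scale = cscale,
                aliased = fr$dropped, kept = fr$kept))
}

#' ASV-effect variance by single-component REML
#'
#' Estimates the per-ASV effect variance `sigma2_gamma` by fitting the ASV
#' matrix as the only random component, with the design factors plus the
#' first genotype principal components as fixed effects to control the
#' genomic background.
#'
#' @param y phenotype vector aligned with `design`.
#' @param design plot design table.
#' @param pcs genotype PC score matrix (individuals x k); rows are matched to
#'   plots through `design$genotype`.
#' @param M observations x ASVs matrix of (centered) log abundances.
#' @return a `megs_fit`; `varcomp["sigma2_u"]` is `sigma2_gamma`.
#' @export
estimate_asv_variance <- function(y, design, pcs, M) {
  check_design(design)
  X <- fixed_effects_matrix(design)
  pc_rows <- pcs[match(as.character(design$genotype), rownames(pcs)), ,
                 drop = FALSE]
  assert_that(!anyNA(pc_rows), "PC scores missing for some design genotypes")
  reml_single_component(y, cbind(X, pc_rows), Z = M)
}

#' Two-variance-component mixed model with plug-in variances
#'
#' Solves the joint model `y = X beta + Z_snp alpha + M_asv gamma + e` with
#' `alpha ~ N(0, sigma2_alpha I)`, `gamma ~ N(0, sigma2_gamma I)` at fixed
#' (plug-in) variances, equivalent to generalized ridge regression with
#' per-block penalties `sigma2_e / sigma2_alpha` and
#' `sigma2_e / sigma2_gamma`. Two solver routes are available: the `n x n`
#' kernel system (default when columns outnumber rows) and the explicit
#' column-system mixed-model equations; they agree to numerical precision.
#' A plug-in of zero collapses that component (its effects are fixed at 0).
#'
#' @param y response vector.
#' @param X fixed-effect matrix.
#' @param Z_snp SNP dosage matrix (centered), may be `NULL`.
#' @param M_asv ASV abundance matrix (centered), may be `NULL`.
#' @param var_snp,var_asv per-column plug-in variances.
#' @param var_e residual plug-in variance (> 0).
#' @param method `"auto"`, `"kernel"` or `"columns"`.
#' @return a `megs_fit` with `random$alpha`, `random$gamma`, fitted values in
#'   `meta$fitted`.
#' @export
fit_two_component <- function(y, X, Z_snp = NULL, M_asv = NULL,
                              var_snp = 0, var_asv = 0, var_e,
                              method = c("auto", "kernel", "columns")) {
  method <- match.arg(method)
  assert_that(var_e > 0, "residual plug-in variance must be > 0")
  assert_that(all(is.finite(y)), "y contains non-finite values")
  n <- length(y)
  if (is.null(Z_snp) || var_snp <= 0) { Z_snp <- NULL; var_snp <- 0 }
  if (is.null(M_asv) || var_asv <= 0) { M_asv <- NULL; var_asv <- 0 }
  fr <- full_rank_basis(as.matrix(X))
  Xr <- fr$X
  ncols <- ncol(Xr) + NCOL(Z_snp %||% matrix(0, n, 0)) +
    NCOL(M_asv %||% matrix(0, n, 0))
  if (method == "auto") method <- if (ncols > n) "kernel" else "columns"

  if (method == "kernel") {
    V <- diag(var_e, n)
    if (!is.null(Z_snp)) V <- V + var_snp * tcrossprod(Z_snp)
    if (!is.null(M_asv)) V <- V + var_asv * tcrossprod(M_asv)
    Vi_yX <- chol_solve(V, cbind(y, Xr))
    XtViX <- crossprod(Xr, Vi_yX[, -1, drop = FALSE])
    beta <- drop(solve(XtViX, crossprod(Xr, Vi_yX[, 1])))
    r <- y - drop(Xr %*% beta)
    Vir <- drop(chol_solve(V, r))
    alpha <- if (!is.null(Z_snp)) drop(crossprod(Z_snp, Vir)) * var_snp else numeric(0)
    gamma <- if (!is.null(M_asv)) drop(crossprod(M_asv, Vir)) * var_asv else numeric(0)
  } else {
    W <- cbind(Xr, Z_snp, M_asv)
    C <- crossprod(W)
    pen <- c(rep(0, ncol(Xr)),
             rep(if (var_snp > 0) var_e / var_snp else 0, NCOL(Z_snp %||% matrix(0, n, 0))),
             rep(if (var_asv > 0) var_e / var_asv else 0, NCOL(M_asv %||% matrix(0, n, 0))))
    diag(C) <- diag(C) + pen
    sol <- drop(chol_solve(C, crossprod(W, y)))
    beta <- sol[seq_len(ncol(Xr))]
    rest <- sol[-seq_len(ncol(Xr))]
    nz <- NCOL(Z_snp %||% matrix(0, n, 0))
    alpha <- rest[seq_len(nz)]
    gamma <- rest[-seq_len(nz)] %||% numeric(0)
    if (nz == 0) { alpha <- numeric(0); gamma <- rest }
  }
  names(beta) <- fr$kept
  if (!is.null(Z_snp)) names(alpha) <- colnames(Z_snp)
  if (!is.null(M_asv)) names(gamma) <- colnames(M_asv)
  fitted <- drop(Xr %*% beta)
  if (length(alpha)) fitted <- fitted + drop(Z_snp %*% alpha)
  if (length(gamma)) fitted <- fitted + drop(M_asv %*% gamma)
  fitted <- unname(fitted)
  new_megs_fit(
    fixed = beta,
    random = list(alpha = alpha, gamma = gamma),
    varcomp = c(sigma2_alpha = var_snp, sigma2_gamma = var_asv,
                sigma2_e = var_e),
    meta = list(method = paste0("two_component/", method), n = n,
                fitted = fitted, aliased = fr$dropped, kept = fr$kept))
}

#' Microbiome-enabled prediction fit with plug-in variances
#'
#' The full plug-in scheme for the joint SNP + ASV model: estimate
#' `sigma2_alpha` (and the residual) from a SNP-only single-component REML
#' fit with the design factors fixed; estimate `sigma2_gamma` from an
#' ASV-only REML fit with design factors plus the first genotype PCs fixed;
#' then solve the two-component system at those plug-ins. With
#' `include_asv = FALSE` this reduces to the conventional SNP-only
#' ridge-regression BLUP fit.
#'
#' @param y phenotype vector aligned with `design` rows.
#' @param design plot design table.
#' @param Z plot-level centered SNP dosage matrix.
#' @param M plot-level centered ASV abundance matrix (ignored when
#'   `include_asv = FALSE`).
#' @param pcs genotype PC scores (individuals x k) for the ASV variance fit.
#' @param include_asv fit the joint model (default) or SNP-only.
#' @return a `megs_fit`; `meta$xlev` stores the factor coding for
#'   [predict.megs_fit()].
#' @export
fit_megs <- function(y, design, Z, M = NULL, pcs = NULL, include_asv = TRUE) {
  check_design(design)
  X <- fixed_effects_matrix(design)
  snp_fit <- reml_single_component(y, X, Z = Z)
  var_snp <- snp_fit$varcomp[["sigma2_u"]]
  var_e <- snp_fit$varcomp[["sigma2_e"]]
  if (include_asv) {
    assert_that(!is.null(M) && !is.null(pcs),
                "include_asv = TRUE needs M and pcs")
    asv_fit <- estimate_asv_variance(y, design, pcs, M)
    var_asv <- asv_fit$varcomp[["sigma2_u"]]
  } else {
    M <- NULL; var_asv <- 0
  }
  fit <- fit_two_component(y, X, Z_snp = Z, M_asv = M,
                           var_snp = var_snp, var_asv = var_asv,
                           var_e = var_e, method = "kernel")
  fit$meta$xlev <- attr(X, "xlev")
  fit$meta$plugin <- c(sigma2_alpha = var_snp, sigma2_gamma = var_asv,
                       sigma2_e = var_e)
  fit
}

#' Genotype-level BLUP with a genomic relationship matrix
#'
#' The conventional genomic-selection model: genotype effects are random with
#' covariance `A sigma2_g` (the additive relationship matrix), the design
#' factors are fixed, and optionally the taxonomic-group abundances enter as
#' a second identity-covariance random component (treating microbes as
#' microenvironmental covariates). Variances come from single-component REML
#' fits (genotype-only, and group-only when used), then the joint system is
#' solved at those plug-ins. BLUPs are returned for every genotype in the
#' relationship matrix, so unphenotyped genotypes are predicted through their
#' relatives.
#'
#' @param y phenotype vector aligned with `design`.
#' @param design plot design table (subset it beforehand to fit one
#'   treatment's plots, e.g. HN and LN separately).
#' @param grm a `grm` from [additive_relationship()] covering every design
#'   genotype.
#' @param asv_groups optional observations x groups abundance matrix
#'   (centered internally).
#' @return a `megs_fit` with `random$g` (all GRM genotypes) and, when groups
#'   are used, `random$gamma`.
#' @export
fit_gblup_genotype <- function(y, design, grm, asv_groups = NULL) {
  check_design(design)
  stopifnot(inherits(grm, "grm"))
  ids <- grm$individual_ids
  missing_g <- setdiff(as.character(design$genotype), ids)
  if (length(missing_g))
    abort_megs(paste("genotypes absent from the relationship matrix:",
                     paste(head(missing_g, 5), collapse = ", ")))
  X <- fixed_effects_matrix(design)
  gi <- match(as.character(design$genotype), ids)
  ZA <- grm$matrix[gi, , drop = FALSE]      # n_obs x n_geno = Zg %*% A
  K1 <- ZA[, gi, drop = FALSE]              # Zg A Zg'
  g_fit <- reml_single_component(y, X, K = K1)
  var_g <- g_fit$varcomp[["sigma2_u"]]
  var_e <- g_fit$varcomp[["sigma2_e"]]
  n <- length(y)
  if (is.null(asv_groups)) {
    V <- var_g * K1 + diag(var_e, n)
    gamma <- numeric(0); var_gamma <- 0
  } else {
    Mc <- sweep(asv_groups, 2L, colMeans(asv_groups), "-")
    grp_fit <- reml_single_component(y, X, Z = Mc)
    var_gamma <- grp_fit$varcomp[["sigma2_u"]]
    V <- var_g * K1 + var_gamma * tcrossprod(Mc) + diag(var_e, n)
  }
  fr <- full_rank_basis(X)
  Vi_yX <- chol_solve(V, cbind(y, fr$X))
  beta <- drop(solve(crossprod(fr$X, Vi_yX[, -1, drop = FALSE]),
                     crossprod(fr$X, Vi_yX[, 1])))
  names(beta) <- fr$kept
  r <- y - drop(fr$X %*% beta)
  Vir <- drop(chol_solve(V, r))
  g <- var_g * drop(crossprod(ZA, Vir))     # sigma2_g * A Zg' V^-1 r
  names(g) <- ids
  if (!is.null(asv_groups)) {
    gamma <- var_gamma * drop(crossprod(Mc, Vir))
    names(gamma) <- colnames(asv_groups)
  }
  new_megs_fit(
    fixed = beta,
    random = c(list(g = g), if (length(gamma)) list(gamma = gamma)),
    varcomp = c(sigma2_g = var_g, sigma2_gamma = var_gamma,
                sigma2_e = var_e),
    meta = list(method = "gblup", n = n, xlev = attr(X, "xlev"),
                aliased = fr$dropped, kept = fr$kept))
}

#' Predict from a fitted model
#'
#' Linear predictor on new rows: fixed effects from the stored factor coding
#' (unseen levels fall back to the reference with a warning) plus whichever
#' random components the fit carries -- `Z alpha` and `M gamma` for
#' marker/ASV fits, the per-genotype BLUP for genotype-level fits. On the
#' training rows this reproduces the fitted values exactly.
#'
#' @param object a `megs_fit`.
#' @param design new design rows (used when the fit was built from a design
#'   table); alternatively pass a ready `X`.
#' @param X optional fixed-effect matrix with the training columns.
#' @param Z new SNP matrix (same columns as training) or `NULL`.
#' @param M new ASV matrix or `NULL`.
#' @param genotype genotype ids of the new rows (genotype-level fits).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.megs_fit <- function(object, design = NULL, X = NULL,
                             Z = NULL, M = NULL, genotype = NULL, ...) {
  if (is.null(X)) {
    assert_that(!is.null(design), "supply new design rows or an X matrix")
    X <- fixed_effects_matrix(design, xlev = object$meta$xlev)
  }
  kept <- names(object$fixed)
  assert_that(all(kept %in% colnames(X)),
              "new fixed-effect matrix lacks training columns")
  pred <- drop(X[, kept, drop = FALSE] %*% object$fixed)
  a <- object$random$alpha
  if (length(a)) {
    assert_that(!is.null(Z) && identical(colnames(Z), names(a)),
                "Z columns do not match the trained SNP effects")
    pred <- pred + drop(Z %*% a)
  }
  gam <- object$random$gamma
  if (length(gam)) {
    assert_that(!is.null(M) && identical(colnames(M), names(gam)),
                "M columns do not match the trained ASV/group effects")
    pred <- pred + drop(M %*% gam)
  }
  if (!is.null(object$random[["g"]])) {
    gen <- genotype %||% (if (!is.null(design)) as.character(design$genotype))
    assert_that(!is.null(gen), "genotype-level fit needs genotype ids")
    assert_that(all(gen %in% names(object$random[["g"]])),
                "unknown genotypes in prediction rows")
    pred <- pred + object$random[["g"]][gen]
  }
  unname(pred)
}
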