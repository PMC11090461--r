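#' Genotype matrix with marker map
#'
#' Container for an individuals x markers dosage matrix (minor-allele counts
#' in \{0, 1, 2\}, `NA` for missing) together with per-marker chromosome and
#' 1-based physical position. Positions must be non-decreasing within each
#' chromosome and identifiers unique.
#'
#' @param dosages numeric matrix, individuals in rows (rownames = individual
#'   ids), markers in columns (colnames = marker ids).
#' @param chrom character/integer vector of per-marker chromosome labels.
#' @param pos integer vector of per-marker 1-based positions.
#' @return an object of class `geno_matrix` with elements `dosages` and
#'   `map` (data.frame: marker_id, chrom, pos).
#' @export
geno_matrix <- function(dosages, chrom, pos) {
  assert_that(is.matrix(dosages), "dosages must be a matrix")
  m <- ncol(dosages)
  assert_that(length(chrom) == m && length(pos) == m,
              "chrom/pos length must equal the number of markers")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(m))
  assert_that(!anyDuplicated(rownames(dosages)), "duplicated individual ids")
  assert_that(!anyDuplicated(colnames(dosages)), "duplicated marker ids")
  vals <- dosages[!is.na(dosages)]
  assert_that(all(vals %in% c(0, 1, 2)), "dosages must be 0, 1, 2 or NA")
  ord_ok <- tapply(pos, as.character(chrom), function(p) !is.unsorted(p))
  assert_that(all(unlist(ord_ok)),
              "marker positions must be non-decreasing within chromosome")
  structure(list(
    dosages = dosages,
    map = data.frame(marker_id = colnames(dosages),
                     chrom = as.character(chrom), pos = as.integer(pos),
                     stringsAsFactors = FALSE)
  ), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing rate %.3f\n", miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by markers and/or individuals
#'
#' @param geno a [geno_matrix()].
#' @param markers marker index or id vector (genomic order preserved as given).
#' @param individuals individual index or id vector.
#' @return a `geno_matrix`.
#' @export
subset_markers <- function(geno, markers = NULL, individuals = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- geno$dosages
  if (!is.null(individuals)) d <- d[individuals, , drop = FALSE]
  idx <- if (is.null(markers)) seq_len(ncol(d)) else markers
  if (is.character(idx)) idx <- match(idx, colnames(d))
  geno_matrix(d[, idx, drop = FALSE],
              geno$map$chrom[idx], geno$map$pos[idx])
}

## Mean-imputed, column-centered dosage matrix; allele freqs as attribute.
centered_dosages <- function(geno, impute = TRUE) {
  d <- geno$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  if (impute && anyNA(d)) {
    for (j in which(colSums(is.na(d)) > 0L)) d[is.na(d[, j]), j] <- 2 * p[j]
  }
  z <- sweep(d, 2L, 2 * p, "-")
  attr(z, "p") <- p
  z
}

#' Microbiome abundance table with taxonomy
#'
#' Observations (field plots) x ASV matrix of log relative abundance, plus a
#' taxonomy map assigning every ASV to exactly one taxonomic group and one
#' class (groups nest within classes), and optional per-ASV annotations
#' (e.g. heritability and selection scores from an upstream study).
#'
#' @param values numeric matrix observations x ASVs (log relative abundance);
#'   rownames are observation (plot) ids, colnames ASV ids.
#' @param taxonomy data.frame with columns `asv_id`, `group`, `class`.
#' @param annotations optional data.frame keyed by `asv_id`.
#' @return an object of class `microbiome_table`.
#' @export
microbiome_table <- function(values, taxonomy, annotations = NULL) {
  assert_that(is.matrix(values), "values must be a matrix")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("asv", seq_len(ncol(values)))
  assert_that(all(c("asv_id", "group", "class") %in% names(taxonomy)),
              "taxonomy needs asv_id, group, class columns")
  assert_that(!anyDuplicated(taxonomy$asv_id), "duplicated asv_id in taxonomy")
  assert_that(setequal(taxonomy$asv_id, colnames(values)),
              "taxonomy must cover exactly the ASVs in `values`")
  taxonomy <- taxonomy[match(colnames(values), taxonomy$asv_id), ]
  g2c <- unique(taxonomy[c("group", "class")])
  assert_that(!anyDuplicated(g2c$group), "each group must nest in one class")
  structure(list(values = values, taxonomy = taxonomy,
                 annotations = annotations),
            class = "microbiome_table")
}

#' @export
print.microbiome_table <- function(x, ...) {
  cat(sprintf("microbiome_table: %d observations x %d ASVs (%d groups, %d classes)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$taxonomy$group)),
              length(unique(x$taxonomy$class))))
  invisible(x)
}

#' @export
dim.microbiome_table <- function(x) dim(x$values)

## Validate that a design table has the expected plot-level columns.
check_design <- function(design) {
  need <- c("plot_id", "genotype", design_factor_cols, "quadrant")
  assert_that(all(need %in% names(design)),
              paste("design table must have columns:", paste(need, collapse = ", ")))
  assert_that(!anyDuplicated(design$plot_id), "duplicated plot_id in design")
  invisible(design)
}

## Check observation alignment between design rows and a microbiome table.
check_alignment <- function(design, micro) {
  ok <- identical(as.character(design$plot_id), rownames(micro$values))
  if (!ok) {
    bad <- which(as.character(design$plot_id) != rownames(micro$values))[1]
    abort_megs(sprintf(
      "design and microbiome rows are misaligned (first mismatch at row %d: '%s' vs '%s')",
      bad, design$plot_id[bad], rownames(micro$values)[bad]))
  }
  invisible(TRUE)
}
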