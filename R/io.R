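#' Write a genotype matrix as TSV (plus marker map sidecar)
#'
#' The dosage file has individuals in rows, one header line of marker ids;
#' the sidecar has columns marker_id, chrom, pos.
#'
#' @param geno a [geno_matrix()].
#' @param file path of the dosage TSV.
#' @param map_file path of the marker map sidecar (default `<file>.map.tsv`).
#' @return invisibly, the two paths.
#' @export
write_geno_tsv <- function(geno, file, map_file = paste0(file, ".map.tsv")) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- data.frame(individual_id = rownames(geno$dosages), geno$dosages,
                  check.names = FALSE)
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(geno$map, map_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(file, map_file))
}

#' Read a genotype matrix from TSV + marker map sidecar
#'
#' @param file dosage TSV written by [write_geno_tsv()].
#' @param map_file marker map sidecar.
#' @return a [geno_matrix()].
#' @export
read_geno_tsv <- function(file, map_file = paste0(file, ".map.tsv")) {
  d <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  map <- read.table(map_file, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- d[[1]]
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- ids
  assert_that(identical(colnames(mat), as.character(map$marker_id)),
              "marker ids in dosage file and map sidecar disagree")
  geno_matrix(mat, map$chrom, map$pos)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits unphased GT calls (`0/0`, `0/1`, `1/1`, `./.`) with REF=A, ALT=T
#' placeholder alleles; dosage counts the ALT (minor) allele.
#'
#' @param geno a [geno_matrix()].
#' @param file output path (uncompressed `.vcf`).
#' @return invisibly, `file`.
#' @export
write_geno_vcf <- function(geno, file) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- geno$dosages
  gt <- matrix("./.", ncol(d), nrow(d))
  codes <- c("0/0", "0/1", "1/1")
  ok <- !is.na(t(d))
  gt[ok] <- codes[t(d)[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- cbind(geno$map$chrom, geno$map$pos, geno$map$marker_id,
                "A", "T", ".", "PASS", ".", "GT", gt)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(file)
}

#' Read a VCF into a genotype matrix
#'
#' Parses GT fields of bi-allelic rows into minor(ALT)-allele dosages;
#' multi-allelic rows are skipped with a warning. Requires the `vcfR`
#' package for parsing.
#'
#' @param file path to an (uncompressed or gzipped) VCF.
#' @return a [geno_matrix()].
#' @export
read_geno_vcf <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort_megs("read_geno_vcf requires the 'vcfR' package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  alt <- vcfR::getALT(v)
  biallelic <- !grepl(",", alt) & nzchar(alt)
  if (any(!biallelic))
    warning(sprintf("skipping %d multi-allelic/invalid VCF rows", sum(!biallelic)))
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- vcfR::getFIX(v)[biallelic, , drop = FALSE]
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    known <- !is.na(g) & !grepl("\\.", g)
    out[known] <- vapply(strsplit(g[known], "[/|]"),
                         function(a) sum(a == "1"), numeric(1))
    out
  }
  dos <- t(apply(gt, 1L, count_alt))
  colnames(dos) <- colnames(gt)
  mat <- t(dos)
  colnames(mat) <- fix[, "ID"]
  geno_matrix(mat, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
}

#' Write a microbiome table (abundances + taxonomy + annotations) as TSV
#'
#' @param micro a [microbiome_table()].
#' @param file abundance TSV (observations x ASVs).
#' @param taxonomy_file taxonomy sidecar TSV.
#' @return invisibly, the written paths.
#' @export
write_microbiome_tsv <- function(micro, file,
                                 taxonomy_file = paste0(file, ".tax.tsv")) {
  stopifnot(inherits(micro, "microbiome_table"))
  d <- data.frame(observation_id = rownames(micro$values), micro$values,
                  check.names = FALSE)
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(micro$taxonomy, taxonomy_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(file, taxonomy_file))
}

#' Read a microbiome table from TSV
#'
#' @param file abundance TSV written by [write_microbiome_tsv()].
#' @param taxonomy_file taxonomy sidecar.
#' @return a [microbiome_table()].
#' @export
read_microbiome_tsv <- function(file, taxonomy_file = paste0(file, ".tax.tsv")) {
  d <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  tax <- read.table(taxonomy_file, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- d[[1]]
  microbiome_table(mat, tax)
}

#' Serialize a model fit to JSON
#'
#' Writes fixed effects, variance components and fit metadata; random-effect
#' BLUP vectors are written to a TSV sidecar (one file per component), since
#' they can be long.
#'
#' @param fit a `megs_fit`.
#' @param file output path for the JSON; sidecars are written next to it as
#'   `<file>.<component>.tsv`.
#' @return invisibly, the written paths.
#' @export
write_fit_json <- function(fit, file) {
  stopifnot(inherits(fit, "megs_fit"))
  meta <- fit$meta
  meta$fitted <- NULL
  meta$reml_profile <- NULL
  out <- list(fixed = as.list(fit$fixed),
              varcomp = as.list(fit$varcomp),
              random_components = lapply(fit$random, length),
              meta = meta)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths <- file
  for (nm in names(fit$random)) {
    if (!length(fit$random[[nm]])) next
    side <- paste0(file, ".", nm, ".tsv")
    write.table(data.frame(id = names(fit$random[[nm]]) %||%
                             seq_along(fit$random[[nm]]),
                           blup = unname(fit$random[[nm]])),
                side, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, side)
  }
  invisible(paths)
}

#' Serialize a truth bundle to JSON
#'
#' @param truth a truth bundle from [simulate_phenotype()].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_truth_json <- function(truth, file) {
  out <- truth
  out$components <- NULL  # bulky per-plot decomposition stays in memory
  # named numeric vectors would serialize as bare arrays; keep their names
  for (nm in c("true_alpha", "true_gamma", "variance_shares"))
    if (!is.null(out[[nm]])) out[[nm]] <- as.list(out[[nm]])
  out$true_B <- lapply(out$true_B, function(b) if (is.null(b)) NULL else b)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(file)
}
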