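#' Genotype matrix container
#'
#' Wraps a samples x SNPs matrix of additive minor-allele codes (0, 1, 2 or
#' `NA` for missing calls) together with per-SNP metadata.  Codes count minor
#' alleles, so the slope of the eQTL model is expressed per minor allele.
#'
#' @param codes Numeric matrix, samples in rows, SNPs in columns.  Row names
#'   are sample IDs, column names SNP IDs.  Entries must be 0, 1, 2 or `NA`.
#' @param snps Data frame with one row per SNP: `snp_id`, `chrom`,
#'   `pos` (1-based base pairs), `ref`, `alt`.  Summary columns (`maf`,
#'   `missing_fraction`, `hwe_p`) are recomputed by [snp_stats()].
#' @return An object of class `genotype_matrix`.
#' @seealso [snp_stats()], [qc_genotypes()]
#' @export
genotype_matrix <- function(codes, snps) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes)) || is.null(colnames(codes))) {
    stop("`codes` needs sample row names and SNP column names", call. = FALSE)
  }
  snps <- tibble::as_tibble(snps)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)))
  if (!identical(colnames(codes), as.character(snps$snp_id))) {
    stop("column order of `codes` must match `snps$snp_id`", call. = FALSE)
  }
  bad <- codes[!is.na(codes) & !(codes %in% c(0, 1, 2))]
  if (length(bad) > 0) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (anyDuplicated(rownames(codes)) || anyDuplicated(colnames(codes))) {
    stop("duplicated sample or SNP IDs", call. = FALSE)
  }
  structure(list(codes = codes, snps = snps), class = "genotype_matrix")
}

#' Per-SNP summary statistics
#'
#' Recomputes minor-allele frequency, missing fraction and the exact
#' Hardy-Weinberg P-value for every SNP, on complete genotypes only.
#' MAF is always reported on the minor allele, i.e. in `[0, 0.5]`.
#'
#' @param g A [genotype_matrix()].
#' @return `g` with `maf`, `missing_fraction` and `hwe_p` columns refreshed
#'   in its `snps` metadata.
#' @export
snp_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  codes <- g$codes
  n <- nrow(codes)
  n_obs <- colSums(!is.na(codes))
  miss <- 1 - n_obs / n
  # allele frequency of the coded (alt) allele among observed calls
  p_alt <- ifelse(n_obs > 0, colSums(codes, na.rm = TRUE) / (2 * n_obs), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  hwe <- vapply(seq_len(ncol(codes)), function(j) {
    x <- codes[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  g$snps$maf <- maf
  g$snps$missing_fraction <- miss
  g$snps$hwe_p <- hwe
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d SNPs (%.2f%% missing)\n",
    nrow(x$codes), ncol(x$codes), 100 * mean(is.na(x$codes))
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a genotype matrix into long format
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `snp_id`, `code`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble::as_tibble(x$codes, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "snp_id", values_to = "code")
}

#' Expression matrix container
#'
#' Wraps a probes x samples matrix of log2-scale expression values with a
#' probe-to-gene map and per-sample metadata (covariates such as gender, and
#' processing batch).
#'
#' @param values Numeric matrix, probes in rows, samples in columns, with
#'   probe row names and sample column names.
#' @param probe_map Data frame `probe_id`, `gene_id`; one row per probe.
#' @param samples Optional data frame of per-sample metadata with a
#'   `sample_id` column (e.g. `gender` coded 0/1, `batch`).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probe_map = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs probe row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicated probe or sample IDs", call. = FALSE)
  }
  if (is.null(probe_map)) {
    probe_map <- tibble::tibble(probe_id = rownames(values), gene_id = rownames(values))
  }
  probe_map <- tibble::as_tibble(probe_map)
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  if (!all(rownames(values) %in% probe_map$probe_id)) {
    stop("every probe needs a row in `probe_map`", call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = colnames(values))
  }
  samples <- tibble::as_tibble(samples)
  stopifnot("sample_id" %in% names(samples))
  structure(
    list(values = values, probe_map = probe_map, samples = samples),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d probes x %d samples\n",
    nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Tidy an expression matrix into long format
#'
#' @param x An [expression_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `probe_id`, `gene_id`, `sample_id`, `value`.
#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "probe_id") |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id", values_to = "value") |>
    dplyr::left_join(x$probe_map, by = "probe_id") |>
    dplyr::select("probe_id", "gene_id", "sample_id", "value")
}
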