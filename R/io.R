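#' @title Read and write the pipeline's tabular formats
#' @description Plain-text interchange: dosage TSV and VCF for genotypes,
#'   TSV for expression / coordinates / edges / eQTL results, BED for
#'   hotspots, GMT for gene-set annotations.
#' @name transreg-io
NULL

#' Write genotypes as a dosage TSV
#'
#' One row per SNP: `snp_id`, `chrom`, `pos`, `ref`, `alt`, then one
#' 0/1/2/NA column per sample.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- dplyr::bind_cols(
    g$snps[, c("snp_id", "chrom", "pos", "ref", "alt")],
    tibble::as_tibble(t(g$codes))
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read genotypes from a dosage TSV
#'
#' @param path File written by [write_dosage_tsv()].
#' @return A [genotype_matrix()] with refreshed SNP statistics.
#' @export
read_dosage_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt")
  codes <- t(as.matrix(tab[, setdiff(names(tab), meta_cols)]))
  colnames(codes) <- tab$snp_id
  snp_stats(genotype_matrix(codes, tab[, meta_cols]))
}

#' Write genotypes as a minimal VCF v4.2 (GT field)
#'
#' Missing codes become `./.`; codes 0/1/2 become `0/0`, `0/1`, `1/1` on
#' the ALT (minor-coded) allele.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt_map <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  samples <- rownames(g$codes)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- vapply(seq_len(ncol(g$codes)), function(j) {
    gts <- g$codes[, j]
    gt <- ifelse(is.na(gts), "./.", gt_map[as.character(gts)])
    paste(c(g$snps$chrom[j], g$snps$pos[j], g$snps$snp_id[j],
            g$snps$ref[j], g$snps$alt[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a biallelic-SNP VCF into a genotype matrix
#'
#' Parses the GT field of an uncompressed VCF; any genotype containing a
#' missing allele becomes `NA`, otherwise the code is the ALT-allele count.
#' Multi-allelic records are rejected.
#'
#' @param path Path to a `.vcf` file.
#' @return A [genotype_matrix()] with refreshed SNP statistics.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"]))) {
    stop("multi-allelic records unsupported", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    alleles <- strsplit(gsub("\\|", "/", x), "/")
    vapply(alleles, function(a) {
      if (length(a) == 0 || any(is.na(a)) || any(a == ".")) NA_real_
      else sum(a == "1")
    }, numeric(1))
  }
  codes <- apply(gt, 2, count_alt)
  if (nrow(gt) == 1) codes <- matrix(codes, nrow = 1, dimnames = dimnames(gt))
  codes <- t(codes)
  colnames(codes) <- fix[, "ID"]
  snps <- tibble::tibble(
    snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.numeric(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"]
  )
  snp_stats(genotype_matrix(codes, snps))
}

#' Write / read an expression TSV (probes x samples)
#'
#' @param x An [expression_matrix()].
#' @param path File path.
#' @return `path` invisibly (write) or an [expression_matrix()] (read; the
#'   probe map defaults to probe = gene and can be re-attached from a probe
#'   map TSV).
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  readr::write_tsv(tibble::as_tibble(x$values, rownames = "probe_id"), path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  vals <- as.matrix(tab[, -1])
  rownames(vals) <- tab[[1]]
  expression_matrix(vals)
}

#' Write / read hotspot intervals as BED (0-based half-open)
#'
#' @param hotspots Tibble `chrom`, `start`, `end`.
#' @param path File path.
#' @return `path` invisibly (write) or the tibble (read).
#' @export
write_bed <- function(hotspots, path) {
  readr::write_tsv(hotspots[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                  show_col_types = FALSE)
}

#' Write / read gene-set annotations in GMT format
#'
#' One line per category: category, description, then member genes,
#' tab-separated.
#'
#' @param annotation Tibble `category_id`, `gene_id`.
#' @param path File path.
#' @return `path` invisibly (write) or the annotation tibble (read).
#' @export
write_gmt <- function(annotation, path) {
  annotation <- tibble::as_tibble(annotation)
  lines <- annotation |>
    dplyr::group_by(.data$category_id) |>
    dplyr::summarise(line = paste(c(.data$category_id[1], "synthetic",
                                    .data$gene_id), collapse = "\t"),
                     .groups = "drop")
  writeLines(lines$line, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  purrr::imap_dfr(sets, function(genes, cat) {
    tibble::tibble(category_id = cat, gene_id = genes)
  })
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits every interchange file the pipeline consumes: `dosage.tsv`,
#' `genotypes.vcf`, `expression.tsv`, `gene_coords.tsv`, `edges.tsv`,
#' `annotation.gmt` and `truth.yaml`.
#'
#' @param sim Output of [sim_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dosage_tsv(sim$genotypes, file.path(dir, "dosage.tsv"))
  write_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  write_expression_tsv(sim$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(sim$gene_coords, file.path(dir, "gene_coords.tsv"))
  readr::write_tsv(sim$edges, file.path(dir, "edges.tsv"))
  if (nrow(sim$annotation) > 0) {
    write_gmt(sim$annotation, file.path(dir, "annotation.gmt"))
  }
  yaml::write_yaml(
    list(
      modules = split(sim$truth$modules$gene_id, sim$truth$modules$module_id),
      effects = as.list(sim$truth$effects),
      enriched = as.list(sim$truth$enriched)
    ),
    file.path(dir, "truth.yaml")
  )
  invisible(dir)
}
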