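#' Partition chromosomes into recombination-hotspot-delimited loci
#'
#' Reduces each hotspot interval to its midpoint and cuts the chromosome at
#' those points: a chromosome with k hotspots yields k + 1 loci that tile it
#' exactly.  All coordinates are BED-style 0-based half-open.  Overlapping
#' hotspots are merged (with a warning) before midpoints are taken.
#'
#' @param hotspots Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param chrom_sizes Tibble `chrom`, `size` in bp; every chromosome listed
#'   here is partitioned (those without hotspots become a single locus).
#' @return A `loci_partition`: tibble `locus_id`, `chrom`, `start`, `end`
#'   (0-based half-open), sorted, disjoint and gap-free per chromosome.
#' @examples
#' partition_loci(
#'   data.frame(chrom = "chr1", start = c(99, 199), end = c(101, 201)),
#'   data.frame(chrom = "chr1", size = 300)
#' )
#' @export
partition_loci <- function(hotspots, chrom_sizes) {
  hotspots <- tibble::as_tibble(hotspots)
  chrom_sizes <- tibble::as_tibble(chrom_sizes)
  stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
  if (nrow(hotspots) > 0) {
    stopifnot(all(c("chrom", "start", "end") %in% names(hotspots)))
    if (!all(hotspots$chrom %in% chrom_sizes$chrom)) {
      stop("hotspot on a chromosome absent from chrom_sizes", call. = FALSE)
    }
  }
  out <- purrr::pmap_dfr(chrom_sizes, function(chrom, size) {
    hs <- hotspots[hotspots$chrom == chrom, , drop = FALSE]
    if (nrow(hs) > 0 && (any(hs$start < 0) || any(hs$end > size))) {
      stop("hotspot outside chromosome bounds on ", chrom, call. = FALSE)
    }
    cuts <- numeric(0)
    if (nrow(hs) > 0) {
      hs <- hs[order(hs$start), , drop = FALSE]
      merged <- list()
      cur <- c(hs$start[1], hs$end[1])
      if (nrow(hs) > 1) {
        for (i in 2:nrow(hs)) {
          if (hs$start[i] < cur[2]) {
            warning("overlapping hotspots merged on ", chrom, call. = FALSE)
            cur[2] <- max(cur[2], hs$end[i])
          } else {
            merged[[length(merged) + 1]] <- cur
            cur <- c(hs$start[i], hs$end[i])
          }
        }
      }
      merged[[length(merged) + 1]] <- cur
      cuts <- vapply(merged, function(iv) floor((iv[1] + iv[2]) / 2), numeric(1))
      cuts <- cuts[cuts > 0 & cuts < size]
    }
    bounds <- c(0, sort(unique(cuts)), size)
    tibble::tibble(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1]
    )
  })
  out <- dplyr::mutate(out, locus_id = sprintf("L%05d", dplyr::row_number()),
                       .before = 1)
  class(out) <- c("loci_partition", class(out))
  out
}

#' Map SNPs to hotspot-delimited loci
#'
#' Assigns each SNP the unique locus whose half-open interval contains its
#' 0-based position; a position exactly on a boundary belongs to the
#' right-hand locus.
#'
#' @param snps Tibble `snp_id`, `chrom`, `pos`.
#' @param part A `loci_partition` from [partition_loci()].
#' @param based Coordinate base of `pos`: 1 (VCF/dosage convention, the
#'   default; converted internally) or 0.
#' @return Tibble `snp_id`, `chrom`, `pos`, `locus_id`.
#' @export
map_snps_to_loci <- function(snps, part, based = 1L) {
  snps <- tibble::as_tibble(snps)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)), based %in% c(0L, 1L))
  if (!all(snps$chrom %in% part$chrom)) {
    stop("SNP on a chromosome absent from the partition: ",
         paste(setdiff(snps$chrom, part$chrom), collapse = ", "), call. = FALSE)
  }
  pos0 <- snps$pos - based
  locus <- character(nrow(snps))
  for (ch in unique(snps$chrom)) {
    pp <- part[part$chrom == ch, , drop = FALSE]
    i <- snps$chrom == ch
    j <- findInterval(pos0[i], pp$start)
    if (any(j == 0) || any(pos0[i] >= pp$end[nrow(pp)])) {
      stop("SNP position outside the partitioned chromosome ", ch, call. = FALSE)
    }
    locus[i] <- pp$locus_id[j]
  }
  dplyr::mutate(snps[, c("snp_id", "chrom", "pos")], locus_id = locus)
}

#' Transcript Complexity Value of a gene
#'
#' The TCV counts the distinct hotspot-delimited independent loci harboring
#' at least one significant eQTL for the gene: `cis_tcv` over cis-labeled
#' associations at nominal P below `cis_alpha`, `trans_tcv` over
#' trans-labeled associations below `trans_alpha`.  Multiple transcripts of
#' one gene contribute by union of their significant loci; duplicate
#' records are harmless.
#'
#' @param results eQTL result tibble (from [tidy.eqtl_scan()]) containing at
#'   least `gene_id`, `snp_id`, `p_value`, `label`.
#' @param snp_loci SNP-to-locus map from [map_snps_to_loci()].
#' @param genes Genes to profile; default all genes in `results`.
#' @param cis_alpha,trans_alpha Nominal significance thresholds (defaults
#'   0.05 and 1e-5: trans claims demand far stronger evidence).
#' @return Tibble `gene_id`, `cis_tcv`, `trans_tcv`.
#' @export
compute_tcv <- function(results, snp_loci, genes = NULL, cis_alpha = 0.05,
                        trans_alpha = 1e-5) {
  stopifnot(cis_alpha > 0, cis_alpha < 1, trans_alpha > 0, trans_alpha < 1)
  results <- tibble::as_tibble(results)
  if (is.null(genes)) genes <- sort(unique(results$gene_id))
  missing_genes <- setdiff(genes, results$gene_id)
  if (length(missing_genes) > 0) {
    stop("no tested transcript for gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  res <- results |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::left_join(snp_loci[, c("snp_id", "locus_id")], by = "snp_id")
  if (anyNA(res$locus_id)) {
    stop("some result SNPs are absent from the locus map", call. = FALSE)
  }
  counts <- res |>
    dplyr::filter(
      (.data$label == "cis" & .data$p_value < cis_alpha) |
        (.data$label == "trans" & .data$p_value < trans_alpha)
    ) |>
    dplyr::distinct(.data$gene_id, .data$label, .data$locus_id) |>
    dplyr::count(.data$gene_id, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  for (col in c("cis", "trans")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  tibble::tibble(gene_id = genes) |>
    dplyr::left_join(counts, by = "gene_id") |>
    dplyr::mutate(
      cis_tcv = dplyr::coalesce(.data$cis, 0L),
      trans_tcv = dplyr::coalesce(.data$trans, 0L)
    ) |>
    dplyr::select("gene_id", "cis_tcv", "trans_tcv")
}

#' Compare a gene's regulatory profile between two cell types
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[cis_a, trans_a], [cis_b, trans_b]]` of locus counts; a degenerate
#' margin (zero row or column) gives P = 1.
#'
#' @param cis_a,trans_a TCVs in cell type A.
#' @param cis_b,trans_b TCVs in cell type B.
#' @param alpha Flagging threshold (default 0.05).
#' @return One-row tibble: the four counts, `p_value`, `flagged`.
#' @export
compare_profiles <- function(cis_a, trans_a, cis_b, trans_b, alpha = 0.05) {
  counts <- c(cis_a, trans_a, cis_b, trans_b)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (sum(counts) == 0) {
    stop("at least one nonzero count required", call. = FALSE)
  }
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    1
  } else {
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  tibble::tibble(
    cis_a = cis_a, trans_a = trans_a, cis_b = cis_b, trans_b = trans_b,
    p_value = p, flagged = p < alpha
  )
}

#' Differential-regulation comparison across two cell types
#'
#' Computes per-gene cis/trans TCVs in both cell types and tests each gene's
#' 2x2 locus-count table with Fisher's exact test.  Both eQTL result
#' streams must come from scans over the identical SNP set; otherwise locus
#' counts would not be comparable and the call errors.
#'
#' @param results_a,results_b eQTL result tibbles for cell types A and B
#'   (same columns as [tidy.eqtl_scan()]).
#' @param snp_loci SNP-to-locus map covering the common SNP set.
#' @param genes Genes to compare; default the genes present in both streams.
#' @param cis_alpha,trans_alpha Passed to [compute_tcv()].
#' @param alpha Flagging threshold.
#' @return Tibble per gene: TCVs in both cell types, `p_value`, `flagged`;
#'   sorted by `p_value`.
#' @export
run_comparison <- function(results_a, results_b, snp_loci, genes = NULL,
                           cis_alpha = 0.05, trans_alpha = 1e-5,
                           alpha = 0.05) {
  results_a <- tibble::as_tibble(results_a)
  results_b <- tibble::as_tibble(results_b)
  snps_a <- sort(unique(results_a$snp_id))
  snps_b <- sort(unique(results_b$snp_id))
  if (!identical(snps_a, snps_b)) {
    stop("the two result streams were not computed on the identical SNP set (",
         length(setdiff(snps_a, snps_b)), " / ",
         length(setdiff(snps_b, snps_a)), " exclusive SNPs)", call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- intersect(unique(results_a$gene_id), unique(results_b$gene_id))
  }
  missing_b <- setdiff(genes, results_b$gene_id)
  if (length(missing_b) > 0) {
    stop("gene(s) untested in stream B: ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  }
  missing_a <- setdiff(genes, results_a$gene_id)
  if (length(missing_a) > 0) {
    stop("gene(s) untested in stream A: ", paste(missing_a, collapse = ", "),
         call. = FALSE)
  }
  tcv_a <- compute_tcv(results_a, snp_loci, genes, cis_alpha, trans_alpha)
  tcv_b <- compute_tcv(results_b, snp_loci, genes, cis_alpha, trans_alpha)
  purrr::map_dfr(seq_along(genes), function(i) {
    ca <- tcv_a$cis_tcv[i]; ta <- tcv_a$trans_tcv[i]
    cb <- tcv_b$cis_tcv[i]; tb <- tcv_b$trans_tcv[i]
    row <- if (ca + ta + cb + tb == 0) {
      tibble::tibble(cis_a = ca, trans_a = ta, cis_b = cb, trans_b = tb,
                     p_value = 1, flagged = FALSE)
    } else {
      compare_profiles(ca, ta, cb, tb, alpha = alpha)
    }
    dplyr::mutate(row, gene_id = genes[i], .before = 1)
  }) |>
    dplyr::arrange(.data$p_value)
}

#' Restrict two genotype matrices to their shared SNP set
#'
#' A comparative analysis must score the exact same polymorphisms in both
#' cell types; SNPs exclusive to either matrix are dropped.
#'
#' @param a,b [genotype_matrix()] objects.
#' @return List with restricted `a`, `b` and `report` (counts of shared and
#'   excluded SNPs).
#' @export
restrict_to_shared_snps <- function(a, b) {
  stopifnot(inherits(a, "genotype_matrix"), inherits(b, "genotype_matrix"))
  shared <- intersect(a$snps$snp_id, b$snps$snp_id)
  report <- tibble::tibble(
    set = c("a_total", "b_total", "excluded_from_a", "excluded_from_b", "shared"),
    n = c(nrow(a$snps), nrow(b$snps),
          nrow(a$snps) - length(shared), nrow(b$snps) - length(shared),
          length(shared))
  )
  list(
    a = genotype_matrix(a$codes[, shared, drop = FALSE],
                        a$snps[match(shared, a$snps$snp_id), ]),
    b = genotype_matrix(b$codes[, shared, drop = FALSE],
                        b$snps[match(shared, b$snps$snp_id), ]),
    report = report
  )
}
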