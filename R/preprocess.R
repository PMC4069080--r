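#' Re-annotate microarray probes against a transcript map
#'
#' Applies the probe-retention rule used when refreshing an expression
#' array's annotation against a current transcript database:
#' * probes mapping exactly one transcript are kept;
#' * probes mapping several transcripts are kept only when all transcripts
#'   belong to one gene (the probe is assigned that gene);
#' * unmapped probes and cross-gene multi-mappers are dropped.
#'
#' @param probe_map Data frame with columns `probe_id`, `transcript_id`,
#'   `gene_id`; one row per probe-transcript mapping.  A probe with no
#'   mapping is represented by a single row with `NA` transcript and gene.
#' @return A list with `map` (tibble `probe_id`, `gene_id` of retained
#'   probes) and `report` (tibble of category counts: unique-mapping,
#'   multi-mapping same gene, multi-mapping cross gene, unmapped, kept).
#' @examples
#' pm <- data.frame(
#'   probe_id = c("p1", "p2", "p2", "p3", "p3", "p4"),
#'   transcript_id = c("t1", "t2", "t3", "t4", "t5", NA),
#'   gene_id = c("gA", "gB", "gB", "gC", "gD", NA)
#' )
#' update_probe_annotation(pm)$report
#' @export
update_probe_annotation <- function(probe_map) {
  probe_map <- tibble::as_tibble(probe_map)
  stopifnot(nrow(probe_map) > 0,
            all(c("probe_id", "transcript_id", "gene_id") %in% names(probe_map)))
  per_probe <- probe_map |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      n_tx = sum(!is.na(.data$transcript_id)),
      n_gene = dplyr::n_distinct(.data$gene_id[!is.na(.data$gene_id)]),
      gene_id = if (dplyr::n_distinct(.data$gene_id[!is.na(.data$gene_id)]) == 1)
        .data$gene_id[!is.na(.data$gene_id)][1] else NA_character_,
      .groups = "drop"
    ) |>
    dplyr::mutate(category = dplyr::case_when(
      .data$n_tx == 0 ~ "unmapped",
      .data$n_tx == 1 ~ "unique",
      .data$n_gene == 1 ~ "multi_same_gene",
      TRUE ~ "multi_cross_gene"
    ))
  kept <- per_probe |>
    dplyr::filter(.data$category %in% c("unique", "multi_same_gene")) |>
    dplyr::select("probe_id", "gene_id")
  counts <- table(factor(per_probe$category,
                         levels = c("unique", "multi_same_gene",
                                    "multi_cross_gene", "unmapped")))
  report <- tibble::tibble(
    category = c(names(counts), "kept"),
    n = c(as.integer(counts), nrow(kept))
  )
  list(map = kept, report = report)
}

#' Log2 transform and quantile-normalize an expression matrix
#'
#' Classic quantile normalization: values are ranked within each sample and
#' replaced by the across-sample mean of the corresponding order statistics;
#' ties receive the mean of the order-statistic means they span.  After
#' normalization, the sorted value vector of every sample is identical.
#'
#' @param x An [expression_matrix()] or plain probes x samples matrix.
#' @param log2_already Set to `TRUE` when `x` is already on the log2 scale;
#'   otherwise values must be strictly positive and are log2-transformed
#'   first.
#' @return Object of the same type with normalized values.
#' @export
quantile_normalize_log2 <- function(x, log2_already = FALSE) {
  vals <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  if (!log2_already) {
    if (any(vals <= 0, na.rm = TRUE)) {
      stop("raw intensities must be strictly positive for log2 transform",
           call. = FALSE)
    }
    vals <- log2(vals)
  }
  norm <- limma::normalizeQuantiles(vals, ties = TRUE)
  dimnames(norm) <- dimnames(vals)
  if (inherits(x, "expression_matrix")) {
    x$values <- norm
    x
  } else {
    norm
  }
}

#' Location-scale batch adjustment
#'
#' Removes additive and multiplicative batch effects per gene: within each
#' batch, values are centred to the gene's grand mean and the batch SD is
#' rescaled to the pooled (batch-centred) SD.  Genes with zero variance in a
#' batch are centred only.  This is a non-shrinkage location-scale
#' adjustment; it assumes each batch holds enough samples for a stable SD.
#'
#' @param x An [expression_matrix()] or probes x samples matrix.
#' @param batches Batch label per sample.  Defaults to the `batch` column of
#'   the sample metadata when `x` is an [expression_matrix()].
#' @return Object of the same type with adjusted values.
#' @export
batch_adjust <- function(x, batches = NULL) {
  vals <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  if (is.null(batches) && inherits(x, "expression_matrix")) {
    batches <- x$samples$batch
  }
  stopifnot(length(batches) == ncol(vals))
  batches <- as.character(batches)
  tab <- table(batches)
  if (any(tab < 2)) {
    stop("every batch needs at least 2 samples", call. = FALSE)
  }
  out <- vals
  grand <- rowMeans(vals)
  # pooled SD of batch-centred residuals per gene
  centred <- vals
  for (b in names(tab)) {
    idx <- which(batches == b)
    centred[, idx] <- vals[, idx] - rowMeans(vals[, idx, drop = FALSE])
  }
  n <- ncol(vals)
  k <- length(tab)
  pooled_sd <- sqrt(rowSums(centred^2) / pmax(n - k, 1))
  for (b in names(tab)) {
    idx <- which(batches == b)
    bm <- rowMeans(vals[, idx, drop = FALSE])
    bs <- apply(vals[, idx, drop = FALSE], 1, stats::sd)
    scale_f <- ifelse(bs > 0, pooled_sd / bs, 1)
    out[, idx] <- (vals[, idx, drop = FALSE] - bm) * scale_f + grand
  }
  if (inherits(x, "expression_matrix")) {
    x$values <- out
    x
  } else {
    out
  }
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on observed genotype counts using the
#' Levene-Haldane distribution of the heterozygote count conditional on the
#' allele counts: the P-value is the sum of probabilities of all
#' heterozygote counts whose probability does not exceed that of the
#' observed count.
#'
#' @param n_AA,n_Aa,n_aa Observed counts of the three genotype classes.
#' @return The exact two-sided P-value in (0, 1].
#' @examples
#' hwe_exact_test(1, 0, 1)   # 1/3
#' hwe_exact_test(10, 0, 0)  # monomorphic: 1
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one observed genotype required", call. = FALSE)
  n_a <- 2 * n_aa + n_Aa       # rare-allele count (orientation irrelevant)
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    hom_rare <- (n_minor - h) / 2
    hom_common <- n - h - hom_rare
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
      lgamma(hom_common + 1) + h * log(2) +
      lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp)
  p <- p / sum(p)              # guard against accumulated rounding
  obs <- min(n_Aa, n_minor)
  p_obs <- p[match(obs, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Drops SNPs exceeding the missingness threshold and SNPs deviating from
#' Hardy-Weinberg equilibrium at the given significance level (exact test on
#' complete genotypes).  Filters are evaluated on the input, so a SNP can
#' fail both; the report counts each filter and the overlap, and reconciles
#' with the output dimension.
#'
#' @param g A [genotype_matrix()].
#' @param miss_max Maximum tolerated missing fraction (SNPs strictly above
#'   are removed; default 0.10).
#' @param hwe_alpha HWE significance threshold (SNPs with P below are
#'   removed; default 1e-5).
#' @return A list with `genotypes` (filtered [genotype_matrix()], statistics
#'   refreshed) and `report` (tibble: filter, threshold, n_removed;
#'   including the overlap and the retained count).
#' @export
qc_genotypes <- function(g, miss_max = 0.10, hwe_alpha = 1e-5) {
  stopifnot(inherits(g, "genotype_matrix"), ncol(g$codes) > 0)
  if (miss_max < 0 || miss_max > 1 || hwe_alpha < 0 || hwe_alpha > 1) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  g <- snp_stats(g)
  fail_miss <- g$snps$missing_fraction > miss_max
  fail_hwe <- !is.na(g$snps$hwe_p) & g$snps$hwe_p < hwe_alpha
  drop <- fail_miss | fail_hwe
  report <- tibble::tibble(
    filter = c("missingness", "hwe", "overlap_both", "removed_total", "kept"),
    threshold = c(miss_max, hwe_alpha, NA, NA, NA),
    n = c(sum(fail_miss), sum(fail_hwe), sum(fail_miss & fail_hwe),
          sum(drop), sum(!drop))
  )
  kept <- genotype_matrix(g$codes[, !drop, drop = FALSE],
                          g$snps[!drop, , drop = FALSE])
  list(genotypes = snp_stats(kept), report = report)
}

#' Iterative PCA detection of genotype outlier samples
#'
#' Standardizes mean-imputed genotype codes, computes principal components,
#' flags samples lying beyond `sd_thresh` standard deviations on any of the
#' top `n_pcs` components, removes them, and repeats until no sample is
#' flagged or `n_iter` iterations are exhausted.
#'
#' @param g A [genotype_matrix()].
#' @param n_pcs Number of leading components examined (default 10).
#' @param n_iter Maximum iterations (default 10).
#' @param sd_thresh Outlyingness threshold in SD units (default 6).
#' @return Character vector of all flagged sample IDs (possibly empty).
#' @export
pca_outlier_samples <- function(g, n_pcs = 10, n_iter = 10, sd_thresh = 6) {
  stopifnot(inherits(g, "genotype_matrix"))
  codes <- g$codes
  if (nrow(codes) < n_pcs + 1) {
    stop("need at least n_pcs + 1 samples", call. = FALSE)
  }
  flagged <- character()
  current <- codes
  for (iter in seq_len(n_iter)) {
    if (nrow(current) < n_pcs + 1) break
    imp <- apply(current, 2, function(x) {
      if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
      x
    })
    keep <- apply(imp, 2, stats::sd) > 0
    imp <- scale(imp[, keep, drop = FALSE])
    pcs <- min(n_pcs, nrow(imp) - 1, ncol(imp))
    sc <- stats::prcomp(imp, center = FALSE, scale. = FALSE)$x[, seq_len(pcs), drop = FALSE]
    z <- scale(sc)
    hit <- rownames(current)[apply(abs(z) > sd_thresh, 1, any)]
    if (length(hit) == 0) break
    flagged <- c(flagged, hit)
    current <- current[setdiff(rownames(current), hit), , drop = FALSE]
  }
  flagged
}

#' Flag expression outlier samples by median inter-sample correlation
#'
#' A sample is flagged when its median Spearman correlation with the other
#' samples falls below the threshold; a light stand-in for visual
#' intensity-bias inspection.
#'
#' @param x An [expression_matrix()] or probes x samples matrix.
#' @param min_cor Flagging threshold (default 0.8).
#' @return Character vector of flagged sample IDs.
#' @export
flag_expression_outliers <- function(x, min_cor = 0.8) {
  vals <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  cc <- stats::cor(vals, method = "spearman")
  diag(cc) <- NA
  med <- apply(cc, 2, stats::median, na.rm = TRUE)
  colnames(vals)[med < min_cor]
}
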