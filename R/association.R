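#' Residualize a vector on covariates
#'
#' Least-squares residuals after regressing on an intercept plus the given
#' covariates.  Residuals are orthogonal to every covariate and sum to zero.
#'
#' @param values Numeric vector.
#' @param covariates Optional data frame / matrix of covariates (one row per
#'   element of `values`), or `NULL` for intercept only.
#' @return Numeric vector of residuals.
#' @export
residualize <- function(values, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(values - mean(values))
  }
  cm <- as.matrix(covariates)
  storage.mode(cm) <- "double"
  X <- cbind(1, cm)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient covariate matrix", call. = FALSE)
  }
  stats::lm.fit(X, values)$residuals
}

#' Fit the additive eQTL model for one transcript-SNP pair
#'
#' Ordinary least squares of expression on intercept + covariates + genotype
#' dosage; the slope is the expression change per minor allele.  Samples
#' with a missing genotype are dropped pairwise.  Equivalent to correlating
#' the covariate-residualized expression and dosage:
#' \eqn{t = r \sqrt{df / (1 - r^2)}}, \eqn{df = n - 2 - n_{cov}}.
#'
#' @param y Expression vector (no missing values).
#' @param x Genotype dosage vector (0/1/2, `NA` allowed).
#' @param covariates Optional covariate data frame/matrix aligned with `y`.
#' @return One-row tibble: `beta`, `t_stat`, `df`, `p_value`, `n_used`.
#' @examples
#' fit_pair(c(1, 2, 2.5, 1.5, 0.5, 3), c(0, 1, 2, 1, 0, 2))
#' @export
fit_pair <- function(y, x, covariates = NULL) {
  ok <- !is.na(x) & !is.na(y)
  y <- y[ok]
  x <- x[ok]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[ok, , drop = FALSE]
  }
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- length(y)
  df <- n - 2L - n_cov
  if (df < 1) stop("not enough complete samples for the fit", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("genotype constant after removing missing calls", call. = FALSE)
  }
  ry <- residualize(y, covariates)
  rx <- residualize(x, covariates)
  sxx <- sum(rx^2)
  syy <- sum(ry^2)
  sxy <- sum(rx * ry)
  beta <- sxy / sxx
  if (syy == 0) {
    # constant (or covariate-explained) expression: no association signal
    return(tibble::tibble(beta = 0, t_stat = 0, df = df, p_value = 1,
                          n_used = n))
  }
  r2 <- sxy^2 / (sxx * syy)
  if (r2 >= 1) {
    t <- sign(beta) * Inf
    p <- 0
  } else {
    t <- (sxy / sqrt(sxx * syy)) * sqrt(df / (1 - r2))
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  }
  tibble::tibble(beta = beta, t_stat = t, df = df, p_value = p, n_used = n)
}

#' Classify a SNP-gene pair as cis or trans
#'
#' Cis means same chromosome and distance from the SNP position to the
#' closed gene interval of at most `window` (0 when inside the gene body);
#' everything else, including any cross-chromosome pair, is trans.  The
#' boundary is inclusive: exactly `window` bp away is still cis.
#'
#' @param snp_chrom,snp_pos SNP coordinates (1-based bp).
#' @param gene_chrom,gene_start,gene_end Gene body coordinates (1-based
#'   inclusive).
#' @param window Maximum cis distance in bp (default 1e6).
#' @return Character vector, "cis" or "trans" (vectorized).
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, gene_chrom, gene_start,
                               gene_end, window = 1e6) {
  if (any(gene_start > gene_end)) {
    stop("malformed gene interval: start > end", call. = FALSE)
  }
  d <- pmax(gene_start - snp_pos, snp_pos - gene_end, 0)
  ifelse(snp_chrom == gene_chrom & d <= window, "cis", "trans")
}

#' False discovery rate adjustment
#'
#' `bh` is the Benjamini-Hochberg step-up with the usual cumulative-minimum
#' monotonization; `storey` scales the BH q-values by the null proportion
#' \eqn{\pi_0 = \min(1, \#\{p > \lambda\} / ((1-\lambda) m))} estimated at
#' \eqn{\lambda = 0.5}.
#'
#' @param p_values Numeric vector of P-values in \[0, 1\].
#' @param method `"bh"` or `"storey"` (default `"storey"`).
#' @param lambda Tuning point for the Storey null-proportion estimate.
#' @return Vector of q-values, same length and order as `p_values`.
#' @export
fdr_adjust <- function(p_values, method = c("storey", "bh"), lambda = 0.5) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("P-values must lie in [0, 1]", call. = FALSE)
  }
  if (length(p_values) == 0) return(numeric(0))
  q <- stats::p.adjust(p_values, method = "BH")
  if (method == "storey") {
    m <- sum(!is.na(p_values))
    pi0 <- min(1, sum(p_values > lambda, na.rm = TRUE) / ((1 - lambda) * m))
    q <- pmin(1, q * pi0)
  }
  q
}

#' Genome-wide eQTL scan
#'
#' Tests every transcript-SNP pair that passes the MAF filter and the
#' cis/trans mode filter under the additive linear model with covariates,
#' then adjusts for multiple testing within the scan.  The heavy path is a
#' matrix correlation between covariate-residualized expression and dosage;
#' SNPs with missing calls fall back to a per-SNP fit on pairwise-complete
#' samples.
#'
#' @param expr An [expression_matrix()].
#' @param geno A [genotype_matrix()].
#' @param gene_coords Data frame `gene_id`, `chrom`, `start`, `end` covering
#'   every scanned gene.
#' @param covariates Optional data frame with `sample_id` plus numeric
#'   covariate columns (e.g. `gender`); must cover every analyzed sample
#'   with no missing values.
#' @param mode `"all"`, `"cis"` (only pairs within the window) or `"trans"`
#'   (only pairs outside it / cross-chromosome).
#' @param maf_min SNPs with minor allele frequency below this are excluded
#'   entirely (default 0.10).
#' @param cis_window Cis distance threshold in bp (default 1e6).
#' @param gene_subset Optional character vector restricting the scanned
#'   transcripts to those mapping to these genes.
#' @param fdr_method Passed to [fdr_adjust()].
#' @return An object of class `eqtl_scan`: a list with `results` (tibble of
#'   [tidy.eqtl_scan()] columns), `n_tests`, `n_snps_used`, `mode`, and the
#'   filter parameters.  `tidy()` returns the result table, `glance()` a
#'   one-row summary.
#' @export
eqtl_scan <- function(expr, geno, gene_coords, covariates = NULL,
                      mode = c("all", "cis", "trans"), maf_min = 0.10,
                      cis_window = 1e6, gene_subset = NULL,
                      fdr_method = c("storey", "bh")) {
  mode <- match.arg(mode)
  fdr_method <- match.arg(fdr_method)
  stopifnot(inherits(expr, "expression_matrix"), inherits(geno, "genotype_matrix"))
  gene_coords <- tibble::as_tibble(gene_coords)

  samples <- intersect(colnames(expr$values), rownames(geno$codes))
  if (length(samples) == 0) stop("no overlapping samples", call. = FALSE)
  Y <- expr$values[, samples, drop = FALSE]
  G <- geno$codes[samples, , drop = FALSE]

  cov_mat <- NULL
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    stopifnot("sample_id" %in% names(covariates))
    if (!all(samples %in% covariates$sample_id)) {
      stop("covariates must cover every analyzed sample", call. = FALSE)
    }
    cov_mat <- as.matrix(covariates[match(samples, covariates$sample_id),
                                    setdiff(names(covariates), "sample_id"),
                                    drop = FALSE])
    if (anyNA(cov_mat)) stop("missing covariate values", call. = FALSE)
  }
  n_cov <- if (is.null(cov_mat)) 0L else ncol(cov_mat)

  # transcript bookkeeping
  pm <- expr$probe_map[match(rownames(Y), expr$probe_map$probe_id), ]
  if (!is.null(gene_subset)) {
    if (length(gene_subset) == 0) stop("empty gene_subset", call. = FALSE)
    keep <- pm$gene_id %in% gene_subset
    Y <- Y[keep, , drop = FALSE]
    pm <- pm[keep, , drop = FALSE]
  }
  if (nrow(Y) == 0) stop("no transcripts to scan", call. = FALSE)
  gc_idx <- match(pm$gene_id, gene_coords$gene_id)
  if (anyNA(gc_idx)) {
    stop("gene_coords missing for: ",
         paste(unique(pm$gene_id[is.na(gc_idx)]), collapse = ", "),
         call. = FALSE)
  }
  gc <- gene_coords[gc_idx, ]

  # MAF / monomorphic filter on complete-genotype samples
  geno_sub <- snp_stats(genotype_matrix(G, geno$snps))
  snp_ok <- !is.na(geno_sub$snps$maf) & geno_sub$snps$maf >= maf_min &
    apply(G, 2, function(x) stats::sd(x, na.rm = TRUE) > 0)
  G <- G[, snp_ok, drop = FALSE]
  snps <- geno_sub$snps[snp_ok, ]
  if (ncol(G) == 0) stop("no SNPs pass the MAF filter", call. = FALSE)

  # label matrix: transcripts x SNPs
  lab <- matrix("trans", nrow = nrow(Y), ncol = ncol(G))
  for (i in seq_len(nrow(Y))) {
    lab[i, ] <- classify_cis_trans(snps$chrom, snps$pos, gc$chrom[i],
                                   gc$start[i], gc$end[i], cis_window)
  }
  test_mask <- switch(mode,
    all = matrix(TRUE, nrow(Y), ncol(G)),
    cis = lab == "cis",
    trans = lab == "trans"
  )

  n <- length(samples)
  df_full <- n - 2L - n_cov
  Ry <- t(apply(Y, 1, residualize, covariates = cov_mat))
  if (nrow(Y) == 1) Ry <- matrix(Ry, nrow = 1)

  complete <- !apply(G, 2, anyNA)
  beta_m <- t_m <- p_m <- matrix(NA_real_, nrow(Y), ncol(G))
  df_m <- n_m <- matrix(NA_real_, nrow(Y), ncol(G))

  if (any(complete)) {
    Gc <- G[, complete, drop = FALSE]
    Rx <- apply(Gc, 2, residualize, covariates = cov_mat)
    if (n == 1) Rx <- matrix(Rx, nrow = 1)
    sy <- sqrt(rowSums(Ry^2))
    sx <- sqrt(colSums(Rx^2))
    num <- Ry %*% Rx                       # transcripts x complete SNPs
    beta <- sweep(num, 2, sx^2, "/")
    r <- sweep(sweep(num, 2, sx, "/"), 1, pmax(sy, .Machine$double.eps), "/")
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt(df_full / pmax(1 - r^2, .Machine$double.eps))
    tt[abs(r) == 1] <- sign(r[abs(r) == 1]) * Inf
    pp <- 2 * stats::pt(abs(tt), df_full, lower.tail = FALSE)
    pp[sy == 0, ] <- 1
    tt[sy == 0, ] <- 0
    beta[sy == 0, ] <- 0
    beta_m[, complete] <- beta
    t_m[, complete] <- tt
    p_m[, complete] <- pp
    df_m[, complete] <- df_full
    n_m[, complete] <- n
  }
  for (j in which(!complete)) {
    x <- G[, j]
    ok <- !is.na(x)
    if (sum(ok) < n_cov + 3 || stats::sd(x[ok]) == 0) next  # skipped, logged below
    for (i in seq_len(nrow(Y))) {
      if (!test_mask[i, j]) next
      ft <- fit_pair(Y[i, ], x, covariates = cov_mat)
      beta_m[i, j] <- ft$beta; t_m[i, j] <- ft$t_stat
      p_m[i, j] <- ft$p_value; df_m[i, j] <- ft$df; n_m[i, j] <- ft$n_used
    }
  }

  use <- test_mask & !is.na(p_m)
  idx <- which(use, arr.ind = TRUE)
  results <- tibble::tibble(
    transcript_id = rownames(Y)[idx[, 1]],
    gene_id = pm$gene_id[idx[, 1]],
    snp_id = snps$snp_id[idx[, 2]],
    snp_chrom = snps$chrom[idx[, 2]],
    snp_pos = snps$pos[idx[, 2]],
    gene_chrom = gc$chrom[idx[, 1]],
    gene_start = gc$start[idx[, 1]],
    gene_end = gc$end[idx[, 1]],
    beta = beta_m[use],
    t_stat = t_m[use],
    df = as.integer(df_m[use]),
    p_value = p_m[use],
    label = lab[use],
    n_used = as.integer(n_m[use])
  )
  results$p_fdr <- fdr_adjust(results$p_value, method = fdr_method)
  results <- dplyr::arrange(results, .data$p_value)

  structure(
    list(results = results, n_tests = nrow(results),
         n_snps_used = ncol(G), n_transcripts = nrow(Y), mode = mode,
         maf_min = maf_min, cis_window = cis_window, fdr_method = fdr_method),
    class = "eqtl_scan"
  )
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat(sprintf(
    "<eqtl_scan> mode=%s: %d tests (%d transcripts x %d SNPs passing filters); %d at q<0.05\n",
    x$mode, x$n_tests, x$n_transcripts, x$n_snps_used,
    sum(x$results$p_fdr < 0.05)
  ))
  invisible(x)
}

#' Tidy an eQTL scan into its association table
#'
#' @param x An `eqtl_scan` object.
#' @param ... Unused.
#' @return Tibble with one row per tested transcript-SNP pair, sorted by
#'   P-value: `transcript_id`, `gene_id`, `snp_id`, SNP and gene
#'   coordinates, `beta`, `t_stat`, `df`, `p_value`, `p_fdr`, `label`,
#'   `n_used`.
#' @export
tidy.eqtl_scan <- function(x, ...) {
  dplyr::select(
    x$results, "transcript_id", "gene_id", "snp_id", "snp_chrom", "snp_pos",
    "gene_chrom", "gene_start", "gene_end", "beta", "t_stat", "df",
    "p_value", "p_fdr", "label", "n_used"
  )
}

#' One-row summary of an eQTL scan
#'
#' @param x An `eqtl_scan` object.
#' @param alpha FDR significance level used for the discovery count.
#' @param ... Unused.
#' @return One-row tibble: `mode`, `n_tests`, `n_transcripts`,
#'   `n_snps_used`, `n_significant`, `min_p`.
#' @export
glance.eqtl_scan <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    mode = x$mode,
    n_tests = x$n_tests,
    n_transcripts = x$n_transcripts,
    n_snps_used = x$n_snps_used,
    n_significant = sum(x$results$p_fdr < alpha),
    min_p = if (x$n_tests > 0) min(x$results$p_value) else NA_real_
  )
}

#' Diagnostic plot for an eQTL scan
#'
#' P-value histogram and uniform QQ panel; a well-calibrated null scan shows
#' a flat histogram and QQ points on the diagonal.
#'
#' @param object An `eqtl_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eqtl_scan <- function(object, ...) {
  res <- object$results
  m <- nrow(res)
  qq <- tibble::tibble(
    expected = -log10(stats::ppoints(m)),
    observed = -log10(sort(res$p_value))
  )
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](P)),
      y = expression(Observed ~ -log[10](P)),
      title = sprintf("eQTL scan QQ (%s mode, %d tests)", object$mode, m)
    ) +
    ggplot2::theme_minimal()
}
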