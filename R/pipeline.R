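#' Run the systems-genetics trans-eQTL pipeline end to end
#'
#' Orchestrates the five-step workflow: genotype QC, (optional) cis scan,
#' co-expression module detection, functional enrichment, evidence-network
#' centrality and central-gene selection, then a trans-eQTL scan restricted
#' to the selected genes.  Restricting the scan this way shrinks the number
#' of trans tests from (all transcripts x SNPs) to (selected transcripts x
#' SNPs), which is the point of the method.  When no module is enriched the
#' pipeline stops after the enrichment stage with an explicit
#' empty-selection record.
#'
#' @param data List with elements `expression` ([expression_matrix()]),
#'   `genotypes` ([genotype_matrix()]), `gene_coords`, `annotation`
#'   (tibble `category_id`, `gene_id`), `edges` (tibble `gene_a`, `gene_b`,
#'   `combined_score`) and optionally `covariates`; e.g. the output of
#'   [sim_dataset()].
#' @param params Named list overriding any default in
#'   [pipeline_defaults()].
#' @return Object of class `transreg_pipeline`: per-stage results plus a
#'   `manifest` tibble (stage, status, inputs hash, parameter hash, output
#'   summary) in execution order.  `glance()` summarises the run.
#' @export
run_pipeline <- function(data, params = list()) {
  p <- utils::modifyList(pipeline_defaults(), params)
  stopifnot(inherits(data$expression, "expression_matrix"),
            inherits(data$genotypes, "genotype_matrix"))
  out <- list(params = p)
  manifest <- list()
  log_stage <- function(stage, status, detail, obj) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, status = status, detail = detail,
      output_hash = rlang::hash(obj)
    )
    message(sprintf("[%s] %s: %s", stage, status, detail))
  }

  qc <- qc_genotypes(data$genotypes, miss_max = p$miss_max,
                     hwe_alpha = p$hwe_alpha)
  geno <- qc$genotypes
  if (p$pca_outliers && nrow(geno$codes) >= p$n_pcs + 2) {
    bad <- pca_outlier_samples(geno, n_pcs = p$n_pcs, n_iter = p$n_iter,
                               sd_thresh = p$sd_thresh)
    if (length(bad) > 0) {
      keep <- setdiff(rownames(geno$codes), bad)
      geno <- snp_stats(genotype_matrix(geno$codes[keep, , drop = FALSE],
                                        geno$snps))
    }
    qc$pca_outliers <- if (exists("bad")) bad else character()
  }
  out$qc <- qc
  out$genotypes <- geno
  log_stage("qc", "ok",
            sprintf("%d SNPs kept, %d samples", ncol(geno$codes),
                    nrow(geno$codes)), qc$report)

  if (p$run_cis) {
    out$cis <- eqtl_scan(data$expression, geno, data$gene_coords,
                         covariates = data$covariates, mode = "cis",
                         maf_min = p$maf_min, cis_window = p$cis_window,
                         fdr_method = p$fdr_method)
    log_stage("cis_scan", "ok",
              sprintf("%d tests", out$cis$n_tests), out$cis$results)
  }

  out$modules <- find_modules(data$expression, power = p$power,
                              signed = p$signed, cut_height = p$cut_height,
                              min_size = p$min_size)
  log_stage("modules", "ok",
            sprintf("%d modules",
                    sum(attr(out$modules, "sizes")$module != "M0")),
            out$modules)

  out$enrichment <- enrich_modules(out$modules, data$annotation,
                                   alpha = p$enrich_alpha)
  out$selected_modules <- select_enriched_modules(out$enrichment,
                                                  alpha = p$enrich_alpha)
  if (length(out$selected_modules) == 0) {
    log_stage("enrichment", "stopped", "no module enriched; empty selection",
              out$enrichment)
    out$manifest <- dplyr::bind_rows(manifest)
    out$stopped_early <- TRUE
    class(out) <- "transreg_pipeline"
    return(out)
  }
  log_stage("enrichment", "ok",
            paste("selected:", paste(out$selected_modules, collapse = ", ")),
            out$enrichment)

  out$networks <- list()
  cent_all <- list()
  for (m in out$selected_modules) {
    genes_m <- out$modules$gene_id[out$modules$module == m]
    net <- build_network(genes_m, data$edges, score_min = p$score_min)
    out$networks[[m]] <- net
    if (igraph::vcount(net) > 0) {
      cent_all[[m]] <- centrality_table(net, module = m)
    }
  }
  out$centrality <- dplyr::bind_rows(cent_all)
  log_stage("network", "ok",
            sprintf("%d retained genes across %d module network(s)",
                    nrow(out$centrality), length(out$networks)),
            out$centrality)

  out$selected_genes <- unique(unlist(lapply(cent_all, function(ct) {
    select_central_genes(ct, top_q = p$top_q)
  })))
  log_stage("selection", "ok",
            sprintf("%d central genes", length(out$selected_genes)),
            out$selected_genes)

  out$trans <- eqtl_scan(data$expression, geno, data$gene_coords,
                         covariates = data$covariates, mode = "trans",
                         maf_min = p$maf_min, cis_window = p$cis_window,
                         gene_subset = out$selected_genes,
                         fdr_method = p$fdr_method)
  log_stage("trans_scan", "ok",
            sprintf("%d tests, %d at q<%.2g", out$trans$n_tests,
                    sum(out$trans$results$p_fdr < p$fdr_alpha), p$fdr_alpha),
            out$trans$results)

  out$manifest <- dplyr::bind_rows(manifest)
  out$stopped_early <- FALSE
  class(out) <- "transreg_pipeline"
  out
}

#' Default pipeline parameters
#'
#' Shipped thresholds: missingness 0.10, HWE alpha 1e-5, MAF 0.10, 1 Mb cis
#' window, Storey FDR at 0.05, unsigned power-6 adjacency cut at 0.95 with
#' minimum module size 30, enrichment alpha 0.05, evidence-score cutoff
#' 0.4, top 10% centrality selection.
#'
#' @return Named list of defaults, all overridable via `params` of
#'   [run_pipeline()].
#' @export
pipeline_defaults <- function() {
  list(
    miss_max = 0.10, hwe_alpha = 1e-5,
    pca_outliers = FALSE, n_pcs = 10, n_iter = 10, sd_thresh = 6,
    run_cis = FALSE,
    maf_min = 0.10, cis_window = 1e6, fdr_method = "storey", fdr_alpha = 0.05,
    power = 6, signed = FALSE, cut_height = 0.95, min_size = 30,
    enrich_alpha = 0.05, score_min = 0.4, top_q = 0.1
  )
}

#' @export
print.transreg_pipeline <- function(x, ...) {
  cat("<transreg_pipeline>\n")
  print(x$manifest)
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `transreg_pipeline`.
#' @param ... Unused.
#' @return Tibble: modules found, modules selected, central genes, trans
#'   tests and discoveries at the configured FDR level.
#' @export
glance.transreg_pipeline <- function(x, ...) {
  tibble::tibble(
    n_modules = sum(attr(x$modules, "sizes")$module != "M0"),
    n_selected_modules = length(x$selected_modules),
    n_central_genes = length(x$selected_genes),
    n_trans_tests = if (is.null(x$trans)) NA_integer_ else x$trans$n_tests,
    n_trans_hits = if (is.null(x$trans)) NA_integer_ else
      sum(x$trans$results$p_fdr < x$params$fdr_alpha),
    stopped_early = x$stopped_early
  )
}
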