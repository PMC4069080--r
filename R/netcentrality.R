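#' Fisher exact over-representation test for one module and category
#'
#' Two-sided Fisher exact test on the 2x2 table crossing module membership
#' with category membership over the gene universe.  The odds ratio used
#' for the direction call is the sample odds ratio, Haldane-corrected
#' (+0.5 in every cell) only when some cell is zero.
#'
#' @param module_genes Character vector of module genes (subset of
#'   `universe`).
#' @param category Character vector of category genes (subset of
#'   `universe`).
#' @param universe Character vector: all genes eligible for membership.
#' @param alpha Significance level used only for the direction call.
#' @return One-row tibble: `p_value`, `odds_ratio`, `direction`
#'   ("over", "under" or "ns") and the four table cells.
#' @export
enrich_fisher <- function(module_genes, category, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) < 2) stop("universe must hold at least 2 genes", call. = FALSE)
  module_genes <- intersect(unique(module_genes), universe)
  category <- intersect(unique(category), universe)
  a <- length(intersect(module_genes, category))
  b <- length(module_genes) - a
  cc <- length(category) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  direction <- if (p < alpha && or > 1) "over"
  else if (p < alpha && or < 1) "under"
  else "ns"
  tibble::tibble(
    p_value = p, odds_ratio = or, direction = direction,
    in_module_in_cat = a, in_module_out_cat = b,
    out_module_in_cat = cc, out_module_out_cat = d
  )
}

#' Enrichment of every module against every category
#'
#' @param assignment A `module_assignment` (or tibble `gene_id`, `module`);
#'   M0 (unassigned) is skipped.
#' @param annotation Tibble `category_id`, `gene_id`.
#' @param universe Optional gene universe; defaults to all assigned genes.
#' @param alpha Direction-call significance level.
#' @return Tibble: `module`, `category_id`, `p_value`, `odds_ratio`,
#'   `direction`, table cells; sorted by `p_value`.
#' @export
enrich_modules <- function(assignment, annotation, universe = NULL,
                           alpha = 0.05) {
  assignment <- tibble::as_tibble(assignment)
  annotation <- tibble::as_tibble(annotation)
  if (is.null(universe)) universe <- assignment$gene_id
  mods <- setdiff(sort(unique(assignment$module)), "M0")
  cats <- sort(unique(annotation$category_id))
  empty <- tibble::tibble(
    module = character(), category_id = character(), p_value = numeric(),
    odds_ratio = numeric(), direction = character(),
    in_module_in_cat = integer(), in_module_out_cat = integer(),
    out_module_in_cat = integer(), out_module_out_cat = integer()
  )
  if (length(mods) == 0 || length(cats) == 0) return(empty)
  tidyr::expand_grid(module = mods, category_id = cats) |>
    dplyr::mutate(res = purrr::map2(.data$module, .data$category_id, function(m, ct) {
      enrich_fisher(
        assignment$gene_id[assignment$module == m],
        annotation$gene_id[annotation$category_id == ct],
        universe, alpha = alpha
      )
    })) |>
    tidyr::unnest("res") |>
    dplyr::arrange(.data$p_value)
}

#' Select significantly over-represented modules
#'
#' Only over-represented modules advance to network construction;
#' under-represented ones are as significant but point away from the
#' process of interest.
#'
#' @param results Output of [enrich_modules()] (or any tibble with
#'   `module`, `p_value`, `direction`).
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of module IDs ordered by ascending P.
#' @export
select_enriched_modules <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) return(character())
  results |>
    dplyr::filter(.data$direction == "over", .data$p_value < alpha) |>
    dplyr::arrange(.data$p_value) |>
    dplyr::pull("module") |>
    unique()
}

#' Build a functional-evidence network for a module
#'
#' Keeps edges whose two endpoints both belong to the module and whose
#' combined evidence score reaches `score_min`; genes left without any
#' retained edge are excluded, so the network holds only interconnected
#' genes.
#'
#' @param module_genes Character vector of module genes.
#' @param edges Tibble `gene_a`, `gene_b`, `combined_score` (scores in
#'   \[0, 1\], undirected; duplicate and self pairs are collapsed).
#' @param score_min Minimum combined score (default 0.4, the conventional
#'   medium-confidence cutoff for combined evidence scores).
#' @return An undirected [igraph::graph] with edge attribute `score` and
#'   attributes `n_module_genes` / `n_retained` recording how many module
#'   genes survived.
#' @export
build_network <- function(module_genes, edges, score_min = 0.4) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b", "combined_score") %in% names(edges)))
  if (any(edges$combined_score < 0 | edges$combined_score > 1)) {
    stop("combined scores must lie in [0, 1]", call. = FALSE)
  }
  keep <- edges |>
    dplyr::filter(
      .data$gene_a %in% module_genes,
      .data$gene_b %in% module_genes,
      .data$gene_a != .data$gene_b,
      .data$combined_score >= score_min
    ) |>
    dplyr::mutate(
      lo = pmin(.data$gene_a, .data$gene_b),
      hi = pmax(.data$gene_a, .data$gene_b)
    ) |>
    dplyr::distinct(.data$lo, .data$hi, .keep_all = TRUE)
  g <- igraph::graph_from_data_frame(
    keep[, c("lo", "hi")], directed = FALSE
  )
  igraph::E(g)$score <- keep$combined_score
  g$n_module_genes <- length(unique(module_genes))
  g$n_retained <- igraph::vcount(g)
  g
}

#' Degree and betweenness centrality of a functional network
#'
#' DC is the raw (unweighted, integer) edge count per gene.  BC is
#' unweighted shortest-path betweenness normalized by
#' \eqn{(n-1)(n-2)/2}, the number of vertex pairs not involving the focal
#' node in an undirected graph of `n` nodes; disconnected components share
#' the global normalizer.  For networks of fewer than 3 nodes BC is 0.
#'
#' @param net An undirected igraph, e.g. from [build_network()].
#' @param module Optional module label to attach.
#' @return Object of class `centrality_table`: tibble `gene_id`, `module`,
#'   `dc` (integer), `bc` (in \[0, 1\]), sorted by decreasing `dc`.
#' @export
centrality_table <- function(net, module = NA_character_) {
  stopifnot(igraph::is_igraph(net))
  n <- igraph::vcount(net)
  dc <- igraph::degree(net)
  bc <- if (n < 3) {
    stats::setNames(rep(0, n), names(dc))
  } else {
    igraph::betweenness(net, directed = FALSE, weights = NA) /
      ((n - 1) * (n - 2) / 2)
  }
  out <- tibble::tibble(
    gene_id = names(dc),
    module = module,
    dc = as.integer(dc),
    bc = as.numeric(bc)
  ) |>
    dplyr::arrange(dplyr::desc(.data$dc), .data$gene_id)
  class(out) <- c("centrality_table", class(out))
  out
}

#' Select central genes by degree and betweenness
#'
#' Union of high-degree (hub) and high-betweenness (bottleneck) genes.
#' Threshold mode uses absolute per-call cutoffs `dc_min` / `bc_min`;
#' quantile mode takes the top `top_q` fraction by each measure.  Exactly
#' one mode must be used.
#'
#' @param cent A `centrality_table` (or tibble `gene_id`, `dc`, `bc`).
#' @param dc_min,bc_min Absolute cutoffs (threshold mode; either may be
#'   `Inf` to disable one arm).
#' @param top_q Fraction in (0, 1\] (quantile mode).
#' @return Character vector of selected gene IDs (deduplicated, in
#'   decreasing-DC order).
#' @export
select_central_genes <- function(cent, dc_min = NULL, bc_min = NULL,
                                 top_q = NULL) {
  cent <- tibble::as_tibble(cent)
  threshold_mode <- !is.null(dc_min) || !is.null(bc_min)
  if (threshold_mode == !is.null(top_q)) {
    stop("use either dc_min/bc_min or top_q, not both", call. = FALSE)
  }
  if (threshold_mode) {
    if (is.null(dc_min)) dc_min <- Inf
    if (is.null(bc_min)) bc_min <- Inf
    sel <- cent$gene_id[cent$dc >= dc_min | cent$bc >= bc_min]
  } else {
    stopifnot(top_q > 0, top_q <= 1)
    k <- max(1, ceiling(top_q * nrow(cent)))
    top_dc <- cent$gene_id[order(-cent$dc, cent$gene_id)][seq_len(k)]
    top_bc <- cent$gene_id[order(-cent$bc, cent$gene_id)][seq_len(k)]
    sel <- cent$gene_id[cent$gene_id %in% union(top_dc, top_bc)]
  }
  if (length(sel) == 0) {
    stop("no genes retained; thresholds too strict", call. = FALSE)
  }
  sel
}

#' Write a functional network as GraphML with centrality attributes
#'
#' @param net An undirected igraph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  cent <- centrality_table(net)
  idx <- match(igraph::V(net)$name, cent$gene_id)
  igraph::V(net)$dc <- cent$dc[idx]
  igraph::V(net)$bc <- cent$bc[idx]
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Plot degree against betweenness centrality
#'
#' @param object A `centrality_table`.
#' @param dc_min,bc_min Optional cutoffs drawn as reference lines.
#' @param ... Unused.
#' @return A ggplot object; hubs sit right, bottlenecks sit high.
#' @export
autoplot.centrality_table <- function(object, dc_min = NULL, bc_min = NULL,
                                      ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$dc, y = .data$bc)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "degree centrality (DC)",
                  y = "betweenness centrality (BC)",
                  title = "Functional-network centrality") +
    ggplot2::theme_minimal()
  if (!is.null(dc_min)) p <- p + ggplot2::geom_vline(xintercept = dc_min, linetype = 2)
  if (!is.null(bc_min)) p <- p + ggplot2::geom_hline(yintercept = bc_min, linetype = 2)
  p
}
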