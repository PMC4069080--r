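#' Weighted co-expression adjacency matrix
#'
#' Raises the Pearson correlation between gene expression profiles to a
#' soft-threshold power: unsigned \eqn{a_{ij} = |cor(i,j)|^\beta}, signed
#' \eqn{a_{ij} = ((1 + cor)/2)^\beta}; the diagonal is 1.  Zero-variance
#' genes are excluded with a message.
#'
#' @param expr An [expression_matrix()] or probes x samples matrix.
#' @param power Soft-threshold exponent (integer >= 1).
#' @param signed Use the signed transform (default unsigned).
#' @return Symmetric genes x genes adjacency matrix with unit diagonal.
#' @export
adjacency <- function(expr, power = 6, signed = FALSE) {
  stopifnot(power >= 1)
  vals <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    message("excluding ", sum(sds == 0), " zero-variance gene(s)")
    vals <- vals[sds > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(vals))
  a <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' For an adjacency matrix with entries in \[0, 1\] and unit diagonal,
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'                       {\min(k_i, k_j) + 1 - a_{ij}},}
#' with connectivity \eqn{k_i = \sum_{u \ne i} a_{iu}} and \eqn{TOM_{ii}=1}.
#' Two genes are similar when they share neighbors, not merely when they are
#' directly correlated.
#'
#' @param a Symmetric adjacency matrix (entries in \[0, 1\], unit diagonal).
#' @return Symmetric TOM matrix with entries in \[0, 1\] and unit diagonal.
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  if (!isSymmetric(unname(a), tol = 1e-10)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(a < 0 - 1e-12) || any(a > 1 + 1e-12)) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  k <- rowSums(a) - 1
  shared <- a %*% a - 2 * a          # removes u = i and u = j terms (diag = 1)
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- dimnames(a)
  tom
}

#' Select the soft-threshold power by scale-free fit
#'
#' For each candidate power, builds the adjacency, bins the connectivity
#' distribution into at least 10 log-spaced bins and regresses
#' \eqn{\log_{10} freq(k)} on \eqn{\log_{10} k}.  The fit index is the
#' regression \eqn{R^2} signed negatively when the slope is positive (a
#' scale-free network requires a decreasing degree distribution).  Returns
#' the smallest power reaching `r2_target`, otherwise the power with the
#' best fit (with a warning).
#'
#' @param expr An [expression_matrix()] or probes x samples matrix (>= 10
#'   genes, >= 3 samples).
#' @param powers Candidate integer powers.
#' @param r2_target Scale-free fit target (default 0.8).
#' @param signed Passed to [adjacency()].
#' @return The selected power, with the per-power fit table in attribute
#'   `"fit"`.
#' @export
soft_threshold_select <- function(expr, powers = 1:10, r2_target = 0.8,
                                  signed = FALSE) {
  if (length(powers) == 0) stop("empty powers list", call. = FALSE)
  vals <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  stopifnot(nrow(vals) >= 10, ncol(vals) >= 3)
  fit <- purrr::map_dbl(powers, function(p) {
    a <- adjacency(vals, power = p, signed = signed)
    k <- rowSums(a) - 1
    k <- k[k > 0]
    n_bins <- max(10, min(20, floor(length(k) / 5)))
    cuts <- cut(k, breaks = n_bins)
    freq <- tapply(k, cuts, length)
    kmean <- tapply(k, cuts, mean)
    ok <- !is.na(freq) & freq > 0
    if (sum(ok) < 3) return(NA_real_)
    fitlm <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
    r2 <- summary(fitlm)$r.squared
    slope <- stats::coef(fitlm)[2]
    if (is.na(slope)) return(NA_real_)
    -sign(slope) * r2
  })
  tab <- tibble::tibble(power = powers, sft_r2 = fit)
  hit <- which(!is.na(fit) & fit >= r2_target)
  sel <- if (length(hit) > 0) {
    powers[min(hit)]
  } else {
    warning("no candidate power reaches the scale-free fit target; ",
            "returning the best fit", call. = FALSE)
    powers[which.max(fit)]
  }
  attr(sel, "fit") <- tab
  sel
}

#' Detect co-expression modules from a TOM matrix
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut at a fixed height.  Clusters below `min_size` are pooled into the
#' unassigned module `M0`; surviving clusters are renumbered `M1`, `M2`, ...
#' by decreasing size (ties broken by smallest member gene ID).  Genes are
#' sorted lexicographically before clustering so the result is invariant to
#' input order.
#'
#' @param tom TOM (or any similarity in \[0, 1\] with unit diagonal) matrix
#'   with gene dimnames.
#' @param cut_height Dendrogram cut height on `1 - TOM`, in (0, 1\].
#' @param min_size Minimum module size (>= 2).
#' @return Object of class `module_assignment`: tibble `gene_id`, `module`
#'   with per-module sizes in attribute `"sizes"`.
#' @export
detect_modules <- function(tom, cut_height = 0.95, min_size = 30) {
  stopifnot(cut_height > 0, cut_height <= 1)
  if (min_size < 2) stop("min_size must be at least 2", call. = FALSE)
  tom <- as.matrix(tom)
  ord <- order(rownames(tom))
  tom <- tom[ord, ord]
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  genes <- rownames(tom)
  sizes <- table(cl)
  keep_cl <- names(sizes)[sizes >= min_size]
  first_gene <- tapply(genes, cl, min)
  keep_info <- tibble::tibble(
    cl = keep_cl,
    size = as.integer(sizes[keep_cl]),
    first = first_gene[keep_cl]
  ) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$first)
  relabel <- stats::setNames(
    paste0("M", seq_len(nrow(keep_info))), keep_info$cl
  )
  module <- ifelse(as.character(cl) %in% names(relabel),
                   relabel[as.character(cl)], "M0")
  out <- tibble::tibble(gene_id = genes, module = unname(module))
  attr(out, "sizes") <- out |>
    dplyr::count(.data$module, name = "n_genes") |>
    dplyr::arrange(.data$module)
  class(out) <- c("module_assignment", class(out))
  out
}

#' Full module-detection pipeline step
#'
#' Convenience wrapper: adjacency at the given (or selected) power, TOM,
#' then [detect_modules()].
#'
#' @param expr An [expression_matrix()] or probes x samples matrix.
#' @param power Soft-threshold power, or `NULL` to pick one with
#'   [soft_threshold_select()].
#' @param signed,cut_height,min_size See [adjacency()] and
#'   [detect_modules()].
#' @return A `module_assignment` (see [detect_modules()]) with the used
#'   power in attribute `"power"`.
#' @export
find_modules <- function(expr, power = 6, signed = FALSE, cut_height = 0.95,
                         min_size = 30) {
  if (is.null(power)) power <- soft_threshold_select(expr, signed = signed)
  a <- adjacency(expr, power = power, signed = signed)
  tom <- tom_similarity(a)
  out <- detect_modules(tom, cut_height = cut_height, min_size = min_size)
  attr(out, "power") <- as.integer(power)
  out
}

#' Plot module sizes
#'
#' @param object A `module_assignment`.
#' @param ... Unused.
#' @return A ggplot bar chart of module sizes (M0 = unassigned).
#' @export
autoplot.module_assignment <- function(object, ...) {
  sizes <- attr(object, "sizes")
  ggplot2::ggplot(sizes, ggplot2::aes(
    x = stats::reorder(.data$module, -.data$n_genes), y = .data$n_genes
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "module", y = "genes",
                  title = "Co-expression module sizes") +
    ggplot2::theme_minimal()
}
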