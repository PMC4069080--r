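#' Simulation configuration for the synthetic systems-genetics dataset
#'
#' Describes a population of unrelated samples genotyped at independent
#' biallelic SNPs in Hardy-Weinberg equilibrium, an expression matrix with
#' module structure generated from a latent factor per module, planted
#' cis/trans genotype effects, a functional-category annotation with
#' per-module membership probabilities, and a STRING-like evidence edge
#' table that is denser within modules than between them.
#'
#' @param n_samples Number of samples (>= 2).
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos` (1-based bp)
#'   and `maf` in (0, 0.5].
#' @param modules Data frame with columns `module_id`, `gene_id` and
#'   optionally `loading` (factor loading, default 1).
#' @param effects Optional data frame of planted effects: `snp_id`,
#'   `gene_id`, `beta` (expression units per minor allele) and `kind`
#'   ("cis" or "trans").
#' @param missing_rate Probability that a genotype call is missing.
#' @param noise_sd Residual SD of the expression model.
#' @param factor_sd Per-module SD of the latent factor; a single number or a
#'   vector named by module ID.
#' @param annotation Optional data frame `category_id`, `module_id`, `prob`:
#'   the probability that a gene of that module carries the category.
#' @param edges List with `within` and `between` edge probabilities and
#'   `score_range`, a length-2 vector inside \[0, 1\].  Optional elements
#'   `hubs` (gene IDs) and `hub_prob` (default 0.95) plant hub genes: a
#'   within-module pair touching a hub gene connects with `hub_prob`
#'   instead of `within`, giving hubs a high edge degree.
#' @param gene_coords Optional data frame `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).  When omitted, coordinates are placed
#'   automatically: genes with a planted cis effect sit at their SNP, all
#'   other genes on a dedicated SNP-free chromosome so that planted trans
#'   effects are guaranteed to classify as trans.
#' @param gender_effect Additive expression shift for gender = 1 samples,
#'   applied to every gene (default 0); gender itself is Bernoulli(0.5).
#' @param seed Master seed.  Stage generators draw from child seeds derived
#'   by fixed offsets, so each stage is individually reproducible.
#' @return A validated object of class `sim_config`.
#' @examples
#' cfg <- sim_config(
#'   n_samples = 50,
#'   snps = data.frame(snp_id = "rs1", chrom = "chr1", pos = 5e6, maf = 0.3),
#'   modules = data.frame(module_id = "M1", gene_id = paste0("g", 1:10))
#' )
#' sim <- sim_dataset(cfg)
#' @export
sim_config <- function(n_samples,
                       snps,
                       modules,
                       effects = NULL,
                       missing_rate = 0,
                       noise_sd = 1,
                       factor_sd = 1,
                       annotation = NULL,
                       edges = list(within = 0.3, between = 0.01,
                                    score_range = c(0.4, 1)),
                       gene_coords = NULL,
                       gender_effect = 0,
                       seed = 1L) {
  stopifnot(n_samples >= 2, missing_rate >= 0, missing_rate <= 1, noise_sd >= 0)
  snps <- tibble::as_tibble(snps)
  stopifnot(all(c("snp_id", "chrom", "pos", "maf") %in% names(snps)))
  if (any(snps$maf <= 0 | snps$maf > 0.5)) {
    stop("`maf` must lie in (0, 0.5]", call. = FALSE)
  }
  if (anyDuplicated(snps$snp_id)) stop("duplicated snp_id", call. = FALSE)

  modules <- tibble::as_tibble(modules)
  stopifnot(all(c("module_id", "gene_id") %in% names(modules)))
  if (!"loading" %in% names(modules)) modules$loading <- 1
  if (anyDuplicated(modules$gene_id)) {
    stop("a gene may belong to only one module", call. = FALSE)
  }

  module_ids <- unique(modules$module_id)
  if (length(factor_sd) == 1 && is.null(names(factor_sd))) {
    factor_sd <- stats::setNames(rep(factor_sd, length(module_ids)), module_ids)
  }
  if (!all(module_ids %in% names(factor_sd))) {
    stop("`factor_sd` must cover every module", call. = FALSE)
  }

  if (!is.null(effects)) {
    effects <- tibble::as_tibble(effects)
    stopifnot(all(c("snp_id", "gene_id", "beta", "kind") %in% names(effects)))
    stopifnot(all(effects$kind %in% c("cis", "trans")))
    if (!all(effects$snp_id %in% snps$snp_id)) {
      stop("planted effect references an undeclared SNP", call. = FALSE)
    }
    if (!all(effects$gene_id %in% modules$gene_id)) {
      stop("planted effect references an undeclared gene", call. = FALSE)
    }
  } else {
    effects <- tibble::tibble(snp_id = character(), gene_id = character(),
                              beta = numeric(), kind = character())
  }

  if (!is.null(annotation)) {
    annotation <- tibble::as_tibble(annotation)
    stopifnot(all(c("category_id", "module_id", "prob") %in% names(annotation)))
    if (any(annotation$prob < 0 | annotation$prob > 1)) {
      stop("annotation probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (!all(annotation$module_id %in% module_ids)) {
      stop("annotation references an unknown module", call. = FALSE)
    }
  } else {
    annotation <- tibble::tibble(category_id = character(),
                                 module_id = character(), prob = numeric())
  }

  stopifnot(is.list(edges), length(edges$score_range) == 2)
  if (edges$within < 0 || edges$within > 1 || edges$between < 0 || edges$between > 1) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(edges$score_range < 0) || any(edges$score_range > 1) ||
      edges$score_range[1] > edges$score_range[2]) {
    stop("`score_range` must be an increasing pair inside [0, 1]", call. = FALSE)
  }
  if (is.null(edges$hubs)) edges$hubs <- character()
  if (is.null(edges$hub_prob)) edges$hub_prob <- 0.95
  if (!all(edges$hubs %in% modules$gene_id)) {
    stop("edge hub references an undeclared gene", call. = FALSE)
  }

  cfg <- structure(
    list(
      n_samples = as.integer(n_samples), snps = snps, modules = modules,
      effects = effects, missing_rate = missing_rate, noise_sd = noise_sd,
      factor_sd = factor_sd, annotation = annotation, edges = edges,
      gender_effect = gender_effect, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  cfg$gene_coords <- if (is.null(gene_coords)) {
    default_gene_coords(cfg)
  } else {
    tibble::as_tibble(gene_coords)
  }
  validate_trans_placement(cfg)
  cfg
}

# Child seeds keep each stage reproducible on its own; modulus keeps the
# derived value inside the 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% (2^31 - 1))
}

default_gene_coords <- function(cfg) {
  genes <- cfg$modules$gene_id
  cis <- cfg$effects[cfg$effects$kind == "cis", , drop = FALSE]
  coords <- tibble::tibble(
    gene_id = genes,
    chrom = "chrZ",
    start = seq_along(genes) * 5e6,
    end = seq_along(genes) * 5e6 + 999
  )
  if (nrow(cis) > 0) {
    first_cis <- cis[!duplicated(cis$gene_id), ]
    idx <- match(first_cis$gene_id, coords$gene_id)
    snp_idx <- match(first_cis$snp_id, cfg$snps$snp_id)
    coords$chrom[idx] <- cfg$snps$chrom[snp_idx]
    coords$start[idx] <- cfg$snps$pos[snp_idx]
    coords$end[idx] <- cfg$snps$pos[snp_idx] + 999
  }
  coords
}

validate_trans_placement <- function(cfg, window = 1e6) {
  tr <- cfg$effects[cfg$effects$kind == "trans", , drop = FALSE]
  if (nrow(tr) == 0) return(invisible(TRUE))
  snp <- cfg$snps[match(tr$snp_id, cfg$snps$snp_id), ]
  gc <- cfg$gene_coords[match(tr$gene_id, cfg$gene_coords$gene_id), ]
  same <- snp$chrom == gc$chrom
  d <- pmax(gc$start - snp$pos, snp$pos - gc$end, 0)
  if (any(same & d <= window)) {
    stop("planted trans effect lies within the cis window of its gene",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate genotypes under Hardy-Weinberg equilibrium
#'
#' Each genotype is drawn independently as Binomial(2, maf) per sample, then
#' masked missing with probability `missing_rate`.  Deterministic given the
#' config (including its seed).
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] with per-SNP summary statistics filled in.
#' @export
sim_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_samples
  m <- nrow(config$snps)
  codes <- vapply(config$snps$maf, function(f) stats::rbinom(n, 2, f),
                  numeric(n))
  if (m == 1) codes <- matrix(codes, ncol = 1)
  if (config$missing_rate > 0) {
    codes[stats::runif(n * m) < config$missing_rate] <- NA_real_
  }
  dimnames(codes) <- list(sprintf("S%03d", seq_len(n)), config$snps$snp_id)
  snps <- config$snps
  snps$ref <- if ("ref" %in% names(snps)) snps$ref else "A"
  snps$alt <- if ("alt" %in% names(snps)) snps$alt else "G"
  snp_stats(genotype_matrix(codes, snps))
}

#' Generate module-structured expression with planted genotype effects
#'
#' Per module m, a latent factor \eqn{F_m \sim N(0, factor\_sd_m^2)} is drawn
#' per sample; gene g of module m takes
#' \eqn{Y_g = loading_g F_m + \sum \beta X_{snp} + \gamma\,gender + N(0, noise\_sd^2)},
#' the sum running over planted effects on g.  Missing genotype codes enter
#' the planted term at their SNP mean so the phenotype stays defined.
#'
#' @param config A [sim_config()].
#' @param genotypes The [genotype_matrix()] produced by [sim_genotypes()]
#'   under the same config.
#' @return An [expression_matrix()] (probes = genes, one probe per gene) with
#'   gender and batch metadata attached.
#' @export
sim_expression <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_matrix"))
  set.seed(child_seed(config$seed, 2L))
  n <- config$n_samples
  genes <- config$modules$gene_id
  module_ids <- unique(config$modules$module_id)

  factors <- vapply(module_ids, function(m) {
    stats::rnorm(n, 0, config$factor_sd[[m]])
  }, numeric(n))
  if (length(module_ids) == 1) factors <- matrix(factors, ncol = 1)
  colnames(factors) <- module_ids

  gender <- stats::rbinom(n, 1, 0.5)

  vals <- matrix(0, nrow = length(genes), ncol = n,
                 dimnames = list(genes, rownames(genotypes$codes)))
  for (i in seq_along(genes)) {
    m <- config$modules$module_id[i]
    vals[i, ] <- config$modules$loading[i] * factors[, m] +
      config$gender_effect * gender
  }
  if (nrow(config$effects) > 0) {
    for (k in seq_len(nrow(config$effects))) {
      ef <- config$effects[k, ]
      x <- genotypes$codes[, ef$snp_id]
      if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
      vals[ef$gene_id, ] <- vals[ef$gene_id, ] + ef$beta * x
    }
  }
  if (config$noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(length(vals), 0, config$noise_sd),
                          nrow = nrow(vals))
  }
  expression_matrix(
    vals,
    probe_map = tibble::tibble(probe_id = genes, gene_id = genes),
    samples = tibble::tibble(sample_id = colnames(vals), gender = gender,
                             batch = "B1")
  )
}

#' Generate a functional-category annotation table
#'
#' Each gene of module m is annotated to a category with that category's
#' per-module probability.
#'
#' @param config A [sim_config()] with a nonempty `annotation` spec.
#' @return A tibble `category_id`, `gene_id`; writable as GMT with
#'   [write_gmt()].
#' @export
sim_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 3L))
  ann <- config$annotation
  if (nrow(ann) == 0) {
    return(tibble::tibble(category_id = character(), gene_id = character()))
  }
  purrr::pmap_dfr(ann, function(category_id, module_id, prob) {
    genes <- config$modules$gene_id[config$modules$module_id == module_id]
    keep <- stats::runif(length(genes)) < prob
    tibble::tibble(category_id = category_id, gene_id = genes[keep])
  })
}

#' Generate a STRING-like functional-evidence edge table
#'
#' Unordered unique gene pairs receive an edge with the within-module
#' probability when both genes share a module and the between-module
#' probability otherwise; combined scores are uniform on `score_range`.
#'
#' @param config A [sim_config()].
#' @return A tibble `gene_a`, `gene_b`, `combined_score` with `gene_a <
#'   gene_b` lexicographically.
#' @export
sim_edges <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 4L))
  genes <- sort(config$modules$gene_id)
  if (length(genes) < 2) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          combined_score = numeric()))
  }
  mod <- stats::setNames(config$modules$module_id, config$modules$gene_id)
  pairs <- utils::combn(genes, 2)
  same <- mod[pairs[1, ]] == mod[pairs[2, ]]
  p <- ifelse(same, config$edges$within, config$edges$between)
  if (length(config$edges$hubs) > 0) {
    touches_hub <- pairs[1, ] %in% config$edges$hubs |
      pairs[2, ] %in% config$edges$hubs
    p[same & touches_hub] <- config$edges$hub_prob
  }
  keep <- stats::runif(ncol(pairs)) < p
  sr <- config$edges$score_range
  tibble::tibble(
    gene_a = pairs[1, keep],
    gene_b = pairs[2, keep],
    combined_score = stats::runif(sum(keep), sr[1], sr[2])
  )
}

#' Truth record for a simulated dataset
#'
#' @param config A [sim_config()].
#' @return A list with `modules` (gene -> module tibble), `effects` (the
#'   planted effect table, unmodified) and `enriched` (for each category, the
#'   module(s) with the highest annotation probability).
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  enriched <- if (nrow(config$annotation) > 0) {
    config$annotation |>
      dplyr::group_by(.data$category_id) |>
      dplyr::filter(.data$prob == max(.data$prob)) |>
      dplyr::ungroup() |>
      dplyr::select("category_id", "module_id")
  } else {
    tibble::tibble(category_id = character(), module_id = character())
  }
  list(
    modules = dplyr::select(config$modules, "gene_id", "module_id"),
    effects = config$effects,
    enriched = enriched
  )
}

#' Generate a complete synthetic dataset
#'
#' Runs every stage generator under the config's child seeds and bundles the
#' pieces with the truth record.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes`, `expression`, `gene_coords`,
#'   `annotation`, `edges`, `truth` and `config`.
#' @export
sim_dataset <- function(config) {
  genotypes <- sim_genotypes(config)
  list(
    genotypes = genotypes,
    expression = sim_expression(config, genotypes),
    gene_coords = config$gene_coords,
    annotation = sim_annotation(config),
    edges = sim_edges(config),
    truth = sim_truth(config),
    config = config
  )
}

#' Generate recombination-hotspot intervals
#'
#' Places `n_per_chrom` non-overlapping hotspot intervals of the given width
#' uniformly on each chromosome, for use with [partition_loci()].
#'
#' @param chrom_sizes Data frame `chrom`, `size` (bp).
#' @param n_per_chrom Hotspots per chromosome.
#' @param width Hotspot width in bp (default 2000).
#' @param seed Seed.
#' @return A tibble `chrom`, `start`, `end` in BED convention (0-based
#'   half-open), sorted within chromosome.
#' @export
sim_hotspots <- function(chrom_sizes, n_per_chrom, width = 2000, seed = 1L) {
  set.seed(as.integer(seed))
  chrom_sizes <- tibble::as_tibble(chrom_sizes)
  purrr::pmap_dfr(chrom_sizes, function(chrom, size) {
    stopifnot(size > (width + 2) * n_per_chrom)
    mids <- sort(sample(seq(width, size - width), n_per_chrom))
    tibble::tibble(
      chrom = chrom,
      start = pmax(0, mids - width %/% 2),
      end = pmin(size, mids + width %/% 2)
    )
  })
}
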