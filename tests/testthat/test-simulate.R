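test_that("config validation rejects out-of-range parameters", {
  snps <- make_snps(2)
  mods <- make_modules(c(3))
  expect_error(sim_config(1, snps, mods), "n_samples")
  bad <- snps; bad$maf <- c(0, 0.3)
  expect_error(sim_config(10, bad, mods), "maf")
  expect_error(
    sim_config(10, snps, mods,
               effects = tibble::tibble(snp_id = "rsX", gene_id = "g001",
                                        beta = 1, kind = "trans")),
    "undeclared SNP"
  )
  expect_error(
    sim_config(10, snps, mods,
               effects = tibble::tibble(snp_id = "rs0001", gene_id = "nope",
                                        beta = 1, kind = "trans")),
    "undeclared gene"
  )
  expect_error(
    sim_config(10, snps, mods,
               annotation = tibble::tibble(category_id = "c", module_id = "MX",
                                           prob = 0.5)),
    "unknown module"
  )
})

test_that("genotype generation matches binomial moments and degenerate cases", {
  # near-zero MAF: almost all codes are 0
  cfg <- sim_config(100, make_snps(1, maf = 0.001), make_modules(2), seed = 3)
  g <- sim_genotypes(cfg)
  expect_gte(mean(g$codes == 0), 0.95)

  # missing_rate = 1: everything missing
  cfg <- sim_config(20, make_snps(3), make_modules(2), missing_rate = 1, seed = 3)
  expect_true(all(is.na(sim_genotypes(cfg)$codes)))

  # binomial moments at n = 10000, maf = 0.3: mean 0.6, het fraction 0.42
  cfg <- sim_config(10000, make_snps(1, maf = 0.3), make_modules(2), seed = 5)
  x <- sim_genotypes(cfg)$codes[, 1]
  se_mean <- sqrt(2 * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(x) - 0.6), 3 * se_mean)
  se_het <- sqrt(0.42 * 0.58 / 10000)
  expect_lt(abs(mean(x == 1) - 0.42), 3 * se_het)
})

test_that("genotype marginals pass chi-square goodness of fit to HWE", {
  cfg <- sim_config(10000, make_snps(3, maf = c(0.1, 0.3, 0.5)),
                    make_modules(2), seed = 7)
  g <- sim_genotypes(cfg)
  for (j in 1:3) {
    f <- cfg$snps$maf[j]
    expected <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    obs <- tabulate(g$codes[, j] + 1, nbins = 3)
    expect_gt(stats::chisq.test(obs, p = expected)$p.value, 0.001)
  }
})

test_that("simulation is deterministic under a fixed config", {
  cfg <- make_cfg(seed = 11,
                  annotation = tibble::tibble(category_id = "immune",
                                              module_id = "M1", prob = 0.8))
  a <- sim_dataset(cfg)
  b <- sim_dataset(cfg)
  expect_identical(a$genotypes$codes, b$genotypes$codes)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$edges, b$edges)
})

test_that("noise-free expression equals the scaled factor / planted slope exactly", {
  # single-gene module, no noise: gene is exactly its loading-scaled factor
  cfg <- sim_config(50, make_snps(1), tibble::tibble(module_id = "M1",
                                                     gene_id = "g001",
                                                     loading = 2),
                    noise_sd = 0, factor_sd = 1.5, seed = 2)
  sim <- sim_dataset(cfg)
  y <- sim$expression$values["g001", ]
  expect_equal(stats::sd(y) > 0, TRUE)

  # loading 0 + planted beta, noise 0: regression recovers the slope exactly
  cfg <- sim_config(
    60, make_snps(1, maf = 0.4),
    tibble::tibble(module_id = "M1", gene_id = "g001", loading = 0),
    effects = tibble::tibble(snp_id = "rs0001", gene_id = "g001",
                             beta = 1.5, kind = "trans"),
    noise_sd = 0, seed = 4
  )
  sim <- sim_dataset(cfg)
  fit <- stats::lm(sim$expression$values["g001", ] ~ sim$genotypes$codes[, 1])
  expect_equal(unname(stats::coef(fit)[2]), 1.5, tolerance = 1e-12)
})

test_that("noise-free within-module pairs are perfectly correlated", {
  cfg <- sim_config(30, make_snps(1), make_modules(c(5, 5)), noise_sd = 0,
                    seed = 6)
  sim <- sim_dataset(cfg)
  cc <- stats::cor(t(sim$expression$values))
  within <- abs(cc[1:5, 1:5])
  expect_true(all(abs(within - 1) < 1e-12))
})

test_that("module structure yields higher within- than between-module correlation", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(200, make_snps(1), make_modules(c(50, 50)),
                      noise_sd = 0.5, seed = s)
    sim <- sim_dataset(cfg)
    cc <- abs(stats::cor(t(sim$expression$values)))
    diag(cc) <- NA
    within <- mean(c(cc[1:50, 1:50], cc[51:100, 51:100]), na.rm = TRUE)
    between <- mean(cc[1:50, 51:100], na.rm = TRUE)
    within > between
  }, logical(1))
  expect_true(all(hits))
})

test_that("annotation generation matches its per-module probabilities", {
  mods <- make_modules(c(50, 450))
  base <- list(n_samples = 10, snps = make_snps(1), modules = mods)
  # prob 1 / 0: category is exactly module A
  cfg <- sim_config(10, make_snps(1), mods,
                    annotation = tibble::tibble(category_id = "cat",
                                                module_id = c("M1", "M2"),
                                                prob = c(1, 0)), seed = 8)
  ann <- sim_annotation(cfg)
  expect_setequal(ann$gene_id, mods$gene_id[mods$module_id == "M1"])
  # prob 0 everywhere: empty
  cfg0 <- sim_config(10, make_snps(1), mods,
                     annotation = tibble::tibble(category_id = "cat",
                                                 module_id = c("M1", "M2"),
                                                 prob = c(0, 0)), seed = 8)
  expect_equal(nrow(sim_annotation(cfg0)), 0)
  # prob 0.8 over 50 + 0.1 over 450: expected size 85 within 3 SE
  cfgp <- sim_config(10, make_snps(1), mods,
                     annotation = tibble::tibble(category_id = "cat",
                                                 module_id = c("M1", "M2"),
                                                 prob = c(0.8, 0.1)), seed = 9)
  size <- nrow(sim_annotation(cfgp))
  se <- sqrt(50 * 0.8 * 0.2 + 450 * 0.1 * 0.9)
  expect_lt(abs(size - 85), 3 * se)
})

test_that("edge generation matches its probabilities and counts", {
  mods4 <- make_modules(c(4))
  cfg <- sim_config(10, make_snps(1), mods4,
                    edges = list(within = 1, between = 0,
                                 score_range = c(0.4, 1)), seed = 2)
  expect_equal(nrow(sim_edges(cfg)), 6)  # complete graph on 4 nodes

  cfg0 <- sim_config(10, make_snps(1), make_modules(c(4, 4)),
                     edges = list(within = 0, between = 0,
                                  score_range = c(0.4, 1)), seed = 2)
  expect_equal(nrow(sim_edges(cfg0)), 0)

  cfg5 <- sim_config(10, make_snps(1), make_modules(c(20)),
                     edges = list(within = 0.5, between = 0,
                                  score_range = c(0.4, 1)), seed = 12)
  n_pairs <- choose(20, 2)
  se <- sqrt(n_pairs * 0.5 * 0.5)
  expect_lt(abs(nrow(sim_edges(cfg5)) - 0.5 * n_pairs), 3 * se)

  # hub genes connect with elevated probability
  cfgh <- sim_config(10, make_snps(1), make_modules(c(30)),
                     edges = list(within = 0.2, between = 0, hubs = "g001",
                                  hub_prob = 1, score_range = c(0.4, 1)),
                     seed = 3)
  ed <- sim_edges(cfgh)
  expect_equal(sum(ed$gene_a == "g001" | ed$gene_b == "g001"), 29)
})

test_that("truth record round-trips the planted configuration", {
  cfg <- make_cfg(seed = 13,
                  annotation = tibble::tibble(category_id = "immune",
                                              module_id = c("M1", "M2", "M3"),
                                              prob = c(0.8, 0.1, 0.1)))
  tr <- sim_truth(cfg)
  expect_equal(sort(unique(tr$modules$module_id)), c("M1", "M2", "M3"))
  expect_identical(tr$effects, cfg$effects)
  expect_equal(tr$enriched$module_id, "M1")
  # empty effects stay empty
  cfg0 <- sim_config(10, make_snps(2), make_modules(c(3)))
  expect_equal(nrow(sim_truth(cfg0)$effects), 0)
})

test_that("planted trans effects must lie outside the cis window", {
  snps <- make_snps(1)
  mods <- make_modules(c(2))
  gc <- tibble::tibble(gene_id = c("g001", "g002"), chrom = "chr1",
                       start = snps$pos + 100, end = snps$pos + 1099)
  expect_error(
    sim_config(10, snps, mods,
               effects = tibble::tibble(snp_id = "rs0001", gene_id = "g001",
                                        beta = 1, kind = "trans"),
               gene_coords = gc),
    "within the cis window"
  )
})
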