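test_that("locus partition cuts at hotspot midpoints and tiles chromosomes", {
  part <- partition_loci(
    tibble::tibble(chrom = "chr1", start = c(99, 199), end = c(101, 201)),
    tibble::tibble(chrom = "chr1", size = 300)
  )
  expect_equal(part$start, c(0, 100, 200))
  expect_equal(part$end, c(100, 200, 300))

  # no hotspots: one locus per chromosome
  p0 <- partition_loci(tibble::tibble(chrom = character(), start = numeric(),
                                      end = numeric()),
                       tibble::tibble(chrom = c("chr1", "chr2"),
                                      size = c(100, 50)))
  expect_equal(nrow(p0), 2)

  # k_c hotspots per chromosome => sum(k_c + 1) loci, tiling exactly
  sizes <- tibble::tibble(chrom = paste0("chr", 1:22), size = 5e6)
  hs <- sim_hotspots(sizes, n_per_chrom = 4, seed = 3)
  part22 <- partition_loci(hs, sizes)
  expect_equal(nrow(part22), 22 * 5)
  tiling <- part22 |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = sum(.data$end - .data$start))
  expect_true(all(tiling$len == 5e6))
  # gap-free: consecutive loci abut
  gaps <- part22 |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(.data$start[-1] == .data$end[-dplyr::n()]))
  expect_true(all(gaps$ok))

  # overlapping hotspots are merged with a warning
  expect_warning(
    pm <- partition_loci(
      tibble::tibble(chrom = "chr1", start = c(90, 100), end = c(110, 120)),
      tibble::tibble(chrom = "chr1", size = 300)
    ),
    "merged"
  )
  expect_equal(nrow(pm), 2)
  expect_error(
    partition_loci(tibble::tibble(chrom = "chr1", start = 0, end = 500),
                   tibble::tibble(chrom = "chr1", size = 300)),
    "outside chromosome"
  )
})

test_that("SNP-to-locus mapping follows the half-open convention", {
  part <- partition_loci(
    tibble::tibble(chrom = "chr1", start = 99, end = 101),
    tibble::tibble(chrom = "chr1", size = 200)
  )
  snps <- tibble::tibble(snp_id = c("a", "b", "c"), chrom = "chr1",
                         pos = c(0, 99, 100))
  m <- map_snps_to_loci(snps, part, based = 0)
  # boundary position 100 belongs to the right-hand locus; 0 to the first
  expect_equal(m$locus_id, c(part$locus_id[1], part$locus_id[1],
                             part$locus_id[2]))
  expect_error(
    map_snps_to_loci(tibble::tibble(snp_id = "x", chrom = "chrX", pos = 5),
                     part),
    "absent from the partition"
  )
  # every random SNP maps to exactly one locus
  sizes <- tibble::tibble(chrom = c("chr1", "chr2"), size = 1e6)
  part2 <- partition_loci(sim_hotspots(sizes, 5, seed = 4), sizes)
  set.seed(5)
  rs <- tibble::tibble(snp_id = paste0("r", 1:1000),
                       chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
                       pos = sample(1:1e6, 1000))
  mm <- map_snps_to_loci(rs, part2, based = 1)
  expect_false(anyNA(mm$locus_id))
  expect_equal(nrow(mm), 1000)
  # containment double-check on a sample
  for (i in sample(1000, 50)) {
    loc <- part2[part2$locus_id == mm$locus_id[i], ]
    expect_true(loc$chrom == mm$chrom[i] &&
                  mm$pos[i] - 1 >= loc$start && mm$pos[i] - 1 < loc$end)
  }
})

tcv_fixture <- function() {
  part <- partition_loci(
    tibble::tibble(chrom = "chr1", start = c(99, 199, 299) - 1,
                   end = c(99, 199, 299) + 1),
    tibble::tibble(chrom = "chr1", size = 400)
  )
  snps <- tibble::tibble(
    snp_id = paste0("s", 1:6), chrom = "chr1",
    pos = c(51, 61, 151, 160, 210, 330)  # loci 1,1,2,2,3,4 (1-based pos)
  )
  list(part = part, map = map_snps_to_loci(snps, part, based = 1))
}

test_that("TCV counts distinct significant loci per gene", {
  fx <- tcv_fixture()
  res <- tibble::tibble(
    transcript_id = "t1", gene_id = "g",
    snp_id = paste0("s", 1:6),
    p_value = c(0.01, 0.02, 0.3, 1e-7, 1e-8, 1e-3),
    label = c("cis", "cis", "cis", "trans", "trans", "trans")
  )
  tcv <- compute_tcv(res, fx$map, cis_alpha = 0.05, trans_alpha = 1e-5)
  # cis: s1, s2 significant, both locus 1 => 1; trans: s4 (locus 2), s5 (locus 3)
  expect_equal(tcv$cis_tcv, 1L)
  expect_equal(tcv$trans_tcv, 2L)

  # no significant SNPs: (0, 0)
  res0 <- dplyr::mutate(res, p_value = 0.99)
  tcv0 <- compute_tcv(res0, fx$map)
  expect_equal(c(tcv0$cis_tcv, tcv0$trans_tcv), c(0L, 0L))

  # duplicate records and transcript order do not change the count
  res_dup <- dplyr::bind_rows(res, res, dplyr::arrange(res, dplyr::desc(snp_id)))
  expect_equal(compute_tcv(res_dup, fx$map), tcv)

  # monotonicity: relaxing alpha never decreases TCV
  tcv_tight <- compute_tcv(res, fx$map, cis_alpha = 0.011, trans_alpha = 1e-9)
  expect_lte(tcv_tight$cis_tcv, tcv$cis_tcv)
  expect_lte(tcv_tight$trans_tcv, tcv$trans_tcv)

  expect_error(compute_tcv(res, fx$map, genes = "missing"), "no tested")
})

test_that("profile comparison matches exact enumeration and degenerate rules", {
  expect_equal(compare_profiles(3, 3, 3, 3)$p_value, 1)
  expect_equal(compare_profiles(5, 0, 0, 5)$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_equal(compare_profiles(4, 0, 7, 0)$p_value, 1)  # zero column
  expect_error(compare_profiles(0, 0, 0, 0), "nonzero")
  expect_error(compare_profiles(-1, 2, 3, 4), "negative")
  # exact-enumeration agreement over random tables
  set.seed(6)
  for (i in 1:60) {
    cells <- as.integer(stats::rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    if (any(rowSums(matrix(cells, 2, byrow = TRUE)) == 0) ||
        any(colSums(matrix(cells, 2, byrow = TRUE)) == 0)) next
    expect_equal(
      compare_profiles(cells[1], cells[2], cells[3], cells[4])$p_value,
      oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
      tolerance = 1e-9
    )
  }
})

test_that("run_comparison flags differential regulation and guards inputs", {
  fx <- tcv_fixture()
  res_a <- tibble::tibble(
    gene_id = "g", snp_id = paste0("s", 1:6),
    p_value = c(0.5, 0.5, 0.5, 1e-8, 1e-8, 1e-8),
    label = c("cis", "cis", "cis", "trans", "trans", "trans")
  )
  res_b <- dplyr::mutate(res_a,
                         p_value = c(1e-3, 1e-3, 1e-3, 0.5, 0.5, 0.5))
  # identical streams: all p = 1, nothing flagged
  same <- run_comparison(res_a, res_a, fx$map)
  expect_equal(same$p_value, 1)
  expect_false(any(same$flagged))

  cmp <- run_comparison(res_a, res_b, fx$map)
  expect_equal(cmp$cis_a, 0L); expect_equal(cmp$trans_a, 3L)
  expect_equal(cmp$cis_b, 2L); expect_equal(cmp$trans_b, 0L)

  # disjoint SNP sets: hard error
  res_c <- dplyr::mutate(res_b, snp_id = paste0("x", 1:6))
  expect_error(run_comparison(res_a, res_c, fx$map), "identical SNP set")
  # gene untested in B
  res_d <- dplyr::mutate(res_b, gene_id = "other")
  expect_error(run_comparison(res_a, res_d, fx$map, genes = "g"),
               "untested in stream B")
})

test_that("planted cell-type regulatory differences are detected", {
  hits <- vapply(1:10, function(s) {
    n_loci <- 30
    part <- partition_loci(
      tibble::tibble(chrom = "chr1",
                     start = seq(1e5, by = 1e5, length.out = n_loci - 1) - 50,
                     end = seq(1e5, by = 1e5, length.out = n_loci - 1) + 50),
      tibble::tibble(chrom = "chr1", size = n_loci * 1e5)
    )
    set.seed(700 + s)
    snp_ids <- paste0("r", 1:40)
    snps <- tibble::tibble(snp_id = snp_ids, chrom = "chr1",
                           pos = sample(1:(n_loci * 1e5 - 1), 40))
    smap <- map_snps_to_loci(snps, part, based = 1)
    # cell A: strong trans signal at 6 SNPs; cell B: cis signal at 6 SNPs
    mk <- function(idx, lab) {
      p <- rep(stats::runif(40, 0.2, 1))
      p[idx] <- 1e-9
      tibble::tibble(gene_id = "g", snp_id = snp_ids, p_value = p,
                     label = lab)
    }
    res_a <- dplyr::bind_rows(mk(1:6, "trans"), mk(integer(), "cis"))
    res_b <- dplyr::bind_rows(mk(integer(), "trans"), mk(7:12, "cis"))
    run_comparison(res_a, res_b, smap)$flagged[1]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
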