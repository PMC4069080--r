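# Small config builders shared across test files.

make_snps <- function(n, chrom = "chr1", maf = 0.3,
                      pos = seq(1e6, by = 3e6, length.out = n)) {
  tibble::tibble(
    snp_id = sprintf("rs%04d", seq_len(n)),
    chrom = chrom, pos = pos,
    maf = rep(maf, length.out = n)
  )
}

make_modules <- function(sizes, prefix = "M") {
  tibble::tibble(
    module_id = rep(paste0(prefix, seq_along(sizes)), times = sizes),
    gene_id = sprintf("g%03d", seq_len(sum(sizes)))
  )
}

# a canonical 3-module config with one planted trans effect on g001
make_cfg <- function(n_samples = 100, sizes = c(30, 30, 30), n_snps = 40,
                     beta = 1.2, noise_sd = 0.5, seed = 1L, ...) {
  sim_config(
    n_samples = n_samples,
    snps = make_snps(n_snps),
    modules = make_modules(sizes),
    effects = tibble::tibble(snp_id = sprintf("rs%04d", min(10L, n_snps)),
                             gene_id = "g001", beta = beta, kind = "trans"),
    noise_sd = noise_sd,
    seed = seed,
    ...
  )
}
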