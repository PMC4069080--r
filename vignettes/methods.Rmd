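---
title: "Methods: systems-genetics trans-eQTL mapping with transreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: systems-genetics trans-eQTL mapping with transreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transreg)
library(dplyr)
```

## The problem

A genome-wide *trans*-eQTL scan crosses every transcript with every SNP. At
the scale of a typical expression array and genotyping chip (~20,000
transcripts x ~600,000 SNPs) that is on the order of 10^10 tests; with the
small sample sizes available for sorted primary cell types (tens of
patients) nothing survives multiple-testing correction. `transreg`
implements a dimensionality-reduction strategy: use the cell type's own
co-expression structure and external functional-evidence networks to pick a
small set of biologically central genes *before* testing, and pay the
multiple-testing price only for those.

The workflow is:

1. detect co-expression modules from the expression matrix
   (weighted-correlation adjacency, topological overlap, hierarchical
   clustering);
2. test each module for over-representation of a process related to the
   phenotype (Fisher's exact test against a gene-set annotation);
3. build a functional network inside each enriched module from an evidence
   edge table (combined scores in [0, 1], e.g. a STRING export);
4. rank genes by degree centrality (DC, hubs) and betweenness centrality
   (BC, bottlenecks) and keep the union of the top genes by either measure;
5. run the trans-eQTL scan restricted to the selected genes.

A companion procedure compares the cis/trans regulatory architecture of two
cell types per gene via the Transcript Complexity Value (TCV): the number
of distinct recombination-hotspot-delimited loci carrying at least one
significant eQTL, tested between cell types with a 2x2 Fisher exact test.

## The association model

For each transcript-SNP pair the package fits

$$Y_i = \alpha + \beta X_i + \gamma^\top C_i + \varepsilon_i$$

where $Y_i$ is the normalized log2 expression of sample $i$, $X_i \in
\{0,1,2\}$ counts minor alleles, and $C_i$ holds covariates (gender by
convention). The two-sided test of $\beta = 0$ uses
$t = r\sqrt{df/(1-r^2)}$ with $r$ the correlation of covariate-residualized
$Y$ and $X$ and $df = n - 2 - n_{cov}$; this is algebraically the OLS
t-statistic (Frisch–Waugh), and the test suite verifies agreement with a
direct normal-equations solve to 1e-10. Samples with a missing genotype are
dropped pairwise per SNP, with the degrees of freedom recomputed. SNPs with
minor allele frequency below 10% (computed on complete genotypes after QC)
are excluded entirely.

A pair is *cis* when SNP and gene share a chromosome and the distance from
the SNP to the closed gene-body interval is at most 1 Mb (inclusive
boundary; distance 0 inside the gene), *trans* otherwise. The window is
measured to the gene body, not the TSS, because distal regulation is
usually quoted as distance from the gene.

FDR is controlled within each scan invocation (a cis scan and a
selected-gene trans scan are corrected separately — each is its own family
of hypotheses). The default q-value is the Storey variant: BH q-values
scaled by $\hat\pi_0 = \min(1, \#\{p > 0.5\}/(0.5\,m))$. Note that a
$\pi_0$-scaled q-value can legitimately drop below its P-value; plain BH
(`fdr_method = "bh"`) never does.

## Preprocessing and genotype QC

* **Probe re-annotation** keeps probes mapping exactly one transcript, and
  multi-mapping probes only when all their transcripts belong to one gene;
  unmapped probes and cross-gene multi-mappers are dropped. The report
  counts each category so totals reconcile exactly.
* **Quantile normalization** (after log2) replaces each sample's ranked
  values by across-sample means of order statistics, ties receiving the
  mean of the spanned order statistics (delegated to
  `limma::normalizeQuantiles(ties = TRUE)`, which implements exactly this
  convention).
* **Batch adjustment** is a per-gene location-scale correction: each batch
  is centred to the gene's grand mean and rescaled to the pooled SD. It is
  deliberately *not* an empirical-Bayes method — there is no shrinkage
  across genes — so it needs a handful of samples per batch to be stable;
  with very small batches an EB method would behave better.
* **HWE filtering** uses the exact two-sided test on the Levene–Haldane
  distribution of the heterozygote count (sum of probabilities not
  exceeding the observed count's). The exact test is preferable to the
  chi-square at the cohort sizes this pipeline targets (tens of samples).
  SNPs with missing fraction > 0.10 or HWE P < 1e-5 are removed; the QC
  report states each filter's count *and the overlap*, because a SNP can
  fail both and naive subtraction then misreconciles.
* **PCA outlier exclusion** standardizes mean-imputed genotypes, computes
  the top 10 principal components, flags samples beyond 6 SD on any of
  them, and iterates up to 10 times.

## Co-expression modules

Unsigned adjacency $a_{ij} = |cor_{ij}|^\beta$ with default power 6; the
topological overlap measure

$$TOM_{ij} = \frac{\sum_{u\neq i,j} a_{iu}a_{uj} + a_{ij}}
                 {\min(k_i,k_j) + 1 - a_{ij}}$$

is clustered by average linkage on $1 - TOM$ and cut at a fixed height.
Design choices, all configurable:

* **Static cut, not dynamic tree cut.** A fixed-height cut is
  deterministic and fully specifiable, at the cost of flexibility on real
  dendrograms; this is a deliberate divergence from the dynamic hybrid
  cut used by common WGCNA workflows.
* **Default `cut_height = 0.95`.** Under the factor model that generates
  module structure here, within-module TOM for genes with correlation
  $\rho$ at power 6 is roughly $\rho^6$-sized, so within-module
  *dissimilarity* sits around 0.7–0.98 while between-module dissimilarity
  is essentially 1. A cut near 1 (0.95) separates these; cutting low
  (e.g. 0.25) would declare every gene a singleton for any realistic noise
  level. Module size floor `min_size = 30`; smaller clusters pool into the
  unassigned label M0.
* **Determinism.** Genes are sorted lexicographically before clustering
  and module labels are assigned by decreasing size (ties by smallest
  member ID), so results are invariant to input row order.
* Pearson correlation is used rather than a robust midcorrelation — a
  simplicity trade-off that matters mostly for heavy-tailed expression at
  small n.

The soft-threshold helper regresses log10 frequency on log10 connectivity
over binned degrees and returns the smallest power whose signed $R^2$
reaches the target (0.8), mirroring the usual scale-free-fit criterion.

## Enrichment, networks, centrality

Module enrichment is a two-sided Fisher exact test on the 2x2 membership
table over the analyzed gene universe; only *over*-represented modules at
alpha = 0.05 advance (an under-represented module is significant but points
away from the process of interest). The alpha is uncorrected across
categories by default because the intended use tests one curated category
family; a Bonferroni flag would be a one-line wrapper.

Functional networks keep edges with both endpoints in the module and
combined score >= 0.4 (the conventional medium-confidence cutoff for
combined evidence scores); genes without a retained edge are excluded.
DC is the raw integer edge count. BC is unweighted shortest-path
betweenness normalized by $(n-1)(n-2)/2$; in disconnected networks the
global normalizer is kept so values remain comparable across components.
Selection takes the union of hubs and bottlenecks, either by absolute
thresholds or by a top-quantile rule (default top 10% by each measure).

## TCV comparison

Chromosomes are cut at hotspot midpoints (an interval-valued hotspot is
reduced to its midpoint; whether the interval or the point delimits loci is
not observable from published locus counts, and the midpoint is the neutral
choice). A chromosome with k hotspots yields k+1 loci that tile it exactly,
in 0-based half-open coordinates. Each SNP maps to the unique locus
containing its position. A gene's cis TCV counts distinct loci with a
cis-labeled association at nominal P < 0.05; the trans TCV uses P < 1e-5 —
asymmetric thresholds reflecting the much larger trans search space.
Multiple transcripts of a gene contribute by union of significant loci.
Differential regulation between two cell types is the two-sided Fisher
exact test on [[cis_A, trans_A], [cis_B, trans_B]]; degenerate margins give
P = 1. Both cell types must be scanned on the identical SNP set — the
comparison errors out otherwise rather than silently comparing
incommensurable locus counts. Nominal rather than FDR-adjusted P-values
feed the TCV (the thresholds are screening rules, not inference), and the
per-gene Fisher tests are reported uncorrected by default.

## The synthetic-data generator

`sim_config()` / `sim_dataset()` generate every input with known truth:

* **Genotypes**: Binomial(2, MAF) per sample (Hardy–Weinberg), i.i.d.
  across SNPs; missingness applied uniformly at random afterwards. No LD,
  no population structure — deliberately, so that planted effects are the
  only genotype-expression signal.
* **Expression**: per module m a latent factor $F_m \sim N(0,
  \sigma_{F,m}^2)$ per sample; gene g of module m is $\ell_g F_m + \sum
  \beta X + \gamma\,gender + N(0, \sigma^2)$. Loadings default to 1 so the
  factor is identifiable. The factor model is an *assumption* about module
  covariance: real co-expression has heavier tails, nonlinearities and
  overlapping pathways, so passing recovery tests here demonstrates
  correctness of the machinery, not performance on real arrays.
* **Planted effects** declare SNP, gene, slope and cis/trans kind; default
  gene placement puts cis genes at their SNP and everything else on a
  SNP-free chromosome, and the config validates that a planted trans
  effect cannot sit inside its gene's cis window. Realistic recoverable
  slopes are |beta| in roughly 0.3–1.9 expression units per allele.
* **Annotation**: per-module membership probabilities generate a category;
  the planted enriched module is the one with the highest probability.
* **Edges**: within-module pairs connect with one probability, cross-module
  pairs with another; optional hub genes connect at an elevated
  probability, giving them high degree for selection tests.
* **Determinism**: one master seed; each stage draws from a fixed-offset
  child seed, so identical configs give byte-identical outputs and single
  stages are reproducible in isolation.

## Numerical and scale choices

Perfect fits return P = 0 rather than erroring; constant expression
returns beta = 0, P = 1; monomorphic-after-missingness SNPs are skipped.
Correlations are clamped to [-1, 1] before the t-transform. TOM values are
clamped to [0, 1] against floating-point drift (asserted to 1e-12 in
tests).

Simulation-based checks in the test suite use 20 replicate seeds with
n = 120–200 samples, 40–2,000 SNPs and 15–150 genes; null calibration uses
2,000 SNPs x 20 transcripts (40,000 tests per replicate). These sizes give
stable pass/fail behaviour for the stated thresholds (e.g. ARI >= 0.9 in
>= 90% of seeds) while keeping the default test run fast.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  n_samples = 120,
  snps = tibble::tibble(snp_id = sprintf("rs%04d", 1:40), chrom = "chr1",
                        pos = seq(1e6, by = 3e6, length.out = 40), maf = 0.3),
  modules = tibble::tibble(module_id = rep(paste0("M", 1:3), each = 30),
                           gene_id = sprintf("g%03d", 1:90)),
  effects = tibble::tibble(snp_id = "rs0015", gene_id = "g001",
                           beta = 1.2, kind = "trans"),
  noise_sd = 0.5,
  annotation = tibble::tibble(category_id = "immune_system",
                              module_id = paste0("M", 1:3),
                              prob = c(0.9, 0.05, 0.05)),
  edges = list(within = 0.3, between = 0.02, hubs = "g001",
               hub_prob = 0.95, score_range = c(0.5, 1)),
  seed = 42
)
sim <- sim_dataset(cfg)
pl <- run_pipeline(sim, params = list(min_size = 20))
glance(pl)
tidy(pl$trans) |> dplyr::slice_min(p_value, n = 3)
```

## Known limitations

* No LD or kinship modelling: the scan assumes unrelated samples and
  treats SNPs independently; significant trans-eQTLs in LD with each other
  are reported separately.
* The batch adjustment is location-scale only (no EB shrinkage).
* The static dendrogram cut can merge adjacent modules on real data where
  module boundaries are fuzzy; the cut height should be inspected against
  the dendrogram.
* Betweenness values depend on the evidence network's edge coverage;
  centrality from sparse or biased evidence tables inherits that bias.
* TCV treats hotspot-delimited loci as independent, which is an
  approximation to the underlying LD structure.
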