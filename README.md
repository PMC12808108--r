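# xireact

Allele-specific analysis of X-chromosome inactivation escape and
reactivation along a neural differentiation axis.

In female cells one X-chromosome is silenced, but silencing is incomplete
and dynamic: some genes escape X-inactivation everywhere, and others are
reactivated from the inactive X (Xi) as iPSCs differentiate into neural
progenitors (NPCs) and neurons. At a heterozygous variant site, the
fraction of RNA-seq reads carrying the minor allele estimates how much
expression comes from Xi. `xireact` implements the full downstream
statistical pipeline on such allelic counts:

* **Variant classification** — pool replicate counts per cell type,
  estimate the Xi-expression probability
  `p̂_Xi = min(No.Ref/No.Total, 1 − No.Ref/No.Total)`, and label each site
  **reactivated** (monoallelic in iPSC, ratio < 0.025 or > 0.975, with
  `p̂_Xi` significantly > 0.025 in NPC and/or neurons), **escape**
  (`p̂_Xi` significantly > 0.1 in all cell types), **late-silenced**, or
  **inactive**, using one-sided exact binomial tests with
  Benjamini–Hochberg correction (adjusted p < 0.01), plus an automated flag
  for calls whose minor-allele reads come from a single replicate.
* **Gene-level calls** — majority/SNP-priority/coverage rules collapse
  variants to one category per gene; fixed-effect inverse-variance
  meta-analysis of logit-transformed proportions gives a pooled estimate
  with a 99% CI.
* **Gene-set statistics** — resampling overlap enrichment against known
  escapee or disease gene sets, a TSS pairwise-distance clustering test,
  chromatin-state enrichment (one-sided Wilcoxon + BH), and a Fisher test
  of sex-biased expression breadth.
* **Single-cell allelic scores** — per cell and site, the biallelic score
  `s = −ln(major-allele fraction)` (0 monoallelic, 0.69 balanced), summed
  over non-PAR X-linked sites and per gene category, with pseudotime
  binning and the depth-normalized pseudo-bulk variant filter.
* **Transcriptional deviation** — per-cell mean fold change over
  cluster-specific DE genes (reciprocal for downregulated genes), 1 on the
  control profile.
* **Synthetic data** — a seeded generator producing allelic count tables,
  annotations, sparse allele-resolved UMI matrices and expression matrices
  with known ground truth, so every stage is testable without sequencing
  data.

## Worked example

Simulate a 60-gene study (3 cell types × 4 replicates), classify variants,
collapse to genes, and test whether reactivated genes cluster on the
chromosome:

```r
library(xireact)

cfg   <- sim_config(n_genes = 60, seed = 7)
sim   <- simulate_bulk_allelic_counts(cfg)
flt   <- filter_variants(sim$sites, sim$counts)
summ  <- pool_by_cell_type(flt$counts)
calls <- flag_replicate_inconsistency(flt$counts, classify_variants(summ))
genes <- gene_calls(calls, flt$sites, summ)
table(genes$category)
#>   reactivated        escape late_silenced      inactive    untestable
#>             6            12             9            33             0

head(subset(genes, category == "reactivated"), 3)
#>       gene    category n_variants pooled_xi_estimate ci_low ci_high
#> 17 gene017 reactivated          1              0.243  0.190   0.305
#> 21 gene021 reactivated          3              0.242  0.211   0.275
#> 27 gene027 reactivated          2              0.231  0.192   0.275
```

Each reactivated gene carries a pooled estimate of the fraction of its
expression originating from the inactive X (here ~24%) with a 99%
confidence interval from the logit-scale meta-analysis of its variants.
With a fully clustered synthetic layout, the TSS distance test detects the
clustering:

```r
ann <- simulate_annotation(cfg, clustered_fraction = 1)
tss_distance_test(genes$gene[genes$category == "reactivated"], ann,
                  n_iter = 1000, seed = 1)
#> Resampling test (1000 iterations, seed 1)
#>   observed:    3904.4
#>   background: 51846258 +/- 12614446
#>   p (normal CDF, lower tail): 1.980349e-05   p (empirical): 0.000999001
```

The observed mean pairwise TSS distance (~3.9 kb) is far below the random
background (~52 Mb), so the probability of a smaller distance by chance is
essentially zero.

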