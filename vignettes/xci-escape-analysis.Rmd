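---
title: "Classifying X-inactivation escape and reactivation from allelic counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying X-inactivation escape and reactivation from allelic counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(xireact)
```

## The problem

In female cells one X-chromosome is transcriptionally silenced (X-chromosome
inactivation, XCI). Silencing is incomplete: some genes *escape* XCI in every
cell type, others are *reactivated* from the inactive X (Xi) as pluripotent
cells differentiate into neural progenitors and neurons, and a few are
biallelic in iPSCs but silenced later (*late-silenced*). At a heterozygous
variant site, RNA-seq reads can be assigned to alleles, so the fraction of
reads from the minor allele estimates how much expression originates from Xi.
`xireact` turns replicate-level allelic read counts along a differentiation
axis (iPSC, NPC, neuron) into variant- and gene-level calls of these four
states, and adds the downstream set-level and single-cell statistics used to
characterise the resulting gene classes.

## Variant-level model

For each variant and cell type, reads are pooled over replicates. With
`No.Ref` reference reads out of `No.Total`, the allelic ratio is
`No.Ref / No.Total` and the probability of expression from Xi is estimated
by the minor-allele fraction

$$\hat p_{Xi} = \min\left(\tfrac{No.Ref}{No.Total},\; 1 - \tfrac{No.Ref}{No.Total}\right) \in [0, 0.5],$$

which is exactly the two-branch definition (reference fraction if the
reference allele is the minor one, its complement otherwise) written without
the branch; both branches give 0.5 at a tie, so nothing is lost.

Sites enter the analysis only if they intersect a gene, are biallelic, have
call quality of at least 100, are not indels longer than 50 bp, have at
least 5 reads in every sample, and at least 20 pooled reads in a cell type
to be testable there (all thresholds are arguments).

Expression from Xi is tested with a one-sided exact binomial test of the
pooled minor-allele count against a null proportion $p_0$:
$P(X \ge x \mid n, p_0)$. Categories are then assigned with precedence
escape → reactivated → late-silenced:

* **escape**: $\hat p_{Xi}$ significantly greater than 0.1 in *all* cell
  types;
* **reactivated**: monoallelic in iPSC (ratio < 0.025 or > 0.975) and
  $\hat p_{Xi}$ significantly greater than 0.025 in NPC, neurons, or both;
* **late-silenced**: $\hat p_{Xi} < 0.025$ in NPC and neurons and
  significantly greater than 0.025 in iPSC;
* otherwise **inactive**; variants failing group coverage anywhere are
  **untestable**.

Significance means Benjamini–Hochberg adjusted p < 0.01. The BH family is
genuinely open: we correct within each (classification family × cell type)
candidate set, which matches the sequential "first select candidates, then
test" structure of the procedure; a `global` option pools a family's tests
across cell types instead. The binomial observation is the pooled
minor-allele count — only pooled counts exist at the group level, so this is
the only self-consistent choice.

`flag_replicate_inconsistency()` automates the curation step that catches
the common false-positive mode of pooled analysis: minor-allele reads
contributed almost entirely by a single replicate. A call is flagged when
every cell type driving its biallelic evidence either has ≥ 90% (default)
of pooled minor reads in one replicate or has all but one replicate
strictly monoallelic. We require the pattern in *every* driving cell type
because one well-supported cell type is already genuine biallelic evidence;
flagged calls are kept but marked, with an option to demote them to
inactive.

## Gene-level calls

A gene inherits the majority category of its biallelic variants; ties are
re-voted over SNPs only (SNPs are more reliable than indels), and a
remaining tie goes to the category with the best-covered variant. The
gene-level Xi-expression estimate pools the chosen variants'
(minor count, total) pairs by fixed-effect inverse-variance meta-analysis on
the logit scale, with a 99% normal-approximation CI back-transformed through
the inverse logit. Each variant contributes the driving cell type in which
its biallelic signal is strongest (differentiated cell types for
reactivated genes, iPSC for late-silenced, all for escape/inactive).

Two open numerical choices, and what we chose:

* *Continuity correction.* The logit is undefined at x = 0 or x = n. We
  apply the Haldane–Anscombe correction (x + 0.5, n + 1) **only to boundary
  counts**, as standard proportion meta-analysis tools do; interior counts
  are left exact, so a single (30, 100) variant pools to exactly 0.30 with
  the textbook single-proportion logit interval.
* *Fixed vs random effects.* Fixed-effect is the default — the procedure is
  described simply as "inverse-variance" and variants of one gene measure
  the same underlying proportion. `method = "random"` (DerSimonian–Laird)
  is available for heterogeneous genes.

## Set-level statistics

All resampling tests share one shape: an observed statistic, a background
of 1000 (default) random same-size gene draws without replacement, and a
p-value from the normal CDF fitted to the background. Because a normal fit
can misbehave in the far tail, the empirical quantile p-value is always
reported alongside (`p_empirical`); they agree under the null and the
empirical one is the safer choice for calibration checks.

* `overlap_enrichment()` — observed/expected overlap with a reference set
  (known escapees, NDD genes), upper-tail p.
* `tss_distance_test()` — mean pairwise TSS distance of a category, lower
  tail (do the genes cluster on the chromosome?). The statistic is computed
  in O(k log k) from sorted positions; a brute-force pair enumeration backs
  it in the tests.
* `chromatin_state_comparison()` — per-state one-sided Wilcoxon rank-sum
  tests of gene-body state percentages against inactive genes, BH across
  states, significance at adjusted p < 0.05, effect reported as
  log(mean query / mean inactive).
* `sex_bias_test()` — Fisher's exact test on genes binned by the number of
  tissues with female-biased expression. The bin edges are not fixed by the
  source description; defaults are 0, 1–5, 6–15, > 15, configurable, with
  an optional 2×2 collapse (no bias vs any bias).

The universe is always an explicit argument; `expressed_universe()`
implements the usual "> 10 normalized reads in every sample" filter.

## Single-cell allelic scores

Per cell and site, the major-allele fraction is
r = max(ref, alt)/(ref + alt) ∈ [0.5, 1] and the biallelic score is
s = −ln r ∈ [0, ln 2]: 0 for a monoallelic site, 0.69 for a balanced one.
(The source text says "the natural logarithm of this ratio", which is ≤ 0;
its printed anchor values, 0 and 0.69, fix the sign as −ln r.) Scores are
summed per cell over non-PAR X-linked sites — pseudoautosomal genes escape
as a block and would inflate the sum — and per category (reactivation score
over reactivated genes, escapee score over full escapees). When a gene has
several traceable sites in one cell, their UMIs are summed before the
fraction is taken (maximum information; `per_gene = FALSE` scores sites
separately). `min_umis_per_site` defaults to 1: any covered site is scored,
since a stricter default silently biases sums toward zero.

The per-site score at finite depth is biased below its infinite-depth
limit: for a balanced site with n UMIs,
E[s] = ln 2 − E[ln(1 + 2|X/n − 1/2|)], about 0.59 at n = 50 and within 5%
of ln 2 only beyond roughly 500 UMIs. The tests therefore check convergence
with depth rather than asserting the limit at shallow depth.

Pseudo-bulk variant detection uses the depth-normalized filter
(≥ 50 reads per 5×10⁸ total reads for single-cell, ≥ 2 for single-nucleus
libraries, both alleles at PHRED ≥ 20). Pseudotime itself is an input
column (diffusion pseudotime, latent time — embedding methods are out of
scope); `bin_by_pseudotime()` summarises any per-cell value in equal-width
bins (50 by default, 40 used for some published datasets).

## Transcriptional deviation

For each cluster, DE genes between control and mutant (adjusted p < 0.01,
|log2 FC| > 2 by default; the permissive 0.25 screen is the same function
with a different threshold) define a signature. A cell's deviation is the
mean, over the cluster's DE genes, of (expr + ε)/(ctrl mean + ε) for
upregulated genes and its reciprocal for downregulated ones — 1 when the
cell sits on the control profile. ε (default 1e-9) only guards zero
denominators; the statistic operates on linear (de-logged) normalized
expression, since fold changes of log-scale values would not reproduce the
anchor "a 4-fold gene scores 4". `rank_sum_de()` is a minimal Wilcoxon
rank-sum DE helper so the statistic is self-testable on synthetic data;
real analyses may supply their own DE table.

## What the synthetic generator emulates

`sim_config()` fixes the ground truth: per-gene categories, per-cell-type
true Xi-expression probabilities consistent with them (reactivated:
≤ 0.01 in iPSC and ≥ 0.10 later; escape: ≥ 0.15 everywhere; late-silenced:
the reverse ramp; inactive: ≤ 0.01), 1–3 variants per gene, and 3–8
replicates per cell type (default 4). Depth is negative-binomial
(default mean 100 reads/replicate, dispersion 0.3) so the ≥ 5-read and
≥ 20-read filters see realistic dropout; haplotype phase is drawn once per
gene, mirroring physical haplotypes. Single-cell counts are Poisson totals
(default mean 2 UMIs/site) thinned by a detection rate, with the allele
fraction following a piecewise-linear p_Xi trajectory along a uniform
pseudotime — the simplest monotone reactivation model. All randomness flows
from one master seed with fixed per-output offsets, so identical
(config, seed) reproduces identical outputs and regenerating one output
does not disturb the others.

What it does **not** model: allelic mapping bias, reference bias from
alignment, ambient RNA, doublets, cell-type-specific depth, or correlated
replicate effects. Passing the recovery tests therefore shows the
statistical machinery is correct under the stated sampling model, not that
real libraries meet that model.

Problem sizes used in the shipped tests: the recovery fixture is 200 genes
× 3 cell types × 4 replicates at ~400× group depth (per-category
sensitivity and specificity ≥ 0.9 against truth); null calibration uses
1000 variants at the boundary proportion 0.025 (≤ 2% false reactivated
calls at α = 0.01); resampling calibration uses 500 null repetitions of a
15-gene query against a 150-gene universe. These sizes give stable
pass/fail behaviour while keeping the whole suite in seconds.

## Limitations

* The classifier assumes exactly one pluripotent reference cell type
  followed by differentiated ones; designs without an iPSC-like anchor
  cannot define reactivation.
* Pooling replicates discards between-replicate overdispersion; the
  curation flag catches the worst mode (single-replicate support) but a
  beta-binomial test would model it properly.
* Gene-level meta-analysis treats variants of a gene as independent
  measurements; linked variants in one transcript are positively
  correlated, so gene-level CIs are somewhat anticonservative.
* The normal-CDF resampling p-values are approximations; empirical
  quantile p-values are reported alongside and preferred for small tails.
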