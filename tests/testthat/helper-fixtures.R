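# Shared fixture builders for the test suite.

# Minimal site table: n biallelic SNPs on chrX assigned to `gene`.
make_sites <- function(ids, gene = "G1", qual = 200, ref = "A", alt = "G") {
  data.frame(variant_id = ids, gene = gene, chrom = "chrX",
             pos = seq_along(ids) * 100L, ref_allele = ref, alt_allele = alt,
             qual = qual, stringsAsFactors = FALSE)
}

# Count rows for one variant across samples; ref/total given per sample.
make_counts <- function(variant_id, ref, total,
                        cell_type = "iPSC",
                        sample_id = paste0(cell_type, "_rep",
                                           seq_along(ref))) {
  data.frame(variant_id = variant_id, sample_id = sample_id,
             cell_type = cell_type, ref_reads = ref, total_reads = total,
             stringsAsFactors = FALSE)
}

# Group summary rows for one variant across the three standard cell types,
# from pooled (ref, total) pairs.
make_summary <- function(variant_id, ref, total,
                         cell_types = c("iPSC", "NPC", "neuron"),
                         min_group_reads = 20) {
  counts <- do.call(rbind, lapply(seq_along(cell_types), function(i) {
    make_counts(variant_id, ref[i], total[i], cell_type = cell_types[i],
                sample_id = paste0(cell_types[i], "_rep1"))
  }))
  pool_by_cell_type(counts, min_group_reads = min_group_reads)
}

# Brute-force upper-tail binomial p-value by pmf summation (oracle).
brute_binom_upper <- function(x, n, p0) {
  sum(stats::dbinom(x:n, n, p0))
}

# Brute-force mean pairwise distance by pair enumeration (oracle).
brute_mean_pairwise <- function(pos) {
  d <- combn(pos, 2, function(p) abs(p[1] - p[2]))
  mean(d)
}

# Per-category sensitivity/specificity of predicted vs true labels.
class_performance <- function(pred, truth, categories) {
  vapply(categories, function(k) {
    tp <- sum(pred == k & truth == k)
    fn <- sum(pred != k & truth == k)
    fp <- sum(pred == k & truth != k)
    tn <- sum(pred != k & truth != k)
    c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
  }, numeric(2))
}
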