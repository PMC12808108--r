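#' Estimate the probability of expression from the inactive X
#'
#' Converts a reference-allele ratio into an estimate of the probability
#' \eqn{\hat{p}_{Xi}} that a read originates from the inactive X-chromosome.
#' The estimate is the minor-allele fraction: `ref/total` when the reference
#' allele is the minor allele, `1 - ref/total` otherwise, i.e.
#' `min(ratio, 1 - ratio)`. Both branches coincide at a 50/50 ratio, so the
#' branch-free form is used.
#'
#' @param no_ref Pooled reads supporting the reference allele (vectorised).
#' @param no_total Pooled total reads covering the site.
#' @return Numeric vector of estimates in `[0, 0.5]`; `NA` where
#'   `no_total == 0`.
#' @examples
#' xi_probability(2, 100)   # 0.02
#' xi_probability(98, 100)  # 0.02
#' @export
xi_probability <- function(no_ref, no_total) {
  stopifnot(length(no_ref) == length(no_total))
  bad <- !is.na(no_ref) & !is.na(no_total) &
    (no_ref < 0 | no_total < 0 | no_ref > no_total)
  if (any(bad)) {
    stop("invalid counts: need 0 <= no_ref <= no_total (first offending index ",
         which(bad)[1], ")")
  }
  ratio <- ifelse(no_total > 0, no_ref / no_total, NA_real_)
  pmin(ratio, 1 - ratio)
}

#' Filter heterozygous variant sites before allele-specific analysis
#'
#' Applies, in order, the site-level and coverage filters used before
#' allelic-ratio computation: (1) the variant must intersect a known gene,
#' (2) it must be biallelic (exactly one reference and one alternative
#' allele), (3) its call quality must be at least `qual_min`, (4) indels
#' longer than `indel_max_len` are dropped, and (5) the site must be covered
#' by at least `min_reads_per_sample` reads in every sample.
#'
#' @param sites data.frame of variant sites with columns `variant_id`,
#'   `gene`, `chrom`, `pos`, `ref_allele`, `alt_allele`, `qual`. Multiallelic
#'   sites are encoded with comma-separated `alt_allele`.
#' @param counts data.frame of per-sample allele counts with columns
#'   `variant_id`, `sample_id`, `cell_type`, `ref_reads`, `total_reads`.
#' @param qual_min Minimum variant quality score retained (default 100;
#'   sites with quality below this are removed).
#' @param indel_max_len Maximum allele length difference in bp (default 50).
#' @param min_reads_per_sample Minimum total reads required in every sample
#'   (default 5).
#' @return A list with `sites` (retained rows of `sites`), `counts` (count
#'   rows for retained variants) and `tally`, a data.frame reporting the
#'   number of variants removed by each rule in application order.
#' @export
filter_variants <- function(sites, counts, qual_min = 100,
                            indel_max_len = 50, min_reads_per_sample = 5) {
  .check_cols(sites, c("variant_id", "gene", "ref_allele", "alt_allele", "qual"),
              "sites")
  .check_cols(counts, c("variant_id", "sample_id", "ref_reads", "total_reads"),
              "counts")
  if (anyDuplicated(sites$variant_id)) {
    stop("duplicated variant_id in 'sites'")
  }
  unknown <- !(counts$variant_id %in% sites$variant_id)
  if (any(unknown)) {
    stop("count row ", which(unknown)[1], " references unknown variant_id '",
         counts$variant_id[which(unknown)[1]], "'")
  }

  keep <- sites
  tally <- data.frame(rule = character(), removed = integer())
  drop_rule <- function(keep, drop_mask, rule) {
    tally <<- rbind(tally, data.frame(rule = rule, removed = sum(drop_mask)))
    keep[!drop_mask, , drop = FALSE]
  }

  keep <- drop_rule(keep, is.na(keep$gene) | keep$gene == "", "intergenic")
  multi <- grepl(",", keep$alt_allele) | grepl(",", keep$ref_allele) |
    keep$alt_allele == "" | keep$ref_allele == ""
  keep <- drop_rule(keep, multi, "not_biallelic")
  keep <- drop_rule(keep, keep$qual < qual_min, "quality")
  ilen <- abs(nchar(keep$ref_allele) - nchar(keep$alt_allele))
  keep <- drop_rule(keep, ilen > indel_max_len, "long_indel")

  cnt <- counts[counts$variant_id %in% keep$variant_id, , drop = FALSE]
  min_tot <- tapply(cnt$total_reads, cnt$variant_id, min)
  low <- names(min_tot)[min_tot < min_reads_per_sample]
  # a variant absent from the count table has no evidence of expression
  low <- union(low, setdiff(keep$variant_id, cnt$variant_id))
  keep <- drop_rule(keep, keep$variant_id %in% low, "low_sample_coverage")

  list(sites = keep,
       counts = counts[counts$variant_id %in% keep$variant_id, , drop = FALSE],
       tally = tally)
}

#' Pool allele counts across replicates of each cell type
#'
#' Sums reference and total reads over all replicate samples of each cell
#' type and computes the group-level allelic ratio and the inactive-X
#' expression estimate (see [xi_probability()]). Pairs covered by fewer than
#' `min_group_reads` pooled reads are marked untestable.
#'
#' @inheritParams filter_variants
#' @param min_group_reads Minimum pooled reads per (variant, cell type)
#'   required for testing (default 20).
#' @return data.frame with one row per (variant, cell type): `no_ref`,
#'   `no_total`, `allelic_ratio`, `xi_prob_hat`, `xi_count` (pooled
#'   minor-allele reads) and logical `testable`.
#' @export
pool_by_cell_type <- function(counts, min_group_reads = 20) {
  .check_cols(counts, c("variant_id", "cell_type", "ref_reads", "total_reads"),
              "counts")
  if (any(counts$ref_reads < 0 | counts$ref_reads > counts$total_reads)) {
    stop("ref_reads must satisfy 0 <= ref_reads <= total_reads")
  }
  agg <- stats::aggregate(
    counts[c("ref_reads", "total_reads")],
    by = list(variant_id = counts$variant_id, cell_type = counts$cell_type),
    FUN = sum)
  out <- data.frame(
    variant_id = agg$variant_id,
    cell_type = agg$cell_type,
    no_ref = as.integer(agg$ref_reads),
    no_total = as.integer(agg$total_reads),
    stringsAsFactors = FALSE
  )
  out$allelic_ratio <- ifelse(out$no_total > 0, out$no_ref / out$no_total,
                              NA_real_)
  out$xi_prob_hat <- xi_probability(out$no_ref, out$no_total)
  out$xi_count <- pmin(out$no_ref, out$no_total - out$no_ref)
  out$testable <- out$no_total >= min_group_reads
  rownames(out) <- NULL
  out[order(out$variant_id, out$cell_type), , drop = FALSE]
}

#' One-sided binomial test for expression from the inactive X
#'
#' Exact upper-tail binomial p-value \eqn{P(X \ge x \mid n, p_0)} for the
#' pooled minor-allele count, testing whether the inactive-X expression
#' probability exceeds the null proportion `p0`.
#'
#' @param xi_count Pooled minor-allele reads (vectorised).
#' @param no_total Pooled total reads.
#' @param p0 Null proportion in (0, 1), e.g. 0.025 for the reactivation test
#'   or 0.1 for the escape test.
#' @return Numeric vector of p-values; `NA` where `no_total == 0`
#'   (untestable).
#' @export
test_xi_expression <- function(xi_count, no_total, p0) {
  stopifnot(p0 > 0, p0 < 1)
  if (any(xi_count < 0 | xi_count > no_total, na.rm = TRUE)) {
    stop("xi_count must satisfy 0 <= xi_count <= no_total")
  }
  p <- stats::pbinom(xi_count - 1, no_total, p0, lower.tail = FALSE)
  p[no_total == 0] <- NA_real_
  p
}

#' Classify variant sites as reactivated, escape, late-silenced or inactive
#'
#' Implements the variant-level decision rules on pooled group summaries.
#' A variant is testable only if every cell type meets the group coverage
#' threshold. Testable variants are labelled with precedence
#' escape > reactivated > late-silenced:
#'
#' * **escape** -- the one-sided binomial test of
#'   \eqn{\hat{p}_{Xi} > } `escape_p0` is significant (BH-adjusted
#'   p < `alpha`) in every cell type;
#' * **reactivated** -- the reference cell type (first of `cell_types`,
#'   normally iPSC) is monoallelic (allelic ratio < `mono_cutoff` or
#'   > 1 - `mono_cutoff`) and the test of \eqn{\hat{p}_{Xi} > }
#'   `null_p0` is significant in at least one differentiated cell type;
#' * **late_silenced** -- \eqn{\hat{p}_{Xi} < } `mono_cutoff` in every
#'   differentiated cell type and the `null_p0` test is significant in the
#'   reference cell type;
#' * otherwise **inactive**.
#'
#' Benjamini-Hochberg correction is applied within each
#' (classification family x cell type) set of candidate variants
#' (`bh_family = "per_celltype"`, the default) or jointly across all tests
#' of a family (`bh_family = "global"`).
#'
#' @param summaries Group summaries from [pool_by_cell_type()].
#' @param cell_types Ordered cell-type labels; the first is the pluripotent
#'   reference state, the rest are differentiated states.
#' @param mono_cutoff Allelic-ratio cutoff declaring monoallelic expression
#'   (default 0.025, i.e. ratio < 0.025 or > 0.975).
#' @param null_p0 Null proportion for the reactivation/late-silencing tests
#'   (default 0.025).
#' @param escape_p0 Null proportion for the escape test (default 0.1).
#' @param alpha Adjusted-p significance cutoff (default 0.01).
#' @param bh_family Multiple-testing family, see Details.
#' @return data.frame with one row per variant: `variant_id`, `category`
#'   (factor with levels reactivated, escape, late_silenced, inactive,
#'   untestable) and per-cell-type columns `ratio_*`, `xi_*`,
#'   `padj_escape_*`, `padj_null_*` (NA where the variant was not a
#'   candidate of that family).
#' @export
classify_variants <- function(summaries,
                              cell_types = c("iPSC", "NPC", "neuron"),
                              mono_cutoff = 0.025, null_p0 = 0.025,
                              escape_p0 = 0.1, alpha = 0.01,
                              bh_family = c("per_celltype", "global")) {
  bh_family <- match.arg(bh_family)
  .check_cols(summaries,
              c("variant_id", "cell_type", "no_total", "allelic_ratio",
                "xi_prob_hat", "xi_count", "testable"), "summaries")
  stopifnot(length(cell_types) >= 2)
  if (anyDuplicated(summaries[c("variant_id", "cell_type")])) {
    stop("conflicting duplicate summaries for the same (variant, cell type)")
  }
  sub <- summaries[summaries$cell_type %in% cell_types, , drop = FALSE]
  ids <- sort(unique(sub$variant_id))
  ref_ct <- cell_types[1]
  diff_ct <- cell_types[-1]

  # wide matrices indexed [variant, cell type]
  grab <- function(col) {
    m <- matrix(NA_real_, length(ids), length(cell_types),
                dimnames = list(ids, cell_types))
    m[cbind(match(sub$variant_id, ids), match(sub$cell_type, cell_types))] <-
      sub[[col]]
    m
  }
  ratio <- grab("allelic_ratio")
  xi <- grab("xi_prob_hat")
  xc <- grab("xi_count")
  nt <- grab("no_total")
  testable_m <- grab("testable") > 0
  testable_m[is.na(testable_m)] <- FALSE
  testable <- rowSums(testable_m) == length(cell_types)

  adjust_family <- function(p, candidate) {
    # BH within the candidate set; per cell type or pooled across cell types
    padj <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
    idx <- which(candidate)
    if (length(idx) == 0) return(padj)
    if (bh_family == "per_celltype") {
      for (j in seq_len(ncol(p))) {
        padj[idx, j] <- stats::p.adjust(p[idx, j], method = "BH")
      }
    } else {
      padj[idx, ] <- stats::p.adjust(p[idx, ], method = "BH")
    }
    padj
  }

  p_escape <- matrix(NA_real_, length(ids), length(cell_types),
                     dimnames = list(ids, cell_types))
  p_null <- p_escape
  for (ct in cell_types) {
    p_escape[, ct] <- test_xi_expression(xc[, ct], nt[, ct], escape_p0)
    p_null[, ct] <- test_xi_expression(xc[, ct], nt[, ct], null_p0)
  }

  padj_escape <- adjust_family(p_escape, testable)
  esc <- testable &
    rowSums(padj_escape[, cell_types, drop = FALSE] < alpha) == length(cell_types)
  esc[is.na(esc)] <- FALSE

  mono_ref <- ratio[, ref_ct] < mono_cutoff | ratio[, ref_ct] > 1 - mono_cutoff
  cand_re <- testable & !is.na(mono_ref) & mono_ref
  padj_re <- adjust_family(p_null[, diff_ct, drop = FALSE], cand_re)
  re <- cand_re & rowSums(padj_re < alpha, na.rm = TRUE) >= 1

  silent_diff <- rowSums(xi[, diff_ct, drop = FALSE] < mono_cutoff) ==
    length(diff_ct)
  cand_ls <- testable & !is.na(silent_diff) & silent_diff
  padj_ls <- adjust_family(p_null[, ref_ct, drop = FALSE], cand_ls)
  ls <- cand_ls & !is.na(padj_ls[, 1]) & padj_ls[, 1] < alpha

  category <- rep("inactive", length(ids))
  category[ls] <- "late_silenced"
  category[re] <- "reactivated"
  category[esc] <- "escape"
  category[!testable] <- "untestable"

  padj_null <- matrix(NA_real_, length(ids), length(cell_types),
                      dimnames = list(ids, cell_types))
  padj_null[, diff_ct] <- padj_re
  padj_null[, ref_ct] <- padj_ls[, 1]

  out <- data.frame(variant_id = ids,
                    category = factor(category,
                                      levels = c("reactivated", "escape",
                                                 "late_silenced", "inactive",
                                                 "untestable")),
                    stringsAsFactors = FALSE)
  for (ct in cell_types) {
    out[[paste0("ratio_", ct)]] <- ratio[, ct]
    out[[paste0("xi_", ct)]] <- xi[, ct]
    out[[paste0("padj_escape_", ct)]] <- padj_escape[, ct]
    out[[paste0("padj_null_", ct)]] <- padj_null[, ct]
  }
  rownames(out) <- NULL
  out
}

#' Flag biallelic calls whose minor-allele support is replicate-inconsistent
#'
#' The typical false-positive mode of pooled allelic analysis is a variant
#' whose minor-allele reads all come from a single replicate (all but one
#' replicate expressing the reference allele and only one the alternative,
#' or vice versa). For every variant called reactivated, escape, or
#' late-silenced this flags the call when, in every cell type driving the
#' biallelic evidence, either (a) at least `single_rep_fraction` of the
#' pooled minor-allele reads come from one replicate, or (b) all replicates
#' but one are strictly monoallelic.
#'
#' Driving cell types are: the significantly biallelic differentiated cell
#' types for reactivated variants, all cell types for escape variants, and
#' the reference cell type for late-silenced variants.
#'
#' @param counts Per-sample counts as in [filter_variants()].
#' @param calls Output of [classify_variants()].
#' @param cell_types Ordered labels as used in classification.
#' @param alpha Significance cutoff used to identify driving cell types.
#' @param single_rep_fraction Fraction of pooled minor-allele reads carried
#'   by one replicate that triggers the flag (default 0.9).
#' @param demote If `TRUE`, flagged calls are recategorised as inactive.
#' @return `calls` with an added logical `curation_flag` column.
#' @export
flag_replicate_inconsistency <- function(counts, calls,
                                         cell_types = c("iPSC", "NPC", "neuron"),
                                         alpha = 0.01,
                                         single_rep_fraction = 0.9,
                                         demote = FALSE) {
  .check_cols(counts, c("variant_id", "sample_id", "cell_type", "ref_reads",
                        "total_reads"), "counts")
  biallelic <- c("reactivated", "escape", "late_silenced")
  flag <- rep(FALSE, nrow(calls))
  ref_ct <- cell_types[1]
  diff_ct <- cell_types[-1]

  inconsistent <- function(v, ct) {
    cc <- counts[counts$variant_id == v & counts$cell_type == ct, , drop = FALSE]
    if (nrow(cc) < 2) return(FALSE)
    pooled_ref <- sum(cc$ref_reads)
    pooled_alt <- sum(cc$total_reads) - sum(cc$ref_reads)
    minor <- if (pooled_ref <= pooled_alt) cc$ref_reads else
      cc$total_reads - cc$ref_reads
    one_rep <- sum(minor) > 0 && max(minor) / sum(minor) >= single_rep_fraction
    mono <- cc$ref_reads == 0 | cc$ref_reads == cc$total_reads
    all_but_one <- sum(mono) == nrow(cc) - 1
    one_rep || all_but_one
  }

  for (i in which(as.character(calls$category) %in% biallelic)) {
    v <- calls$variant_id[i]
    drivers <- switch(as.character(calls$category[i]),
      escape = cell_types,
      late_silenced = ref_ct,
      reactivated = {
        padj <- vapply(diff_ct, function(ct)
          calls[[paste0("padj_null_", ct)]][i], numeric(1))
        diff_ct[!is.na(padj) & padj < alpha]
      })
    if (length(drivers) == 0) next
    flag[i] <- all(vapply(drivers, function(ct) inconsistent(v, ct),
                          logical(1)))
  }
  calls$curation_flag <- flag
  if (demote) {
    calls$category[flag] <- "inactive"
  }
  calls
}

# shared column check used across modules
.check_cols <- function(df, cols, name) {
  if (!is.data.frame(df)) stop("'", name, "' must be a data.frame")
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("'", name, "' is missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
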