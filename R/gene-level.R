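#' Assign a single biallelic-expression category to a gene
#'
#' Collapses the variant-level calls of one gene to one category using the
#' rule hierarchy: (1) majority vote among the gene's biallelically
#' expressed variants (reactivated, escape, late-silenced); (2) on a tie,
#' SNPs are considered more reliable than indels, so the vote is repeated
#' over SNPs only; (3) a remaining tie goes to the category whose best
#' variant has the highest total coverage. Genes whose variants are all
#' inactive are inactive; genes with no testable variant are untestable.
#'
#' @param variant_calls data.frame for one gene with columns `variant_id`,
#'   `category`, `kind` (`"snp"` or `"indel"`) and `coverage` (total reads
#'   of the variant summed over cell types).
#' @return list with `category` and `chosen_variant_ids` (the variants of
#'   the winning category; for inactive/untestable genes, all of them).
#' @export
assign_gene_category <- function(variant_calls) {
  .check_cols(variant_calls, c("variant_id", "category", "kind", "coverage"),
              "variant_calls")
  cat_chr <- as.character(variant_calls$category)
  biallelic <- c("reactivated", "escape", "late_silenced")
  ba <- variant_calls[cat_chr %in% biallelic, , drop = FALSE]
  if (nrow(ba) == 0) {
    category <- if (any(cat_chr == "inactive")) "inactive" else "untestable"
    return(list(category = category,
                chosen_variant_ids = variant_calls$variant_id))
  }
  vote <- function(df) {
    tab <- table(factor(as.character(df$category), levels = biallelic))
    names(tab)[tab == max(tab) & tab > 0]
  }
  winners <- vote(ba)
  if (length(winners) > 1) {
    snps <- ba[ba$kind == "snp", , drop = FALSE]
    w2 <- vote(snps)
    w2 <- intersect(w2, winners)
    if (length(w2) >= 1) winners <- w2
  }
  if (length(winners) > 1) {
    # highest-coverage variant decides among the tied categories
    best <- vapply(winners, function(k)
      max(ba$coverage[as.character(ba$category) == k]), numeric(1))
    winners <- winners[which.max(best)]
  }
  chosen <- ba$variant_id[as.character(ba$category) == winners[1]]
  list(category = winners[1], chosen_variant_ids = chosen)
}

#' Inverse-variance meta-analysis of allelic proportions on the logit scale
#'
#' Pools per-variant minor-allele proportions into a single gene-level
#' estimate with a fixed-effect (or random-effects) inverse-variance model
#' on logit-transformed proportions, as in standard proportion
#' meta-analysis. Boundary proportions (x = 0 or x = n), whose logit is
#' undefined, are continuity-corrected (Haldane-Anscombe: x' = x + 0.5,
#' n' = n + 1); the logit of x/n has variance 1/x + 1/(n - x). The pooled
#' logit and its normal-approximation confidence interval are
#' back-transformed with the inverse logit.
#'
#' @param xi_count Integer vector of minor-allele counts, one per variant.
#' @param no_total Matching totals, all positive.
#' @param level Confidence level (default 0.99).
#' @param method `"fixed"` (default) or `"random"` (DerSimonian-Laird
#'   between-variant variance added to the weights).
#' @return list with `estimate`, `ci_low`, `ci_high` (proportions), the
#'   pooled `logit` and `se`, and `n_variants`.
#' @examples
#' meta_estimate(30, 100)             # single-proportion logit interval
#' meta_estimate(c(10, 30), c(100, 100))
#' @export
meta_estimate <- function(xi_count, no_total, level = 0.99,
                          method = c("fixed", "random")) {
  method <- match.arg(method)
  stopifnot(length(xi_count) == length(no_total), length(xi_count) >= 1,
            level > 0, level < 1)
  if (any(no_total <= 0)) stop("every no_total must be positive")
  if (any(xi_count < 0 | xi_count > no_total)) {
    stop("xi_count must satisfy 0 <= xi_count <= no_total")
  }
  boundary <- xi_count == 0 | xi_count == no_total
  x <- ifelse(boundary, xi_count + 0.5, xi_count)
  n <- ifelse(boundary, no_total + 1, no_total)
  bad <- n - x <= 0
  if (any(bad)) {
    warning(sum(bad), " variant(s) with no information after continuity ",
            "correction excluded")
    x <- x[!bad]; n <- n[!bad]
    if (length(x) == 0) stop("no usable variants left")
  }
  yi <- log(x / (n - x))
  vi <- 1 / x + 1 / (n - x)
  wi <- 1 / vi
  if (method == "random" && length(yi) > 1) {
    # DerSimonian-Laird tau^2
    mu_fe <- sum(wi * yi) / sum(wi)
    q <- sum(wi * (yi - mu_fe)^2)
    c_const <- sum(wi) - sum(wi^2) / sum(wi)
    tau2 <- max(0, (q - (length(yi) - 1)) / c_const)
    wi <- 1 / (vi + tau2)
  }
  mu <- sum(wi * yi) / sum(wi)
  se <- sqrt(1 / sum(wi))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = stats::plogis(mu),
       ci_low = stats::plogis(mu - z * se),
       ci_high = stats::plogis(mu + z * se),
       logit = mu, se = se, n_variants = length(yi))
}

#' Collapse variant calls to gene-level categories and pooled estimates
#'
#' Runs [assign_gene_category()] per gene, then pools the chosen variants'
#' inactive-X expression proportions with [meta_estimate()]. Each variant
#' contributes the (minor-allele count, total) pair of its most biallelic
#' driving cell type: the differentiated cell types for reactivated genes,
#' all cell types for escape genes, the reference cell type for
#' late-silenced genes, and all cell types for inactive genes.
#'
#' @param calls Variant calls from [classify_variants()] (optionally after
#'   [flag_replicate_inconsistency()]); flagged variants are dropped when a
#'   `curation_flag` column is present.
#' @param sites Variant site table carrying `variant_id`, `gene`,
#'   `ref_allele`, `alt_allele` (used to derive SNP/indel kind).
#' @param summaries Group summaries from [pool_by_cell_type()].
#' @param cell_types Ordered cell-type labels used in classification.
#' @param level Confidence level for the pooled interval (default 0.99).
#' @param method Pooling model passed to [meta_estimate()].
#' @return data.frame with one row per gene: `gene`, `category`,
#'   `n_variants` (contributing to the pooled estimate),
#'   `pooled_xi_estimate`, `ci_low`, `ci_high`, and `chosen_variant_ids`
#'   (comma-separated).
#' @export
gene_calls <- function(calls, sites, summaries,
                       cell_types = c("iPSC", "NPC", "neuron"),
                       level = 0.99, method = "fixed") {
  .check_cols(sites, c("variant_id", "gene", "ref_allele", "alt_allele"),
              "sites")
  if ("curation_flag" %in% names(calls)) {
    calls <- calls[!calls$curation_flag, , drop = FALSE]
  }
  m <- match(calls$variant_id, sites$variant_id)
  if (anyNA(m)) stop("calls contain variant_id absent from 'sites'")
  calls$gene <- sites$gene[m]
  calls$kind <- ifelse(nchar(sites$ref_allele[m]) == nchar(sites$alt_allele[m]),
                       "snp", "indel")
  cov <- tapply(summaries$no_total, summaries$variant_id, sum)
  calls$coverage <- as.numeric(cov[calls$variant_id])
  calls$coverage[is.na(calls$coverage)] <- 0

  ref_ct <- cell_types[1]
  diff_ct <- cell_types[-1]
  driving_cts <- function(category) {
    switch(category,
           reactivated = diff_ct,
           escape = cell_types,
           late_silenced = ref_ct,
           cell_types)
  }

  res <- lapply(split(calls, calls$gene), function(gc) {
    a <- assign_gene_category(gc)
    chosen <- a$chosen_variant_ids
    if (a$category == "untestable") {
      return(data.frame(gene = gc$gene[1], category = a$category,
                        n_variants = 0L, pooled_xi_estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        chosen_variant_ids = paste(chosen, collapse = ",")))
    }
    cts <- driving_cts(a$category)
    ss <- summaries[summaries$variant_id %in% chosen &
                      summaries$cell_type %in% cts &
                      summaries$testable, , drop = FALSE]
    if (nrow(ss) == 0) {
      est <- list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  n_variants = 0L)
    } else {
      # per variant, the driving cell type with the strongest biallelic signal
      pick <- do.call(rbind, lapply(split(ss, ss$variant_id), function(vs) {
        vs[which.max(vs$xi_prob_hat), , drop = FALSE]
      }))
      est <- meta_estimate(pick$xi_count, pick$no_total, level = level,
                           method = method)
    }
    data.frame(gene = gc$gene[1], category = a$category,
               n_variants = est$n_variants,
               pooled_xi_estimate = est$estimate,
               ci_low = est$ci_low, ci_high = est$ci_high,
               chosen_variant_ids = paste(chosen, collapse = ","))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$category <- factor(out$category,
                         levels = c("reactivated", "escape", "late_silenced",
                                    "inactive", "untestable"))
  out
}
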