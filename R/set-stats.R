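#' Resampling test of gene-set overlap enrichment
#'
#' Compares the observed overlap between a query gene set and a reference
#' set against a background built by repeatedly drawing `|query|` genes at
#' random (without replacement) from the universe and counting their
#' overlap with the reference. The enrichment ratio is
#' observed / mean(background) and the significance is the upper tail of a
#' normal distribution fitted to the background (the empirical quantile
#' p-value is reported alongside).
#'
#' @param query_set Character vector of query genes (subset of `universe`).
#' @param reference_set Character vector of reference genes.
#' @param universe Character vector of all eligible genes.
#' @param n_iter Number of resampling iterations (default 1000).
#' @param seed Integer seed for the resampling stream.
#' @param tail `"upper"` (enrichment, default) or `"lower"` (depletion).
#' @return list of class `xireact_resampling` with `observed`,
#'   `background_mean`, `background_sd`, `ratio`, `p_value` (normal CDF),
#'   `p_empirical`, `n_iter`, `seed`.
#' @export
overlap_enrichment <- function(query_set, reference_set, universe,
                               n_iter = 1000, seed = 1,
                               tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  query_set <- unique(query_set)
  reference_set <- unique(reference_set)
  universe <- unique(universe)
  if (!all(query_set %in% universe)) {
    stop("query_set must be a subset of the universe")
  }
  if (length(intersect(reference_set, universe)) == 0) {
    stop("reference_set does not intersect the universe")
  }
  observed <- length(intersect(query_set, reference_set))
  ref_in_u <- universe %in% reference_set
  k <- length(query_set)
  set.seed(seed)
  bg <- vapply(seq_len(n_iter), function(i) {
    sum(ref_in_u[sample.int(length(universe), k)])
  }, numeric(1))
  .resampling_result(observed, bg, tail, n_iter, seed,
                     ratio = observed / mean(bg))
}

#' Resampling test of transcription-start-site clustering
#'
#' Tests whether the genes of a query set lie closer together on the
#' chromosome than expected by chance. The statistic is the mean pairwise
#' distance between the query genes' transcription start sites; the
#' background is the same statistic for random same-size draws from the
#' expressed universe, and the p-value is the lower tail of a normal fit
#' (probability of a smaller mean distance by chance).
#'
#' @param query_set Character vector of at least two annotated genes.
#' @param annotation data.frame with columns `gene` and `tss_pos` covering
#'   the eligible universe.
#' @inheritParams overlap_enrichment
#' @return list of class `xireact_resampling` (see [overlap_enrichment()]);
#'   `ratio` is `NA` for this test.
#' @export
tss_distance_test <- function(query_set, annotation, n_iter = 1000, seed = 1) {
  .check_cols(annotation, c("gene", "tss_pos"), "annotation")
  query_set <- unique(query_set)
  if (length(query_set) < 2) stop("query_set needs at least 2 genes")
  miss <- setdiff(query_set, annotation$gene)
  if (length(miss)) {
    stop("query gene(s) without TSS annotation: ", paste(miss, collapse = ", "))
  }
  pos <- annotation$tss_pos
  observed <- mean_pairwise_distance(
    pos[match(query_set, annotation$gene)])
  k <- length(query_set)
  set.seed(seed)
  bg <- vapply(seq_len(n_iter), function(i) {
    mean_pairwise_distance(pos[sample.int(length(pos), k)])
  }, numeric(1))
  .resampling_result(observed, bg, tail = "lower", n_iter, seed, ratio = NA)
}

#' Mean pairwise distance between positions
#'
#' Mean of `|x_i - x_j|` over all unordered pairs, computed in
#' O(k log k) from the sorted positions.
#'
#' @param pos Numeric vector of coordinates (length >= 2).
#' @return The mean pairwise absolute distance.
#' @export
mean_pairwise_distance <- function(pos) {
  k <- length(pos)
  stopifnot(k >= 2)
  s <- sort(pos)
  # sum over pairs of |xi - xj| = sum_i (2i - k - 1) * x_(i)
  tot <- sum((2 * seq_len(k) - k - 1) * s)
  tot / choose(k, 2)
}

#' Compare chromatin-state profiles of a gene set against inactive genes
#'
#' For each chromatin state, compares the per-gene percentage of the gene
#' body in that state between a query category (e.g. reactivated genes)
#' and inactive genes, using a one-sided Wilcoxon rank-sum test, and
#' reports the log ratio of the two group means. P-values are BH-adjusted
#' across states; a state is called enriched at adjusted p < 0.05.
#'
#' @param profiles data.frame with a `gene` column and one numeric column
#'   per chromatin state; per-gene percentages must sum to about 100
#'   (tolerance `sum_tol`).
#' @param query_set,inactive_set Character vectors of gene names present in
#'   `profiles`.
#' @param tail `"upper"` tests enrichment in the query set (default),
#'   `"lower"` depletion.
#' @param sum_tol Allowed deviation of per-gene state sums from 100.
#' @return data.frame with one row per state: `state`, `mean_query`,
#'   `mean_inactive`, `log_mean_diff` (`Inf` sentinel when the inactive
#'   mean is 0), `p_value`, `p_adj`, `significant`.
#' @export
chromatin_state_comparison <- function(profiles, query_set, inactive_set,
                                       tail = c("upper", "lower"),
                                       sum_tol = 1) {
  tail <- match.arg(tail)
  .check_cols(profiles, "gene", "profiles")
  states <- setdiff(names(profiles), "gene")
  if (length(states) == 0) stop("no state columns in 'profiles'")
  sums <- rowSums(profiles[states])
  if (any(abs(sums - 100) > sum_tol)) {
    stop("state percentages must sum to 100 (+/- ", sum_tol,
         ") for every gene")
  }
  q <- profiles[profiles$gene %in% query_set, states, drop = FALSE]
  i <- profiles[profiles$gene %in% inactive_set, states, drop = FALSE]
  if (nrow(q) == 0 || nrow(i) == 0) {
    stop("query or inactive set has no genes in 'profiles'")
  }
  alt <- if (tail == "upper") "greater" else "less"
  res <- lapply(states, function(s) {
    mq <- mean(q[[s]]); mi <- mean(i[[s]])
    if (mi == 0) {
      warning("state '", s, "' has zero mean in the inactive set")
      ld <- if (mq > 0) Inf else 0
    } else {
      ld <- log(mq / mi)
    }
    p <- suppressWarnings(
      stats::wilcox.test(q[[s]], i[[s]], alternative = alt)$p.value)
    data.frame(state = s, mean_query = mq, mean_inactive = mi,
               log_mean_diff = ld, p_value = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adj < 0.05
  rownames(out) <- NULL
  out
}

#' Fisher's exact test of sex-biased expression breadth
#'
#' Bins genes by the number of tissues in which they show female-biased
#' expression and tests for a difference in the binned distributions
#' between a query category and inactive genes with Fisher's exact test.
#'
#' @param tissue_counts data.frame with columns `gene` and
#'   `n_tissues_female_biased`.
#' @param query_set,inactive_set Character vectors of genes.
#' @param breaks Integer breakpoints partitioning the counts into bins via
#'   `cut(..., right = TRUE)`; defaults give bins 0, 1-5, 6-15, >15.
#' @param collapse_2x2 If `TRUE`, collapse the table to 2x2 as
#'   (zero tissues) vs (any tissue).
#' @return list with the contingency `table`, `p_value`, and `method`;
#'   `NULL` p with a message if the table is degenerate (a single
#'   occupied bin).
#' @export
sex_bias_test <- function(tissue_counts, query_set, inactive_set,
                          breaks = c(-Inf, 0, 5, 15, Inf),
                          collapse_2x2 = FALSE) {
  .check_cols(tissue_counts, c("gene", "n_tissues_female_biased"),
              "tissue_counts")
  get_counts <- function(set) {
    tissue_counts$n_tissues_female_biased[tissue_counts$gene %in% set]
  }
  qc <- get_counts(query_set)
  ic <- get_counts(inactive_set)
  if (length(qc) == 0 || length(ic) == 0) {
    stop("query or inactive set has no genes with tissue-bias data")
  }
  labels <- paste0("bin", seq_len(length(breaks) - 1))
  tab <- rbind(query = table(cut(qc, breaks, labels = labels)),
               inactive = table(cut(ic, breaks, labels = labels)))
  occupied <- colSums(tab) > 0
  if (sum(!occupied) > 0) {
    warning("dropping ", sum(!occupied), " empty bin(s)")
    tab <- tab[, occupied, drop = FALSE]
  }
  if (ncol(tab) < 2) {
    message("all genes fall in a single bin; test skipped")
    return(list(table = tab, p_value = NULL, method = "skipped"))
  }
  if (collapse_2x2) {
    tab <- cbind(tab[, 1, drop = FALSE], rowSums(tab[, -1, drop = FALSE]))
    colnames(tab) <- c("none", "any")
  }
  ft <- stats::fisher.test(tab)
  list(table = tab, p_value = ft$p.value, method = "fisher")
}

#' Expressed-gene universe from a normalized count matrix
#'
#' Helper defining the analysis universe as the genes exceeding a
#' normalized read threshold in every sample, the usual expression filter
#' applied before set-level resampling.
#'
#' @param norm_counts Numeric matrix, genes x samples, of normalized counts.
#' @param min_reads Threshold each sample must exceed (default 10, i.e.
#'   `> 10` reads in each sample).
#' @return Character vector of gene names passing the filter.
#' @export
expressed_universe <- function(norm_counts, min_reads = 10) {
  stopifnot(is.matrix(norm_counts) || inherits(norm_counts, "Matrix"))
  if (is.null(rownames(norm_counts))) stop("norm_counts needs rownames")
  rownames(norm_counts)[apply(norm_counts > min_reads, 1, all)]
}

.resampling_result <- function(observed, bg, tail, n_iter, seed, ratio) {
  m <- mean(bg)
  s <- stats::sd(bg)
  if (s == 0) {
    warning("degenerate background (sd = 0); p set by sign of the deviation")
    p <- if (tail == "upper") {
      if (observed > m) 0 else 1
    } else {
      if (observed < m) 0 else 1
    }
    p_emp <- p
  } else if (tail == "upper") {
    p <- stats::pnorm(observed, m, s, lower.tail = FALSE)
    p_emp <- (sum(bg >= observed) + 1) / (n_iter + 1)
  } else {
    p <- stats::pnorm(observed, m, s, lower.tail = TRUE)
    p_emp <- (sum(bg <= observed) + 1) / (n_iter + 1)
  }
  structure(list(observed = observed, background_mean = m, background_sd = s,
                 ratio = ratio, p_value = p, p_empirical = p_emp,
                 n_iter = n_iter, seed = seed, tail = tail),
            class = "xireact_resampling")
}

#' @exportS3Method base::print
print.xireact_resampling <- function(x, ...) {
  cat("Resampling test (", x$n_iter, " iterations, seed ", x$seed, ")\n",
      sep = "")
  cat("  observed:   ", format(x$observed), "\n")
  cat("  background: ", format(x$background_mean), " +/- ",
      format(x$background_sd), "\n", sep = "")
  if (!is.na(x$ratio)) cat("  ratio:      ", format(x$ratio), "\n")
  cat("  p (normal CDF, ", x$tail, " tail): ", format(x$p_value),
      "   p (empirical): ", format(x$p_empirical), "\n", sep = "")
  invisible(x)
}
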