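#' Per-cluster control expression means
#'
#' Arithmetic mean expression of every gene over the control cells of each
#' cluster; the baseline against which per-cell fold changes are taken.
#'
#' @param expr Numeric matrix, genes x cells (dense or sparse).
#' @param control_cells Character vector of control cell ids (columns of
#'   `expr`).
#' @param clusters Named character vector or factor of cluster labels for
#'   every cell in `expr`.
#' @return Numeric matrix, genes x clusters, of control means. Clusters
#'   without control cells are excluded with a warning.
#' @export
control_means <- function(expr, control_cells, clusters) {
  if (is.null(colnames(expr))) stop("expr needs cell column names")
  if (is.null(names(clusters))) stop("clusters must be named by cell id")
  miss <- setdiff(control_cells, colnames(expr))
  if (length(miss)) stop("control cell(s) not in expr: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  cl <- as.character(clusters[colnames(expr)])
  all_cl <- unique(cl)
  ctrl <- colnames(expr) %in% control_cells
  have <- all_cl[vapply(all_cl, function(k) any(ctrl & cl == k), logical(1))]
  dropped <- setdiff(all_cl, have)
  if (length(dropped)) {
    warning("cluster(s) without control cells excluded: ",
            paste(dropped, collapse = ", "))
  }
  out <- vapply(have, function(k) {
    Matrix::rowMeans(expr[, ctrl & cl == k, drop = FALSE])
  }, numeric(nrow(expr)))
  dimnames(out) <- list(rownames(expr), have)
  out
}

#' Transcriptional deviation of one cell from its cluster's control profile
#'
#' For each differentially expressed (DE) gene of the cell's cluster the
#' fold change over the control mean is computed —
#' `(expr + eps) / (ctrl + eps)` for upregulated genes and its reciprocal
#' for downregulated genes — and the deviation is the mean fold change over
#' those DE genes. A cell identical to the control profile on every DE gene
#' deviates by exactly 1.
#'
#' @param cell_expr Named numeric vector of the cell's expression.
#' @param ctrl_mean Named numeric vector of the cluster's control means.
#' @param de_table data.frame for the cluster with columns `gene` and
#'   `direction` (`"up"` or `"down"`).
#' @param epsilon Pseudocount guarding zero denominators (default 1e-9).
#' @return The deviation value (a single non-negative number).
#' @export
cell_deviation <- function(cell_expr, ctrl_mean, de_table, epsilon = 1e-9) {
  .check_cols(de_table, c("gene", "direction"), "de_table")
  if (nrow(de_table) == 0) stop("de_table is empty")
  if (!all(de_table$direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'")
  }
  g <- de_table$gene
  miss <- setdiff(g, names(cell_expr))
  if (length(miss)) stop("DE gene(s) missing from expression: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  fc <- (cell_expr[g] + epsilon) / (ctrl_mean[g] + epsilon)
  down <- de_table$direction == "down"
  fc[down] <- 1 / fc[down]
  mean(fc)
}

#' Per-cell transcriptional deviation for a whole matrix
#'
#' Convenience wrapper applying [cell_deviation()] to every cell, using its
#' cluster's DE genes and control means.
#'
#' @inheritParams control_means
#' @param ctrl_means Output of [control_means()].
#' @param de_tables Named list of per-cluster DE tables (see
#'   [cell_deviation()]), or a single data.frame with a `cluster` column.
#' @param epsilon Pseudocount, see [cell_deviation()].
#' @return data.frame (cell, cluster, deviation); cells of clusters lacking
#'   control means or DE genes get `NA` with a warning.
#' @export
deviation_scores <- function(expr, ctrl_means, de_tables, clusters,
                             epsilon = 1e-9) {
  if (is.data.frame(de_tables)) {
    .check_cols(de_tables, c("gene", "direction", "cluster"), "de_tables")
    de_tables <- split(de_tables, de_tables$cluster)
  }
  cl <- as.character(clusters[colnames(expr)])
  dev <- rep(NA_real_, ncol(expr))
  usable <- intersect(colnames(ctrl_means), names(de_tables))
  skipped <- setdiff(unique(cl), usable)
  if (length(skipped)) {
    warning("no control means or DE genes for cluster(s): ",
            paste(skipped, collapse = ", "))
  }
  for (k in usable) {
    idx <- which(cl == k)
    if (length(idx) == 0) next
    de <- de_tables[[k]]
    g <- de$gene
    sub <- as.matrix(expr[g, idx, drop = FALSE])
    ctrl <- ctrl_means[g, k]
    fc <- (sub + epsilon) / (ctrl + epsilon)
    down <- de$direction == "down"
    fc[down, ] <- 1 / fc[down, , drop = FALSE]
    dev[idx] <- colMeans(fc)
  }
  data.frame(cell = colnames(expr), cluster = cl, deviation = dev,
             stringsAsFactors = FALSE)
}

#' Aggregate per-cell deviations by cluster or pseudotime bin
#'
#' @param deviations data.frame from [deviation_scores()] (or any frame
#'   with `cell` and `deviation`).
#' @param group Character/factor of group labels per cell (cluster mode),
#'   or numeric pseudotime when `n_bins` is given.
#' @param n_bins If non-NULL, `group` is treated as pseudotime and passed
#'   through [bin_by_pseudotime()].
#' @return data.frame of group means and cell counts.
#' @export
aggregate_deviation <- function(deviations, group, n_bins = NULL) {
  .check_cols(deviations, c("cell", "deviation"), "deviations")
  stopifnot(length(group) == nrow(deviations))
  if (!is.null(n_bins)) {
    return(bin_by_pseudotime(deviations$deviation, group, n_bins))
  }
  f <- factor(group)
  empty <- levels(f)[table(f) == 0]
  if (length(empty)) warning("empty group(s): ", paste(empty, collapse = ", "))
  data.frame(group = levels(f),
             mean = as.numeric(tapply(deviations$deviation, f, mean,
                                      na.rm = TRUE)),
             n = as.integer(table(f)),
             stringsAsFactors = FALSE)
}

#' Rank-sum differential expression between two cell groups
#'
#' Minimal Wilcoxon rank-sum DE helper used to make the deviation statistic
#' self-testable on synthetic data: per-gene two-sided rank-sum test
#' between the two groups, BH adjustment, and log2 fold change of group
#' means with a pseudocount. Genes passing both the adjusted-p and the
#' absolute log2-fold-change thresholds are returned with their direction.
#'
#' @param expr Numeric matrix, genes x cells.
#' @param labels Two-level factor/character of group membership per cell;
#'   the second level is treated as the case group.
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @param min_abs_log2fc Absolute log2 fold-change cutoff (default 2; use
#'   0.25 for the permissive screen).
#' @param pseudocount Added to group means before the ratio (default 1e-9).
#' @return data.frame (gene, direction, log2_fold, p_value, adjusted_p) of
#'   significant genes.
#' @export
rank_sum_de <- function(expr, labels, alpha = 0.01, min_abs_log2fc = 2,
                        pseudocount = 1e-9) {
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  if (any(table(labels) < 2)) stop("each group needs at least 2 cells")
  a <- labels == levels(labels)[1]
  b <- labels == levels(labels)[2]
  p <- apply(expr, 1, function(x) {
    if (length(unique(x)) == 1) return(1)
    suppressWarnings(stats::wilcox.test(x[b], x[a])$p.value)
  })
  l2fc <- log2((rowMeans(expr[, b, drop = FALSE]) + pseudocount) /
                 (rowMeans(expr[, a, drop = FALSE]) + pseudocount))
  padj <- stats::p.adjust(p, method = "BH")
  keep <- padj < alpha & abs(l2fc) > min_abs_log2fc
  data.frame(gene = rownames(expr)[keep],
             direction = ifelse(l2fc[keep] > 0, "up", "down"),
             log2_fold = l2fc[keep],
             p_value = p[keep], adjusted_p = padj[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}
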