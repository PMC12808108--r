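# coerce dense or sparse input to general column-compressed sparse form
# (general, not symmetric/triangular/diagonal, so summary() lists every
# stored entry)
.as_csparse <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE, doDiag = FALSE)
  methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
}

#' Depth-normalized filter for pseudo-bulk variant sites
#'
#' Retains intragenic heterozygous variants detected in pseudo-bulked
#' single-cell data when both alleles reach the base quality cutoff and the
#' pooled read count reaches a sequencing-depth-normalized threshold:
#' `reads >= rate * total_reads / 5e8`, with `rate = 50` for single-cell
#' libraries and `rate = 2` for single-nucleus libraries.
#'
#' @param variants data.frame with columns `variant_id`, `reads` (pooled
#'   reads supporting the site), `qual_ref`, `qual_alt` (per-allele PHRED
#'   qualities) and optionally `gene` (rows with missing gene are dropped
#'   as intergenic).
#' @param total_reads Total reads in the pseudo-bulked library.
#' @param mode `"sc"` (rate 50 per 5e8 reads) or `"sn"` (rate 2 per 5e8).
#' @param min_qual Minimum PHRED quality for each allele (default 20).
#' @param rate Override for the depth-normalized read threshold.
#' @return The retained rows of `variants`.
#' @export
filter_pseudobulk_variants <- function(variants, total_reads,
                                       mode = c("sc", "sn"), min_qual = 20,
                                       rate = NULL) {
  mode <- match.arg(mode)
  stopifnot(total_reads > 0)
  .check_cols(variants, c("variant_id", "reads", "qual_ref", "qual_alt"),
              "variants")
  if (is.null(rate)) rate <- if (mode == "sc") 50 else 2
  thr <- rate * total_reads / 5e8
  keep <- variants$qual_ref >= min_qual & variants$qual_alt >= min_qual &
    variants$reads >= thr
  if ("gene" %in% names(variants)) {
    keep <- keep & !is.na(variants$gene) & variants$gene != ""
  }
  variants[keep, , drop = FALSE]
}

#' Per-cell, per-site biallelic-expression scores from allelic UMI counts
#'
#' For every (cell, site) with at least `min_umis_per_site` UMIs, computes
#' the major-allele fraction r = max(ref, alt) / (ref + alt) and the
#' biallelic score s = -ln(r), so a monoallelic site scores 0 and a
#' balanced biallelic site scores ln 2 (0.69). Scores are summed per cell
#' over X-linked sites, excluding pseudoautosomal (PAR) sites by default
#' since PAR genes escape inactivation as a block.
#'
#' When `per_gene = TRUE` (default) UMIs of sites belonging to the same
#' gene are summed within each cell before the fraction is taken, giving
#' one score per (cell, gene); otherwise each site is scored separately.
#'
#' @param ref_umis,alt_umis Sparse or dense matrices (cells x variants) of
#'   reference- and alternative-allele UMI counts, same dimnames.
#' @param variant_info data.frame with columns `variant_id`, `gene`,
#'   `par_flag`, one row per column of the matrices (matched by
#'   `variant_id` against the column names).
#' @param min_umis_per_site Minimum total UMIs at a site for it to be
#'   scored (default 1).
#' @param exclude_par Drop PAR sites from the per-cell sum (default TRUE).
#' @param per_gene Aggregate UMIs per gene before scoring (default TRUE).
#' @return list with `scores` — a data.frame (cell, unit, gene, ref, alt,
#'   major_fraction, score) of scored units — and `cell_sums`, a data.frame
#'   (cell, biallelic_sum, n_scored) covering every cell.
#' @examples
#' r <- matrix(4, 1, 1, dimnames = list("c1", "v1"))
#' a <- matrix(4, 1, 1, dimnames = list("c1", "v1"))
#' vi <- data.frame(variant_id = "v1", gene = "g1", par_flag = FALSE)
#' score_cells(r, a, vi)$scores$score  # ln 2 = 0.69
#' @export
score_cells <- function(ref_umis, alt_umis, variant_info,
                        min_umis_per_site = 1, exclude_par = TRUE,
                        per_gene = TRUE) {
  .check_cols(variant_info, c("variant_id", "gene", "par_flag"),
              "variant_info")
  if (!identical(dim(ref_umis), dim(alt_umis))) {
    stop("ref_umis and alt_umis must share dimensions")
  }
  if (is.null(colnames(ref_umis)) || is.null(rownames(ref_umis))) {
    stop("UMI matrices need cell rownames and variant colnames")
  }
  if (!identical(dimnames(ref_umis), dimnames(alt_umis))) {
    stop("ref_umis and alt_umis must share dimnames")
  }
  m <- match(colnames(ref_umis), variant_info$variant_id)
  if (anyNA(m)) stop("UMI matrix column(s) missing from variant_info")
  vi <- variant_info[m, , drop = FALSE]
  if (any(ref_umis < 0) || any(alt_umis < 0)) stop("negative UMI counts")

  keep_cols <- if (exclude_par) !vi$par_flag else rep(TRUE, nrow(vi))
  ref <- .as_csparse(ref_umis[, keep_cols, drop = FALSE])
  alt <- .as_csparse(alt_umis[, keep_cols, drop = FALSE])
  vi <- vi[keep_cols, , drop = FALSE]

  # long triplet form of the nonzero (cell, unit) totals
  tri_r <- Matrix::summary(ref)
  tri_a <- Matrix::summary(alt)
  unit <- if (per_gene) vi$gene else vi$variant_id
  long <- rbind(
    data.frame(cell = tri_r$i, unit = unit[tri_r$j], ref = tri_r$x,
               alt = rep(0, nrow(tri_r))),
    data.frame(cell = tri_a$i, unit = unit[tri_a$j],
               ref = rep(0, nrow(tri_a)), alt = tri_a$x))
  if (nrow(long) == 0) {
    cells <- rownames(ref_umis)
    return(list(scores = data.frame(cell = character(), unit = character(),
                                    gene = character(), ref = numeric(),
                                    alt = numeric(), major_fraction = numeric(),
                                    score = numeric()),
                cell_sums = data.frame(cell = cells, biallelic_sum = 0,
                                       n_scored = 0L)))
  }
  agg <- stats::aggregate(long[c("ref", "alt")],
                          by = list(cell = long$cell, unit = long$unit),
                          FUN = sum)
  agg$total <- agg$ref + agg$alt
  agg <- agg[agg$total >= min_umis_per_site, , drop = FALSE]
  agg$major_fraction <- pmax(agg$ref, agg$alt) / agg$total
  agg$score <- -log(agg$major_fraction)
  agg$cell <- rownames(ref_umis)[agg$cell]
  gene_of_unit <- if (per_gene) agg$unit else
    vi$gene[match(agg$unit, vi$variant_id)]
  scores <- data.frame(cell = agg$cell, unit = agg$unit, gene = gene_of_unit,
                       ref = agg$ref, alt = agg$alt,
                       major_fraction = agg$major_fraction, score = agg$score,
                       stringsAsFactors = FALSE)

  cells <- rownames(ref_umis)
  sums <- tapply(scores$score, factor(scores$cell, levels = cells), sum)
  nsc <- tapply(scores$score, factor(scores$cell, levels = cells), length)
  cell_sums <- data.frame(cell = cells,
                          biallelic_sum = as.numeric(ifelse(is.na(sums), 0,
                                                            sums)),
                          n_scored = as.integer(ifelse(is.na(nsc), 0, nsc)),
                          stringsAsFactors = FALSE)
  list(scores = scores, cell_sums = cell_sums)
}

#' Per-cell reactivation and escapee scores
#'
#' Sums the per-site biallelic scores of each cell over the genes of a
#' category: the reactivation score sums over reactivated genes and the
#' escapee score over full-escape genes.
#'
#' @param scores The `scores` data.frame from [score_cells()].
#' @param gene_categories data.frame with columns `gene` and `category`
#'   (as produced by [gene_calls()]).
#' @param cells Optional character vector of all cell barcodes so cells
#'   without scored sites appear with zero scores.
#' @return data.frame (cell, reactivation_score, escapee_score).
#' @export
category_scores <- function(scores, gene_categories, cells = NULL) {
  .check_cols(gene_categories, c("gene", "category"), "gene_categories")
  if (is.null(cells)) cells <- unique(scores$cell)
  cat_of <- as.character(gene_categories$category)[
    match(scores$gene, gene_categories$gene)]
  sum_over <- function(category) {
    sel <- !is.na(cat_of) & cat_of == category
    s <- tapply(scores$score[sel], factor(scores$cell[sel], levels = cells),
                sum)
    as.numeric(ifelse(is.na(s), 0, s))
  }
  data.frame(cell = cells,
             reactivation_score = sum_over("reactivated"),
             escapee_score = sum_over("escape"),
             stringsAsFactors = FALSE)
}

#' Bin per-cell values along pseudotime
#'
#' Cuts pseudotime into `n_bins` equal-width bins over its observed range
#' and reports the mean value and cell count per bin. Empty bins are kept
#' as rows with `NA` mean and zero count.
#'
#' @param values Numeric vector, one value per cell.
#' @param pseudotime Matching numeric vector of pseudotime coordinates.
#' @param n_bins Number of equal-width bins (default 50).
#' @return data.frame (bin, mid, mean, n); `bin` runs from 1 (earliest).
#' @export
bin_by_pseudotime <- function(values, pseudotime, n_bins = 50) {
  stopifnot(length(values) == length(pseudotime), n_bins >= 2,
            all(is.finite(pseudotime)))
  rng <- range(pseudotime)
  if (rng[1] == rng[2]) {
    warning("all cells share one pseudotime value; returning a single bin")
    return(data.frame(bin = 1L, mid = rng[1], mean = mean(values),
                      n = length(values)))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- findInterval(pseudotime, edges, rightmost.closed = TRUE)
  f <- factor(idx, levels = seq_len(n_bins))
  data.frame(bin = seq_len(n_bins),
             mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
             mean = as.numeric(tapply(values, f, mean)),
             n = as.integer(table(f)))
}
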