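#' Build and validate a simulation configuration
#'
#' Defines the ground truth for the synthetic allelic data: per-gene
#' category labels, the per-gene, per-cell-type probability of expression
#' from the inactive X (`p_Xi`), the replicate structure and the
#' negative-binomial read-depth model. Category labels and `p_Xi` profiles
#' must be mutually consistent:
#'
#' * reactivated: `p_Xi <= 0.01` in the reference cell type and `>= 0.10`
#'   in at least one differentiated cell type;
#' * escape: `p_Xi >= 0.15` in every cell type;
#' * late_silenced: `p_Xi >= 0.10` in the reference cell type and
#'   `<= 0.01` in every differentiated cell type;
#' * inactive: `p_Xi <= 0.01` everywhere.
#'
#' @param n_genes Number of genes.
#' @param variants_per_gene Integer range `c(min, max)` of variant sites
#'   per gene.
#' @param cell_types Ordered cell-type labels, pluripotent state first.
#' @param replicates_per_cell_type Replicate samples per cell type.
#' @param depth_mean Expected reads per variant per replicate.
#' @param depth_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); produces realistic low-coverage dropout.
#' @param category_probs Named sampling probabilities for the four
#'   categories.
#' @param xi_levels Named list of per-category `p_Xi` vectors (one value
#'   per cell type) overriding the defaults.
#' @param seed Integer master seed; all generator functions derive their
#'   streams from it.
#' @return Object of class `xireact_sim_config`: a list with the resolved
#'   fields plus `genes`, `category_truth` and the `xi_profile` matrix
#'   (genes x cell types).
#' @export
sim_config <- function(n_genes = 200, variants_per_gene = c(1, 3),
                       cell_types = c("iPSC", "NPC", "neuron"),
                       replicates_per_cell_type = 4,
                       depth_mean = 100, depth_dispersion = 0.3,
                       category_probs = c(reactivated = 0.2, escape = 0.2,
                                          late_silenced = 0.1,
                                          inactive = 0.5),
                       xi_levels = NULL, seed = 1) {
  stopifnot(n_genes >= 1, length(variants_per_gene) == 2,
            variants_per_gene[1] >= 1,
            variants_per_gene[2] >= variants_per_gene[1],
            length(cell_types) >= 2, replicates_per_cell_type >= 1,
            depth_mean > 0, depth_dispersion >= 0)
  cats <- c("reactivated", "escape", "late_silenced", "inactive")
  stopifnot(setequal(names(category_probs), cats))

  n_ct <- length(cell_types)
  defaults <- list(
    reactivated = c(0.005, 0.15, rep(0.25, max(0, n_ct - 2))),
    escape = rep(0.3, n_ct),
    late_silenced = c(0.2, rep(0.005, n_ct - 1)),
    inactive = rep(0.005, n_ct))
  if (!is.null(xi_levels)) defaults[names(xi_levels)] <- xi_levels

  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  category_truth <- sample(cats, n_genes, replace = TRUE,
                           prob = category_probs[cats])
  xi_profile <- t(vapply(category_truth, function(k) defaults[[k]][1:n_ct],
                         numeric(n_ct)))
  dimnames(xi_profile) <- list(genes, cell_types)

  cfg <- structure(list(
    n_genes = n_genes, variants_per_gene = variants_per_gene,
    cell_types = cell_types,
    replicates_per_cell_type = replicates_per_cell_type,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    genes = genes, category_truth = stats::setNames(category_truth, genes),
    xi_profile = xi_profile, seed = seed),
    class = "xireact_sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Check a simulation configuration's internal consistency
#'
#' @param cfg A `xireact_sim_config` object (or a compatible list).
#' @return `cfg`, invisibly; stops with the offending gene named otherwise.
#' @export
validate_sim_config <- function(cfg) {
  p <- cfg$xi_profile
  if (any(!is.finite(p)) || any(p < 0) || any(p > 0.5)) {
    bad <- rownames(p)[which(!is.finite(p) | p < 0 | p > 0.5,
                             arr.ind = TRUE)[1]]
    stop("xi_profile out of range [0, 0.5] for gene '", bad, "'")
  }
  ref <- 1
  diff <- seq(2, ncol(p))
  for (g in rownames(p)) {
    ok <- switch(cfg$category_truth[g],
      reactivated = p[g, ref] <= 0.01 && any(p[g, diff] >= 0.10),
      escape = all(p[g, ] >= 0.15),
      late_silenced = p[g, ref] >= 0.10 && all(p[g, diff] <= 0.01),
      inactive = all(p[g, ] <= 0.01))
    if (!ok) stop("xi_profile of gene '", g, "' is inconsistent with its ",
                  "category '", cfg$category_truth[g], "'")
  }
  invisible(cfg)
}

#' Simulate replicate-level allelic read counts with known ground truth
#'
#' Draws, for every variant site and sample, a sequencing depth from the
#' configured negative-binomial model and reference-allele reads from
#' `Binomial(depth, p_ref)`, where `p_ref = 1 - p_Xi` when the reference
#' allele lies on the active X and `p_Xi` otherwise. The haplotype phase is
#' drawn once per gene so all of a gene's variants are internally
#' consistent, and is recorded in the truth table.
#'
#' @param config A [sim_config()] object.
#' @return list with `counts` (variant_id, gene, sample_id, cell_type,
#'   ref_reads, total_reads), `sites` (variant metadata compatible with
#'   [filter_variants()]) and `truth` (gene, category, phase, plus the
#'   true `p_Xi` per cell type).
#' @export
simulate_bulk_allelic_counts <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  genes <- config$genes
  nv <- sample(seq(config$variants_per_gene[1], config$variants_per_gene[2]),
               length(genes), replace = TRUE)
  phase <- sample(c("ref_on_Xa", "alt_on_Xa"), length(genes), replace = TRUE)
  names(phase) <- genes

  sites <- data.frame(
    variant_id = unlist(lapply(seq_along(genes), function(i)
      paste0(genes[i], "_v", seq_len(nv[i])))),
    gene = rep(genes, nv),
    stringsAsFactors = FALSE)
  sites$chrom <- "chrX"
  sites$pos <- seq_len(nrow(sites)) * 1000L
  sites$ref_allele <- "A"
  sites$alt_allele <- "G"
  sites$qual <- 200

  cts <- config$cell_types
  reps <- config$replicates_per_cell_type
  samples <- data.frame(
    sample_id = paste0(rep(cts, each = reps), "_rep", seq_len(reps)),
    cell_type = rep(cts, each = reps), stringsAsFactors = FALSE)

  grid <- expand.grid(site = seq_len(nrow(sites)),
                      samp = seq_len(nrow(samples)))
  g <- sites$gene[grid$site]
  ct <- samples$cell_type[grid$samp]
  p_xi <- config$xi_profile[cbind(g, ct)]
  p_ref <- ifelse(phase[g] == "ref_on_Xa", 1 - p_xi, p_xi)
  size <- if (config$depth_dispersion > 0) 1 / config$depth_dispersion else Inf
  total <- if (is.finite(size)) {
    stats::rnbinom(nrow(grid), mu = config$depth_mean, size = size)
  } else {
    stats::rpois(nrow(grid), config$depth_mean)
  }
  ref <- stats::rbinom(nrow(grid), total, p_ref)

  counts <- data.frame(
    variant_id = sites$variant_id[grid$site],
    gene = g,
    sample_id = samples$sample_id[grid$samp],
    cell_type = ct,
    ref_reads = ref,
    total_reads = total,
    stringsAsFactors = FALSE)

  truth <- data.frame(gene = genes,
                      category = unname(config$category_truth[genes]),
                      phase = unname(phase[genes]),
                      stringsAsFactors = FALSE)
  for (k in cts) truth[[paste0("p_xi_", k)]] <- config$xi_profile[genes, k]

  list(counts = counts, sites = sites, truth = truth)
}

#' Simulate a gene annotation with optional TSS clustering
#'
#' Places transcription start sites uniformly along one chromosome, then
#' relocates a chosen fraction of a designated gene set into tight windows
#' so the pairwise-distance test has a planted positive. Genes whose TSS
#' falls in the configured terminal interval are flagged pseudoautosomal.
#'
#' @param config A [sim_config()] object (supplies the gene names).
#' @param clustered_fraction Fraction of `cluster_genes` placed inside
#'   clusters, in `[0, 1]` (default 0: fully uniform layout).
#' @param cluster_genes Genes eligible for clustering; defaults to the
#'   config's reactivated genes.
#' @param chrom_length Chromosome length in bp (default 1.5e8, about the
#'   human X).
#' @param cluster_window Width of each planted cluster in bp (default 1e4).
#' @param n_clusters Number of planted windows the clustered genes are
#'   spread over (default 1).
#' @param par_length Length of the terminal PAR interval in bp (default
#'   2.7e6, about human PAR1).
#' @return data.frame (gene, chrom, tss_pos, strand, par_flag) with 1-based
#'   positions.
#' @export
simulate_annotation <- function(config, clustered_fraction = 0,
                                cluster_genes = NULL, chrom_length = 1.5e8,
                                cluster_window = 1e4, n_clusters = 1,
                                par_length = 2.7e6) {
  stopifnot(clustered_fraction >= 0, clustered_fraction <= 1,
            chrom_length > cluster_window, n_clusters >= 1)
  set.seed(config$seed + 2L)
  genes <- config$genes
  if (is.null(cluster_genes)) {
    cluster_genes <- genes[config$category_truth == "reactivated"]
  }
  tss <- ceiling(stats::runif(length(genes), 0, chrom_length))
  names(tss) <- genes
  n_clustered <- round(clustered_fraction * length(cluster_genes))
  if (n_clustered > 0) {
    placed <- sample(cluster_genes, n_clustered)
    centers <- stats::runif(n_clusters, cluster_window,
                            chrom_length - cluster_window)
    assign_to <- sample(seq_len(n_clusters), n_clustered, replace = TRUE)
    tss[placed] <- ceiling(centers[assign_to] +
                             stats::runif(n_clustered, 0, cluster_window))
  }
  data.frame(gene = genes, chrom = "chrX", tss_pos = as.integer(tss),
             strand = sample(c("+", "-"), length(genes), replace = TRUE),
             par_flag = tss <= par_length,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate allele-resolved single-cell UMI counts along pseudotime
#'
#' Gives every cell a uniform pseudotime in `[0, 1]` and every gene a
#' piecewise-linear `p_Xi` trajectory interpolating the configured
#' per-cell-type values at equally spaced pseudotime anchors (the ordered
#' cell types map to pseudotime 0, ..., 1). Per cell and site, total UMIs
#' are Poisson with mean `umi_depth` thinned by a per-gene detection rate;
#' alternative-allele UMIs are binomial given the cell's allele fraction
#' and the gene's haplotype phase (drawn once per gene).
#'
#' @param n_cells Number of cells.
#' @param config A [sim_config()] object; one variant site per gene is
#'   simulated.
#' @param umi_depth Mean total UMIs per covered site (default 2).
#' @param detection_rate Per-gene probability that a site is covered in a
#'   cell at all (default 0.25); thins the Poisson totals.
#' @param par_genes Genes flagged pseudoautosomal in the variant index.
#' @return list with sparse `ref_umis` and `alt_umis` (cells x variants),
#'   `variant_info` (variant_id, gene, par_flag), `cell_meta` (cell,
#'   pseudotime, cluster), and `truth` (gene, category, phase).
#' @export
simulate_sc_allele_umis <- function(n_cells, config, umi_depth = 2,
                                    detection_rate = 0.25,
                                    par_genes = character()) {
  stopifnot(umi_depth > 0, n_cells >= 1,
            detection_rate > 0, detection_rate <= 1)
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  genes <- config$genes
  cts <- config$cell_types
  anchors <- seq(0, 1, length.out = length(cts))
  phase <- sample(c("ref_on_Xa", "alt_on_Xa"), length(genes), replace = TRUE)
  names(phase) <- genes

  cells <- sprintf("cell%05d", seq_len(n_cells))
  pt <- stats::runif(n_cells)
  cluster <- cts[pmin(findInterval(pt, anchors, rightmost.closed = TRUE),
                      length(cts) - 1) + 1]

  # p_Xi(t) per gene: linear interpolation between the cell-type anchors
  pxi_at <- function(g, t) {
    stats::approx(anchors, config$xi_profile[g, ], xout = t, rule = 2)$y
  }

  ij <- list(); xr <- list(); xa <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    total <- stats::rpois(n_cells, umi_depth) *
      stats::rbinom(n_cells, 1, detection_rate)
    covered <- which(total > 0)
    if (length(covered) == 0) next
    p_xi <- pxi_at(g, pt[covered])
    p_alt <- if (phase[g] == "ref_on_Xa") p_xi else 1 - p_xi
    alt <- stats::rbinom(length(covered), total[covered], p_alt)
    ij[[g]] <- cbind(covered, gi)
    xr[[g]] <- total[covered] - alt
    xa[[g]] <- alt
  }
  ijm <- do.call(rbind, ij)
  variant_ids <- paste0(genes, "_s1")
  mk <- function(x) {
    Matrix::sparseMatrix(i = ijm[, 1], j = ijm[, 2], x = x,
                         dims = c(n_cells, length(genes)),
                         dimnames = list(cells, variant_ids))
  }
  list(ref_umis = mk(unlist(xr)), alt_umis = mk(unlist(xa)),
       variant_info = data.frame(variant_id = variant_ids, gene = genes,
                                 par_flag = genes %in% par_genes,
                                 stringsAsFactors = FALSE),
       cell_meta = data.frame(cell = cells, pseudotime = pt,
                              cluster = cluster, stringsAsFactors = FALSE),
       truth = data.frame(gene = genes,
                          category = unname(config$category_truth[genes]),
                          phase = unname(phase[genes]),
                          stringsAsFactors = FALSE))
}

#' Simulate an expression matrix with planted differential expression
#'
#' Log-normal expression for a control condition plus one or more case
#' conditions whose cells are scaled by the specified fold in the stated
#' direction on each differentially expressed gene. With `sdlog = 0` the
#' data are noiseless, so the transcriptional-deviation statistic has a
#' closed-form expectation.
#'
#' @param n_cells Named integer vector of cells per condition; the first
#'   name is the control condition.
#' @param de_spec data.frame (gene, direction, fold) of planted effects;
#'   all folds must be positive. Direction `"up"` multiplies case cells by
#'   `fold^scale`, `"down"` divides.
#' @param fold_scale Named numeric exponent per case condition (default 1
#'   for each) to grade the effect across conditions.
#' @param n_extra_genes Unperturbed background genes added (default 50).
#' @param mu_log,sdlog Log-normal baseline parameters (defaults meanlog 2,
#'   sdlog 0.2).
#' @param seed Integer seed.
#' @return list with `expr` (genes x cells), `labels` (condition per cell),
#'   and `de_table` (gene, direction, log2_fold, adjusted_p placeholder).
#' @export
simulate_expression_for_deviation <- function(n_cells = c(control = 100,
                                                          case = 100),
                                              de_spec,
                                              fold_scale = NULL,
                                              n_extra_genes = 50,
                                              mu_log = 2, sdlog = 0.2,
                                              seed = 1) {
  .check_cols(de_spec, c("gene", "direction", "fold"), "de_spec")
  stopifnot(!is.null(names(n_cells)), length(n_cells) >= 2, all(n_cells >= 1))
  if (any(de_spec$fold <= 0)) stop("all folds must be positive")
  if (!all(de_spec$direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'")
  }
  conds <- names(n_cells)
  cases <- conds[-1]
  if (is.null(fold_scale)) fold_scale <- stats::setNames(rep(1, length(cases)),
                                                         cases)
  stopifnot(all(cases %in% names(fold_scale)))

  set.seed(seed)
  genes <- c(de_spec$gene,
             if (n_extra_genes > 0) sprintf("bg%03d", seq_len(n_extra_genes)))
  n_tot <- sum(n_cells)
  labels <- rep(conds, n_cells)
  cells <- sprintf("%s_c%04d", labels, unlist(lapply(n_cells, seq_len)))
  expr <- matrix(stats::rlnorm(length(genes) * n_tot, mu_log, sdlog),
                 nrow = length(genes), dimnames = list(genes, cells))
  for (cc in cases) {
    idx <- which(labels == cc)
    eff <- de_spec$fold^fold_scale[[cc]]
    eff[de_spec$direction == "down"] <- 1 / eff[de_spec$direction == "down"]
    expr[de_spec$gene, idx] <- expr[de_spec$gene, idx] * eff
  }
  de_table <- data.frame(gene = de_spec$gene, direction = de_spec$direction,
                         log2_fold = ifelse(de_spec$direction == "up", 1, -1) *
                           log2(de_spec$fold),
                         adjusted_p = 0, stringsAsFactors = FALSE)
  list(expr = expr, labels = stats::setNames(labels, cells),
       de_table = de_table)
}
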