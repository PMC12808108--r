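test_that("configurations are validated against their category truth", {
  cfg <- sim_config(n_genes = 20, seed = 1)
  expect_s3_class(cfg, "xireact_sim_config")
  expect_equal(nrow(cfg$xi_profile), 20)
  expect_true(all(cfg$xi_profile >= 0 & cfg$xi_profile <= 0.5))

  bad <- cfg
  g <- names(bad$category_truth)[bad$category_truth == "inactive"][1]
  bad$xi_profile[g, ] <- 0.3
  expect_error(validate_sim_config(bad), g)

  bad2 <- cfg
  bad2$xi_profile[1, 1] <- NaN
  expect_error(validate_sim_config(bad2), "out of range")

  # p_Xi above 0.5 is rejected regardless of category
  bad3 <- cfg
  bad3$xi_profile[1, 1] <- 0.7
  expect_error(validate_sim_config(bad3), "out of range")
})

test_that("the bulk simulator is deterministic given (config, seed)", {
  cfg <- sim_config(n_genes = 15, seed = 99)
  a <- simulate_bulk_allelic_counts(cfg)
  b <- simulate_bulk_allelic_counts(cfg)
  expect_identical(a, b)
  c2 <- simulate_bulk_allelic_counts(sim_config(n_genes = 15, seed = 100))
  expect_false(identical(a$counts, c2$counts))
})

test_that("degenerate probabilities give strictly monoallelic counts", {
  cfg <- sim_config(n_genes = 30, seed = 2,
                    category_probs = c(reactivated = 0, escape = 0,
                                       late_silenced = 0, inactive = 1),
                    xi_levels = list(inactive = rep(0, 3)))
  sim <- simulate_bulk_allelic_counts(cfg)
  per_var <- split(sim$counts, sim$counts$variant_id)
  for (v in per_var) {
    phase <- sim$truth$phase[sim$truth$gene == v$gene[1]]
    if (phase == "ref_on_Xa") {
      expect_true(all(v$ref_reads == v$total_reads))
    } else {
      expect_true(all(v$ref_reads == 0))
    }
  }
})

test_that("the pooled minor-allele fraction is calibrated at high depth", {
  cfg <- sim_config(n_genes = 40, variants_per_gene = c(1, 1),
                    replicates_per_cell_type = 8,
                    depth_mean = 12500, depth_dispersion = 0, seed = 17)
  # 8 samples x 12500 reads = 1e5 group reads per (variant, cell type)
  sim <- simulate_bulk_allelic_counts(cfg)
  summ <- pool_by_cell_type(sim$counts)
  m <- merge(summ, sim$sites[c("variant_id", "gene")], by = "variant_id")
  truth_p <- cfg$xi_profile[cbind(m$gene, m$cell_type)]
  expect_true(all(abs(m$xi_prob_hat - truth_p) < 0.01))

  # a balanced site at depth 1e4 stays within 3 binomial SE of 0.5
  half <- sim_config(n_genes = 5, variants_per_gene = c(1, 1),
                     depth_mean = 2500, depth_dispersion = 0, seed = 18,
                     category_probs = c(reactivated = 0, escape = 1,
                                        late_silenced = 0, inactive = 0),
                     xi_levels = list(escape = rep(0.5, 3)))
  shalf <- pool_by_cell_type(simulate_bulk_allelic_counts(half)$counts)
  se3 <- 3 * sqrt(0.25 / shalf$no_total)
  expect_true(all(abs(shalf$xi_prob_hat - 0.5) <= se3))
})

test_that("annotation places clusters and PAR flags as configured", {
  cfg <- sim_config(n_genes = 60, seed = 5)
  ann <- simulate_annotation(cfg, clustered_fraction = 0)
  expect_setequal(ann$gene, cfg$genes)
  expect_true(all(ann$tss_pos >= 1 & ann$tss_pos <= 1.5e8))
  expect_identical(ann$par_flag, ann$tss_pos <= 2.7e6)

  clustered <- simulate_annotation(cfg, clustered_fraction = 1,
                                   cluster_window = 1e4)
  target <- cfg$genes[cfg$category_truth == "reactivated"]
  spread <- diff(range(clustered$tss_pos[clustered$gene %in% target]))
  expect_lte(spread, 1e4)

  # two genes at fixed positions: the distance statistic is their gap
  toy <- data.frame(gene = c("a", "b"), tss_pos = c(1000, 2000))
  expect_equal(mean_pairwise_distance(toy$tss_pos), 1000)
})

test_that("single-cell simulator output is consistent and deterministic", {
  cfg <- sim_config(n_genes = 25, seed = 6)
  sc <- simulate_sc_allele_umis(300, cfg, umi_depth = 2)
  expect_identical(dim(sc$ref_umis), dim(sc$alt_umis))
  expect_true(all(sc$cell_meta$pseudotime >= 0 & sc$cell_meta$pseudotime <= 1))
  expect_true(all(sc$ref_umis@x >= 0) && all(sc$alt_umis@x >= 0))
  sc2 <- simulate_sc_allele_umis(300, cfg, umi_depth = 2)
  expect_identical(as.matrix(sc$ref_umis), as.matrix(sc2$ref_umis))
})

test_that("fully silenced genes give zero biallelic score in every cell", {
  cfg <- sim_config(n_genes = 10, seed = 9,
                    category_probs = c(reactivated = 0, escape = 0,
                                       late_silenced = 0, inactive = 1),
                    xi_levels = list(inactive = rep(0, 3)))
  sc <- simulate_sc_allele_umis(200, cfg, umi_depth = 4)
  s <- score_cells(sc$ref_umis, sc$alt_umis, sc$variant_info)
  expect_true(all(s$cell_sums$biallelic_sum == 0))
})

test_that("a reactivation ramp yields monotone binned scores along pseudotime", {
  cfg <- sim_config(n_genes = 40, seed = 10,
                    category_probs = c(reactivated = 1, escape = 0,
                                       late_silenced = 0, inactive = 0),
                    xi_levels = list(reactivated = c(0, 0.25, 0.5)))
  sc <- simulate_sc_allele_umis(5000, cfg, umi_depth = 4)
  s <- score_cells(sc$ref_umis, sc$alt_umis, sc$variant_info)
  sums <- s$cell_sums$biallelic_sum[match(sc$cell_meta$cell,
                                          s$cell_sums$cell)]
  b <- bin_by_pseudotime(sums, sc$cell_meta$pseudotime, n_bins = 10)
  rho <- cor(b$bin, b$mean, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("expression simulator plants exact effects when noiseless", {
  de <- data.frame(gene = c("u1", "d1"), direction = c("up", "down"),
                   fold = c(4, 2))
  sim <- simulate_expression_for_deviation(c(control = 5, case = 5), de,
                                           n_extra_genes = 3, sdlog = 0,
                                           seed = 7)
  ctrl <- sim$expr[, sim$labels == "control"]
  case <- sim$expr[, sim$labels == "case"]
  expect_equal(unname(case["u1", ] / ctrl["u1", 1]), rep(4, 5))
  expect_equal(unname(case["d1", ] / ctrl["d1", 1]), rep(0.5, 5))
  # closed-form deviation: up fold 4 and down fold 2 halved -> (4 + 2) / 2
  cm <- control_means(sim$expr, colnames(ctrl),
                      setNames(rep("k", 10), colnames(sim$expr)))
  d <- cell_deviation(sim$expr[, 6], cm[, "k"], de, epsilon = 0)
  expect_equal(d, 3)

  # identity folds leave case cells at deviation 1
  de1 <- data.frame(gene = c("u1", "d1"), direction = c("up", "down"),
                    fold = c(1, 1))
  sim1 <- simulate_expression_for_deviation(c(control = 5, case = 5), de1,
                                            n_extra_genes = 0, sdlog = 0,
                                            seed = 7)
  cm1 <- control_means(sim1$expr,
                       names(sim1$labels)[sim1$labels == "control"],
                       setNames(rep("k", 10), names(sim1$labels)))
  d1 <- cell_deviation(sim1$expr[, 6], cm1[, "k"], de1, epsilon = 0)
  expect_equal(d1, 1)
})

test_that("the classifier recovers simulated categories end to end", {
  cfg <- sim_config(n_genes = 120, seed = 23)
  sim <- simulate_bulk_allelic_counts(cfg)
  f <- filter_variants(sim$sites, sim$counts)
  summ <- pool_by_cell_type(f$counts)
  calls <- flag_replicate_inconsistency(f$counts, classify_variants(summ))
  gc <- gene_calls(calls, f$sites, summ)
  m <- merge(gc[c("gene", "category")], sim$truth[c("gene", "category")],
             by = "gene")
  perf <- class_performance(as.character(m$category.x),
                            as.character(m$category.y),
                            c("reactivated", "escape", "late_silenced",
                              "inactive"))
  expect_true(all(perf["sensitivity", ] >= 0.9))
  expect_true(all(perf["specificity", ] >= 0.9))
})
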