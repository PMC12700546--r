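test_that("LD panel structure: blocks partition variants, identity case, seed determinism", {
  p0 <- simulate_ld_panel(100, 10, within_block_correlation = 0, seed = 5)
  expect_equal(sum(lengths(split(seq_len(100), p0$variants$block_id))), 100)
  offdiag <- unlist(lapply(p0$blocks, function(R) R[row(R) != col(R)]))
  expect_true(all(offdiag == 0))
  expect_true(all(diff(p0$variants$position) > 0))

  p1 <- simulate_ld_panel(100, 10, 0.5, seed = 1)
  p2 <- simulate_ld_panel(100, 10, 0.5, seed = 1)
  expect_identical(p1$variants, p2$variants)
  expect_identical(p1$blocks, p2$blocks)
  for (R in p1$blocks) {
    expect_identical(R, t(R))
    expect_true(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > -1e-12)
  }
})

test_that("multi-allelic flagging hits the requested count and arguments are validated", {
  p <- simulate_ld_panel(200, 10, 0.5, multiallelic_fraction = 0.1, seed = 3)
  expect_equal(sum(p$variants$multiallelic), round(0.1 * 200))
  expect_true(all(grepl(",", p$variants$allele_alt[p$variants$multiallelic])))
  expect_error(simulate_ld_panel(0, 1), "n_variants")
  expect_error(simulate_ld_panel(10, 20), ">=")
  expect_error(simulate_ld_panel(10, 2, within_block_correlation = 1), "\\[0, 1\\)")
})

test_that("summary-statistic simulator obeys the additive model", {
  panel <- simulate_ld_panel(5000, 50, 0.5, 0, seed = 7, mhc_like_fraction = 0)
  base <- build_snp_annotations(panel)
  # null: tau = 0 -> mean chi2 near 1 (3 MC SEs, block-correlated chi2)
  ss0 <- simulate_gwas_sumstats(panel, base, tau_true = c(base = 0), N = 5e4,
                                seed = 11)
  n_eff <- 5000 / (1 + (5000 / 50 - 1) * 0.5^2)
  expect_lt(abs(mean(ss0$Z^2) - 1), 3 * sqrt(2 / n_eff))
  # same seed -> identical draws
  ss0b <- simulate_gwas_sumstats(panel, base, c(base = 0), 5e4, seed = 11)
  expect_identical(ss0$Z, ss0b$Z)

  # all-ones annotation with tau * N * mean(l) = 4 -> mean chi2 near 5,
  # Monte-Carlo oracle over 50 replicate seeds
  ld <- compute_ld_scores(panel, base)
  tau <- 4 / (5e4 * mean(ld$scores[, "base"]))
  means <- vapply(1:50, function(s) {
    mean(simulate_gwas_sumstats(panel, base, c(base = tau), 5e4,
                                seed = 100 + s)$Z^2)
  }, numeric(1))
  expect_lt(abs(mean(means) - 5), 3 * stats::sd(means) / sqrt(50))
  # misaligned annotations refused
  expect_error(simulate_gwas_sumstats(panel, base[-1, , drop = FALSE],
                                      c(base = 0), 5e4, 1), "align")
})

test_that("expression simulator plants markers, is exchangeable under the null, and is seeded", {
  cl <- sprintf("K%d", 1:4)
  e0 <- simulate_expression(100, cl, 10, marker_fraction = 0.02,
                            log_fold_change = 0,
                            covariate_effects = c(age = 0, sex = 0), seed = 9)
  # exchangeable null: cluster means of a gene agree up to sampling noise
  cm <- vapply(cl, function(k)
    rowMeans(e0$expr$values[, e0$expr$cluster == k]), numeric(100))
  expect_lt(mean(abs(cm - rowMeans(cm))), 0.5)

  e1 <- simulate_expression(100, cl, 10, marker_fraction = 0.02,
                            log_fold_change = 2, seed = 9)
  e1b <- simulate_expression(100, cl, 10, marker_fraction = 0.02,
                             log_fold_change = 2, seed = 9)
  expect_identical(e1$expr$values, e1b$expr$values)
  expect_true(all(lengths(e1$truth$marker_genes) == 2))
  expect_error(simulate_expression(100, c("A", "A"), 10), "distinct")
  expect_error(simulate_expression(100, cl, 10, marker_fraction = 0.001),
               ">= 1")
})

test_that("planted markers top the specificity ranking across seeds", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_expression(150, sprintf("K%d", 1:3), 12,
                               marker_fraction = 0.04, log_fold_change = 2,
                               seed = 500 + s)
    spec <- specificity_regression(sim$expr, covariates = sim$covariates)
    sets <- top_k_gene_sets(spec, k = 2 * 6) # twice the marker count
    mean(vapply(names(sets), function(k)
      mean(sim$truth$marker_genes[[k]] %in% sets[[k]]), numeric(1)))
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cluster metadata normalizes fractions and honours the majority rule", {
  md1 <- simulate_cluster_metadata(c("a", "b"), "GLUT", c("PFC", "AMY"),
                                   dominant_fraction = 1, seed = 1)
  expect_true(all(!is.na(md1$assigned_region)))
  md5 <- simulate_cluster_metadata(c("a", "b"), "GLUT", c("PFC", "AMY"),
                                   dominant_fraction = 0.5, seed = 1)
  expect_true(all(is.na(md5$assigned_region)))
  fr <- as.matrix(md5[, grep("^frac_", names(md5))])
  expect_equal(unname(rowSums(fr)), c(1, 1))
  expect_error(simulate_cluster_metadata(character(0), "x", "y"), "nonempty")
})

test_that("perturbation tables straddle the FDR cut with the stated enriched overlap", {
  study <- tiny_study()
  deg <- study$deg_table
  enriched <- study$truth$marker_genes[[study$truth$enriched_clusters]]
  for (ct in unique(deg$cell_type)) {
    sel <- deg[deg$cell_type == ct, ]
    below <- sel$gene[sel$fdr < 0.01]
    expect_equal(length(below), 12)           # set_size survives the cut
    expect_true(any(sel$fdr >= 0.01))          # decoys above the cut
    expect_equal(mean(below %in% enriched), 1) # overlap_with_enriched = 1
  }
  expect_error(simulate_perturbation_sets(study$truth, "ct", set_size = 0),
               "set_size")
  expect_error(simulate_perturbation_sets(study$truth, "ct",
                                          overlap_with_enriched = 2), "\\[0, 1\\]")
})

test_that("fixture bundles round-trip through the pipeline loaders", {
  study <- tiny_study()
  dir <- withr::local_tempdir()
  manifest <- write_fixture_bundle(study, dir)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  loaded <- expect_silent(load_fixture_bundle(dir))

  expect_equal(loaded$sumstats_raw$Z, study$sumstats_raw$Z, tolerance = 1e-12)
  expect_identical(loaded$panel$variants$variant_id,
                   study$panel$variants$variant_id)
  expect_equal(loaded$panel$r, study$panel$r)
  expect_equal(transform_and_aggregate(loaded$expr)$values,
               study$expression$expr$values, tolerance = 1e-9)
  expect_equal(loaded$gene_coords, study$gene_coords)
  expect_identical(lapply(unclass(loaded$marker_sets), identity),
                   lapply(study$truth$marker_genes, identity))
  # manifest row counts match the files
  ss_rows <- nrow(read_sumstats(file.path(dir, "sumstats.tsv")))
  expect_equal(manifest$n_rows[manifest$file == "sumstats.tsv"], ss_rows)
  # truth JSON records the planted parameters
  expect_equal(unname(unlist(loaded$truth$tau)),
               unname(study$truth$tau["enriched"]))
  expect_true(study$truth$enriched_clusters %in%
                names(loaded$truth$marker_genes))
})
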