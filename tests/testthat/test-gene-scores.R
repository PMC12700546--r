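test_that("positional mapping matches the brute-force interval oracle", {
  set.seed(21)
  variants <- data.frame(SNP = sprintf("v%02d", 1:12),
                         CHR = c(rep("1", 8), rep("2", 4)),
                         BP = c(sort(sample.int(5000, 8)), sort(sample.int(5000, 4))),
                         stringsAsFactors = FALSE)
  coords <- data.frame(gene = sprintf("g%d", 1:5),
                       chromosome = c("1", "1", "1", "2", "2"),
                       start = c(100, 1500, 3000, 200, 2600),
                       end = c(1400, 2600, 4500, 2500, 4800),
                       stringsAsFactors = FALSE)
  m <- map_snps_to_genes(variants, coords, drop_mhc_genes = FALSE)
  expect_identical(m$genes, map_oracle(variants, coords))
  mw <- map_snps_to_genes(variants, coords, window_up_kb = 1,
                          window_down_kb = 0.5, drop_mhc_genes = FALSE)
  expect_identical(mw$genes, map_oracle(variants, coords, up = 1, down = 0.5))

  # boundary: variant exactly at the gene start is mapped at window 0
  vb <- data.frame(SNP = "x", CHR = "1", BP = 100)
  mb <- map_snps_to_genes(vb, coords, drop_mhc_genes = FALSE)
  expect_identical(mb$genes$g1, "x")

  # genes overlapping the MHC-like interval are dropped when flagged
  mhc_coords <- rbind(coords,
                      data.frame(gene = "gMHC", chromosome = "6",
                                 start = 24e6, end = 26e6))
  mm <- map_snps_to_genes(variants, mhc_coords, drop_mhc_genes = TRUE)
  expect_false("gMHC" %in% names(mm$genes))
  expect_equal(unname(mm$dropped["mhc"]), 1)

  # non-unique names dropped entirely
  dup_coords <- rbind(coords, coords[1, ])
  md <- map_snps_to_genes(variants, dup_coords, drop_mhc_genes = FALSE)
  expect_false("g1" %in% names(md$genes))
  expect_equal(unname(md$dropped["nonunique"]), 2)
})

test_that("gene association reduces to the SNP p for one variant and the exact chi-square sum when independent", {
  panel <- simulate_ld_panel(40, 40, 0, seed = 2, mhc_like_fraction = 0) # identity LD
  ss <- harmonize_and_filter_sumstats(
    simulate_gwas_sumstats(panel, build_snp_annotations(panel),
                           c(base = 0), 1e4, seed = 6),
    mhc_interval = NULL)
  mapping <- structure(list(genes = list(g1 = ss$SNP[1],
                                         g4 = ss$SNP[2:5],
                                         g10 = ss$SNP[6:15]),
                            dropped = c(nonunique = 0, mhc = 0, empty = 0)),
                       class = "snp_gene_map")
  ga <- gene_association(ss, mapping, panel)
  expect_equal(ga$p[ga$gene == "g1"], ss$P[1], tolerance = 1e-12)
  expect_equal(ga$p[ga$gene == "g4"],
               pchisq(sum(ss$CHISQ[2:5]), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(ga$p[ga$gene == "g10"],
               pchisq(sum(ss$CHISQ[6:15]), df = 10, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(ga$statistic, c(ss$CHISQ[1], mean(ss$CHISQ[2:5]),
                               mean(ss$CHISQ[6:15])))
  # a variant absent from the panel falls back to independence with warning
  mapping2 <- mapping
  mapping2$genes$g1 <- c(mapping2$genes$g1, "rs_not_in_panel")
  expect_warning(gene_association(
    rbind(ss, transform(ss[1, ], SNP = "rs_not_in_panel")), mapping2, panel),
    "independent")
})

test_that("gene-association type-I error is nominal for independent and correlated blocks", {
  for (r in c(0, 0.5)) {
    n_genes <- 10000L; m <- 8L
    panel <- simulate_ld_panel(n_genes * m, n_genes, r, seed = 13,
                               mhc_like_fraction = 0)
    # NB: the panel assigns random block sizes; build gene blocks explicitly
    panel$variants$block_id <- rep(seq_len(n_genes), each = m)
    R <- matrix(r, m, m); diag(R) <- 1
    panel$blocks <- rep(list(R), n_genes)
    ss <- harmonize_and_filter_sumstats(
      simulate_gwas_sumstats(panel, build_snp_annotations(panel),
                             c(base = 0), 1e4, seed = 17 + round(10 * r)),
      mhc_interval = NULL)
    mapping <- structure(list(genes = split(ss$SNP, rep(seq_len(n_genes), each = m)),
                              dropped = c(nonunique = 0, mhc = 0, empty = 0)),
                         class = "snp_gene_map")
    names(mapping$genes) <- sprintf("g%05d", seq_len(n_genes))
    ga <- gene_association(ss, mapping, panel)
    rate <- mean(ga$p < 0.05)
    expect_gte(rate, 0.04)
    expect_lte(rate, 0.06)
  }
})

test_that("gene-property regression recovers a constructed slope and flags collinearity", {
  set.seed(5)
  genes <- sprintf("g%03d", 1:200)
  specs <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(genes, c("A", "B", "C")))
  avg <- stats::setNames(rnorm(200), genes)
  z <- 0.5 * specs[, "A"]
  ga <- structure(data.frame(gene = genes, n_snps = 1, statistic = 1,
                             p = pnorm(z, lower.tail = FALSE), z = z),
                  class = c("gene_assoc", "data.frame"))
  res <- gene_property_scan(ga, specs, avg)
  expect_equal(res$beta[res$cluster == "A"], 0.5, tolerance = 1e-8)
  expect_lt(res$p[res$cluster == "A"], 1e-10)
  expect_gt(min(res$p[res$cluster != "A"]), 1e-4)

  # specificity identical to the average-expression covariate -> flagged
  specs2 <- cbind(specs, D = avg[genes])
  expect_warning(res2 <- gene_property_scan(ga, specs2, avg), "collinear")
  expect_true(res2$collinear[res2$cluster == "D"])
  expect_true(is.na(res2$beta[res2$cluster == "D"]))

  expect_error(gene_property_scan(ga[1:10, ], specs, avg), "overlapping")
})

test_that("gene heritability is calibrated under the null and recovers a planted per-SNP excess", {
  m <- 10L; n_genes <- 800L
  panel <- simulate_ld_panel(n_genes * m, n_genes, 0, seed = 19,
                             mhc_like_fraction = 0)
  panel$variants$block_id <- rep(seq_len(n_genes), each = m)
  panel$blocks <- rep(list(diag(m)), n_genes)
  A <- build_snp_annotations(panel)
  N <- 5e4
  mapping <- structure(list(genes = stats::setNames(
    split(panel$variants$variant_id, panel$variants$block_id),
    sprintf("g%04d", seq_len(n_genes))),
    dropped = c(nonunique = 0, mhc = 0, empty = 0)),
    class = "snp_gene_map")

  ss0 <- harmonize_and_filter_sumstats(
    simulate_gwas_sumstats(panel, A, c(base = 0), N, seed = 23),
    mhc_interval = NULL)
  h0 <- gene_heritability_test(ss0, mapping, panel)
  expect_gt(stats::ks.test(h0$p, "punif")$p.value, 0.01)
  expect_lt(mean(h0$h2_gene), 2 * m / N) # truncated-at-zero null mean stays small
  expect_true(all(h0$h2_gene >= 0))
  expect_true(any(h0$truncated))

  # planted: per-SNP variance tau with N * tau * l = 4 -> h2 near m * 4 / N
  tau <- 4 / N # identity LD: l = 1 for the all-ones annotation
  ss1 <- harmonize_and_filter_sumstats(
    simulate_gwas_sumstats(panel, A, c(base = tau), N, seed = 29),
    mhc_interval = NULL)
  h1 <- gene_heritability_test(ss1, mapping, panel)
  expect_lt(abs(mean(h1$h2_gene) - m * 4 / N),
            2 * stats::sd(h1$h2_gene) / sqrt(n_genes))
  expect_lt(stats::median(h1$q), 0.05)
})

test_that("pre-ranked GSEA is extreme for a top slice, seeded, bounded, and rank-mode monotone-invariant", {
  set.seed(3)
  stats_vec <- stats::setNames(rnorm(2000), sprintf("g%04d", 1:2000))
  top50 <- names(sort(stats_vec, decreasing = TRUE))[1:50]
  sets <- gene_set_collection(list(top = top50,
                                   rand = sample(names(stats_vec), 50)))
  res <- preranked_gsea(stats_vec, sets, n_permutations = 500, seed = 7)
  expect_gt(res$es[res$set == "top"], 0)
  expect_lte(res$p[res$set == "top"], 2 / 501)
  expect_true(all(abs(res$es) <= 1))
  res2 <- preranked_gsea(stats_vec, sets, n_permutations = 500, seed = 7)
  expect_identical(res, res2)

  # monotone transform leaves rank-weighted ES unchanged
  r1 <- preranked_gsea(stats_vec, sets, n_permutations = 100, seed = 1,
                       weight = "rank")
  r2 <- preranked_gsea(exp(stats_vec), sets, n_permutations = 100, seed = 1,
                       weight = "rank")
  expect_equal(r1$es, r2$es, tolerance = 1e-12)

  expect_error(preranked_gsea(stats_vec,
                              gene_set_collection(list(out = c("zz1", "zz2"))),
                              n_permutations = 100),
               "out")
})

test_that("running-sum ES agrees with the independent fgsea implementation", {
  set.seed(8)
  stats_vec <- stats::setNames(rnorm(500), sprintf("g%03d", 1:500))
  sets <- list(s1 = names(sort(stats_vec, decreasing = TRUE))[1:30],
               s2 = sample(names(stats_vec), 40))
  ours <- preranked_gsea(stats_vec, gene_set_collection(sets),
                         n_permutations = 200, seed = 2)
  ref <- suppressWarnings(fgsea::fgsea(sets, stats_vec, nperm = 1000,
                                       gseaParam = 1))
  expect_equal(ours$es[match(ref$pathway, ours$set)], ref$ES,
               tolerance = 0.02)
})
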