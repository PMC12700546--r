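toy_sumstats <- function() {
  # 10 variants: 2 inside the MHC-like interval, 1 multi-allelic elsewhere
  data.frame(
    SNP = sprintf("v%02d", 1:10),
    CHR = c(rep("6", 4), rep("1", 6)),
    BP = c(1e6, 26e6, 30e6, 40e6, seq(1e5, 6e5, by = 1e5)),
    A1 = "A",
    A2 = c(rep("G", 6), "G,T", rep("G", 3)),
    N = 1000, Z = seq(-2, 2.5, by = 0.5),
    stringsAsFactors = FALSE
  )
}

test_that("harmonization filters MHC, multi-allelic and duplicate variants with a reconciling report", {
  ss <- harmonize_and_filter_sumstats(toy_sumstats())
  expect_s3_class(ss, "gwas_sumstats")
  expect_equal(nrow(ss), 7)
  rep <- attr(ss, "filter_report")
  expect_equal(rep$n[rep$step == "input"],
               sum(rep$n[rep$step %in% c("mhc_interval", "multiallelic",
                                         "duplicate", "surviving")]))
  expect_equal(ss$CHISQ, ss$Z^2)

  # no-op filters leave the table intact
  id <- harmonize_and_filter_sumstats(toy_sumstats(), mhc_interval = NULL,
                                      drop_multiallelic = FALSE)
  expect_equal(nrow(id), 10)

  # duplicates: first kept, warning raised
  dup <- rbind(toy_sumstats(), toy_sumstats()[10, ])
  expect_warning(out <- harmonize_and_filter_sumstats(dup), "duplicated")
  expect_equal(sum(out$SNP == "v10"), 1)

  expect_error(harmonize_and_filter_sumstats(toy_sumstats()[, -6]), "missing")
  expect_error(harmonize_and_filter_sumstats(
    within(toy_sumstats(), CHR <- "6"),
    mhc_interval = list(chromosome = 6, start = 0, end = 1e9)), "survive")
})

test_that("Z is reconstructed from p and sign so that Z^2 matches the implied chi-square", {
  raw <- toy_sumstats()
  p <- 2 * pnorm(-abs(raw$Z))
  raw2 <- raw[, setdiff(names(raw), "Z")]
  raw2$P <- p
  raw2$BETA <- sign(raw$Z) * 0.1
  out <- harmonize_and_filter_sumstats(raw2, mhc_interval = NULL,
                                       drop_multiallelic = FALSE)
  expect_equal(out$CHISQ, qchisq(p, df = 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(sign(out$Z), sign(raw$Z))
  expect_error(harmonize_and_filter_sumstats(raw2[, setdiff(names(raw2), "BETA")]),
               "direction")
})

test_that("gene-window and BED annotations follow the interval conventions", {
  variants <- data.frame(SNP = c("a", "b", "c", "d"), CHR = "1",
                         BP = c(50000, 100, 201, 150), stringsAsFactors = FALSE)
  coords <- data.frame(gene = "g1", chromosome = "chr1", start = 1000,
                       end = 2000, stringsAsFactors = FALSE)
  A <- build_snp_annotations(variants, gene_sets = list(set1 = "g1"),
                             gene_coords = coords, window_kb = 100)
  expect_equal(unname(A[, "base"]), rep(1, 4))
  expect_equal(unname(A["a", "set1"]), 1) # 50,000 inside 1,000 +/- 100kb

  # BED 0-based half-open: [100, 200) covers 1-based 101..200
  bed <- data.frame(chrom = "chr1", start = 100, end = 200)
  B <- build_snp_annotations(variants, region_sets = list(r = bed))
  expect_equal(unname(B[c("b", "c", "d"), "r"]), c(0, 0, 1))
  # empty interval matches nothing even at its own coordinate
  bed0 <- data.frame(chrom = "chr1", start = 100, end = 100)
  B0 <- build_snp_annotations(variants, region_sets = list(r = bed0))
  expect_equal(sum(B0[, "r"]), 0)
  # flanking extends both sides
  Bf <- build_snp_annotations(variants, region_sets = list(r = bed),
                              flank_bp = 1)
  expect_equal(unname(Bf["b", "r"]), 1)

  expect_warning(E <- build_snp_annotations(variants,
                                            gene_sets = list(none = "gX"),
                                            gene_coords = coords),
                 "empty")
  expect_equal(sum(E[, "none"]), 0)
})

test_that("LD scores equal the defining sum over block members", {
  # identity LD: l(j, c) = a(j, c)
  p0 <- simulate_ld_panel(50, 5, 0, seed = 1, mhc_like_fraction = 0)
  A <- build_snp_annotations(p0)
  A <- cbind(A, half = rep(c(1, 0), length.out = 50))
  rownames(A) <- p0$variants$variant_id
  ld0 <- compute_ld_scores(p0, A)
  expect_equal(unname(ld0$scores[, "half"]), unname(A[, "half"]))

  # 2-variant block, r = 0.5, all-ones annotation -> 1 + 0.25 = 1.25
  p2 <- simulate_ld_panel(2, 1, 0.5, seed = 1, mhc_like_fraction = 0)
  ld2 <- compute_ld_scores(p2, build_snp_annotations(p2))
  expect_equal(unname(ld2$scores[, "base"]), c(1.25, 1.25))

  # baseline dominates every binary sub-annotation
  p <- simulate_ld_panel(200, 10, 0.5, seed = 3, mhc_like_fraction = 0)
  coords <- synthetic_gene_coords(p, 20)
  A2 <- build_snp_annotations(p, gene_sets = list(s = coords$gene[1:5]),
                              gene_coords = coords, window_kb = 0)
  ld <- compute_ld_scores(p, A2)
  expect_true(all(ld$scores[, "base"] >= ld$scores[, "s"] - 1e-12))

  # unbiased adjustment subtracts (1 - r2) / (n_ref - 2)
  ldu <- compute_ld_scores(p2, build_snp_annotations(p2),
                           r2_adjustment = "unbiased", n_ref = 100)
  expect_equal(unname(ldu$scores[1, "base"]),
               1 + (0.25 - 0.75 / 98), tolerance = 1e-12)
  expect_error(compute_ld_scores(p2, build_snp_annotations(p2),
                                 r2_adjustment = "unbiased"), "n_ref")
})

test_that("noiseless stratified regression recovers planted coefficients exactly", {
  panel <- simulate_ld_panel(600, 12, 0.4, seed = 8, mhc_like_fraction = 0)
  coords <- synthetic_gene_coords(panel, 60)
  A <- build_snp_annotations(panel,
                             gene_sets = list(c1 = coords$gene[1:10],
                                              c2 = coords$gene[31:45]),
                             gene_coords = coords, window_kb = 0)
  ld <- compute_ld_scores(panel, A)
  N <- 5e4; tau <- c(base = 0, c1 = 2e-5, c2 = 5e-6)
  chi2 <- 1 + N * as.numeric(ld$scores %*% tau)
  ss <- data.frame(SNP = panel$variants$variant_id, CHR = "1",
                   BP = panel$variants$position, A1 = "A", A2 = "G",
                   N = N, Z = sqrt(chi2), stringsAsFactors = FALSE)
  ss <- harmonize_and_filter_sumstats(ss, mhc_interval = NULL)
  fit <- stratified_regression(ss, ld, n_jackknife_blocks = 12)
  expect_equal(fit$tau_hat[fit$annotation == "c1"], 2e-5, tolerance = 1e-8)
  expect_equal(fit$tau_hat[fit$annotation == "c2"], 5e-6, tolerance = 1e-8)
  expect_equal(unname(attr(fit, "intercept")["estimate"]), 1,
               tolerance = 1e-6)

  # permuting variant order (id matching) leaves tau unchanged
  perm <- sample(nrow(ss))
  fit_p <- stratified_regression(ss[perm, ], ld, n_jackknife_blocks = 12)
  expect_equal(fit_p$tau_hat, fit$tau_hat, tolerance = 1e-10)
})

test_that("jackknife SE approaches the analytic OLS SE on homoskedastic independent data", {
  # mild LD so the baseline LD score varies (identity LD would make it
  # constant and collinear with the intercept); noise is iid by construction
  panel <- simulate_ld_panel(20000, 200, 0.2, seed = 4, mhc_like_fraction = 0)
  coords <- synthetic_gene_coords(panel, 2000)
  set.seed(11)
  A <- build_snp_annotations(panel,
                             gene_sets = list(s = sample(coords$gene, 200)),
                             gene_coords = coords, window_kb = 0)
  ld <- compute_ld_scores(panel, A)
  N <- 5e4
  x <- ld$scores[, "s"]
  y <- 1 + N * 1e-5 * x + rnorm(20000, sd = 0.3)
  ss <- data.frame(SNP = panel$variants$variant_id, CHR = "1",
                   BP = panel$variants$position, A1 = "A", A2 = "G",
                   N = N, Z = sqrt(pmax(y, 0)), stringsAsFactors = FALSE)
  ss <- harmonize_and_filter_sumstats(ss, mhc_interval = NULL)
  fit <- stratified_regression(ss, ld, n_jackknife_blocks = 200,
                               weights = "none")
  X <- cbind(1, N * ld$scores)
  ols <- lm.fit(X, ss$CHISQ)
  sigma2 <- sum(ols$residuals^2) / (nrow(X) - ncol(X))
  se_analytic <- sqrt(sigma2 * diag(chol2inv(qr.R(qr(X)))))
  i <- which(fit$annotation == "s") + 1L # skip the intercept column
  expect_lt(abs(fit$se[fit$annotation == "s"] - se_analytic[i]) /
              se_analytic[i], 0.10)
})

test_that("scan assigns FDR within families and q equals p for a singleton family", {
  study <- tiny_study()
  ss <- harmonize_and_filter_sumstats(study$sumstats_raw,
                                      mhc_interval = study$panel$mhc_interval)
  one <- build_snp_annotations(study$panel,
                               gene_sets = list(C01 = study$truth$marker_genes$C01),
                               gene_coords = study$gene_coords, window_kb = 0)
  scan1 <- celltype_heritability_scan(ss, study$panel, one,
                                      n_jackknife_blocks = 30)
  expect_equal(scan1$q, scan1$p)

  spec <- specificity_regression(study$expression$expr,
                                 covariates = study$expression$covariates)
  sets <- top_k_gene_sets(spec, k = 12)
  ann <- build_snp_annotations(study$panel, gene_sets = sets,
                               gene_coords = study$gene_coords, window_kb = 0)
  fam <- stats::setNames(rep(c("f1", "f2"), each = 3), colnames(ann)[-1])
  scan <- celltype_heritability_scan(ss, study$panel, ann, families = fam,
                                     n_jackknife_blocks = 30)
  expect_equal(scan$cluster[which.min(scan$p)], "C01") # planted cluster
  for (f in c("f1", "f2")) {
    ix <- scan$family == f
    expect_equal(scan$q[ix], bh_fdr(scan$p[ix]))
  }
  expect_error(celltype_heritability_scan(ss, study$panel, ann,
                                          families = fam[-1],
                                          n_jackknife_blocks = 30),
               "family")
})
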