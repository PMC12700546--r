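#' Planted-signal recovery experiment across simulated studies
#'
#' Repeats the reference synthetic study over a sequence of seeds and, for
#' each replicate, runs both detection routes end to end — the stratified
#' LD-score scan over the specificity top-K annotations and the
#' gene-property regression — then records whether the planted cluster (i)
#' attains the smallest scan p-value, (ii) passes the scan FDR threshold,
#' and (iii) is called concordantly by both methods. This is the package's
#' operating-characteristics benchmark at the reference study conditions.
#'
#' @param n_seeds Number of replicate studies.
#' @param base_seed Replicate i uses seed `base_seed + i`.
#' @param fdr_alpha FDR threshold for significance and concordance.
#' @param top_k Genes per cluster for the scan annotations (default 80, the
#'   planted marker count at the reference conditions).
#' @param ... Passed on to [simulate_study()] to change the study scale.
#' @return Data frame with one row per seed: `seed`, `top_ranked`,
#'   `significant`, `concordant`.
#' @export
planted_recovery_experiment <- function(n_seeds = 50, base_seed = 1000L,
                                        fdr_alpha = 0.05, top_k = 80L, ...) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    study <- simulate_study(seed = base_seed + i, ...)
    ss <- harmonize_and_filter_sumstats(study$sumstats_raw,
                                        mhc_interval = study$panel$mhc_interval)
    spec <- specificity_regression(study$expression$expr,
                                   covariates = study$expression$covariates)
    sets <- top_k_gene_sets(spec, k = top_k)
    ann <- build_snp_annotations(study$panel, gene_sets = sets,
                                 gene_coords = study$gene_coords,
                                 window_kb = 0)
    scan <- celltype_heritability_scan(ss, study$panel, ann,
                                       n_jackknife_blocks = 200,
                                       fdr_alpha = fdr_alpha)
    mapping <- map_snps_to_genes(ss, study$gene_coords,
                                 mhc_interval = study$panel$mhc_interval)
    ga <- gene_association(ss, mapping, study$panel)
    prop <- gene_property_scan(ga, spec,
                               rowMeans(study$expression$expr$values))
    conc <- concordance_intersect(scan, prop, alpha = fdr_alpha)
    planted <- study$truth$enriched_clusters
    data.frame(
      seed = base_seed + i,
      top_ranked = scan$cluster[which.min(scan$p)] == planted,
      significant = scan$q[scan$cluster == planted] < fdr_alpha,
      concordant = planted %in% conc$table$cluster[conc$table$concordant])
  })
  do.call(rbind, rows)
}

#' Null calibration of the stratified scan
#'
#' Simulates repeated GWAS under the global null (no annotation carries
#' heritability) against a fixed LD panel and a fixed gene-set annotation,
#' and returns the one-sided p-value of the annotation coefficient from
#' each scan. Under a well-calibrated test these p-values are uniform.
#'
#' @param n_scans Number of simulated GWAS.
#' @param base_seed Panel and annotation use `base_seed`; scan i uses
#'   `base_seed + i`.
#' @param n_variants,n_blocks,n_genes Panel geometry.
#' @param annotation_genes Genes in the scanned annotation.
#' @param N GWAS sample size.
#' @return Numeric vector of `n_scans` one-sided p-values.
#' @export
null_scan_pvalues <- function(n_scans = 1000, base_seed = 1L,
                              n_variants = 10000L, n_blocks = 100L,
                              n_genes = 1000L, annotation_genes = 100L,
                              N = 5e4) {
  panel <- simulate_ld_panel(n_variants, n_blocks, 0.5, 0, seed = base_seed,
                             mhc_like_fraction = 0)
  coords <- synthetic_gene_coords(panel, n_genes)
  genes <- seeded(base_seed, sample(coords$gene, annotation_genes))
  ann <- build_snp_annotations(panel, gene_sets = list(s = genes),
                               gene_coords = coords, window_kb = 0)
  ld <- compute_ld_scores(panel, ann)
  vapply(seq_len(n_scans), function(i) {
    raw <- simulate_gwas_sumstats(panel, ann, c(s = 0), N,
                                  seed = base_seed + i)
    ss <- harmonize_and_filter_sumstats(raw, mhc_interval = NULL)
    fit <- stratified_regression(ss, ld, n_jackknife_blocks = n_blocks)
    fit$p_one_sided[fit$annotation == "s"]
  }, numeric(1))
}
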