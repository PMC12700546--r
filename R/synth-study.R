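#' Simulate a complete synthetic study with known ground truth
#'
#' Composes the individual generators into one coherent study: a block-LD
#' panel, gene coordinates tiling the panel, clustered expression with
#' donor covariates and planted marker genes, cluster metadata, GWAS
#' summary statistics with heritability planted on the enriched cluster's
#' marker-gene variants, and perturbation (DEG) tables overlapping the
#' enriched genes. The defaults are the package's reference study
#' conditions (see the methods vignette); all randomness derives from
#' `seed`.
#'
#' @param seed Master seed; sub-generators use fixed offsets from it.
#' @param n_variants,n_blocks,within_block_correlation,multiallelic_fraction
#'   Passed to [simulate_ld_panel()].
#' @param n_genes Genes tiling the panel (see [synthetic_gene_coords()]).
#' @param n_clusters,cells_per_cluster,n_donors,marker_fraction,log_fold_change,covariate_effects
#'   Passed to [simulate_expression()]; clusters are labelled `C01`, `C02`,
#'   ...
#' @param enriched_cluster Label of the cluster whose marker-gene variants
#'   carry the planted heritability (default the first cluster).
#' @param tau Planted per-SNP heritability coefficient of the enriched
#'   annotation.
#' @param N GWAS sample size.
#' @param deg_cell_types,deg_overlap,deg_set_size Passed to
#'   [simulate_perturbation_sets()].
#' @param neurotransmitter_classes,region_labels,dominant_fraction Passed to
#'   [simulate_cluster_metadata()].
#' @return A list of class `synthetic_study`: `panel`, `gene_coords`,
#'   `expression` (list from [simulate_expression()]), `cluster_metadata`,
#'   `annotations` (base + enriched annotation), `sumstats_raw`,
#'   `deg_table`, `truth`.
#' @export
simulate_study <- function(seed = 1L,
                           n_variants = 20000L, n_blocks = 200L,
                           within_block_correlation = 0.5,
                           multiallelic_fraction = 0.01,
                           n_genes = 2000L,
                           n_clusters = 24L, cells_per_cluster = 20L,
                           n_donors = 8L,
                           marker_fraction = 0.04, log_fold_change = 2,
                           covariate_effects = c(age = 0.1, sex = 0.2),
                           enriched_cluster = NULL,
                           tau = 5e-5, N = 50000,
                           deg_cell_types = c("neuron_A", "neuron_B", "nonneuronal"),
                           deg_overlap = 1, deg_set_size = 20L,
                           neurotransmitter_classes = c("GABA", "GLUT"),
                           region_labels = c("PFC", "HIP", "AMY", "THA"),
                           dominant_fraction = 0.8) {
  seed <- as.integer(seed)
  clusters <- sprintf("C%02d", seq_len(check_count(n_clusters, "n_clusters")))
  enriched_cluster <- enriched_cluster %||% clusters[1L]
  if (!enriched_cluster %in% clusters)
    stop_invalid("`enriched_cluster` is not one of the cluster labels")

  panel <- simulate_ld_panel(n_variants, n_blocks,
                             within_block_correlation = within_block_correlation,
                             multiallelic_fraction = multiallelic_fraction,
                             seed = seed)
  gene_coords <- synthetic_gene_coords(panel, n_genes)

  esim <- simulate_expression(n_genes, clusters, cells_per_cluster,
                              marker_fraction = marker_fraction,
                              log_fold_change = log_fold_change,
                              covariate_effects = covariate_effects,
                              n_donors = n_donors, seed = seed + 1L)
  # Gene ids of the expression generator coincide with the coordinate tiling.
  esim$truth$enriched_clusters <- enriched_cluster

  enriched_genes <- esim$truth$marker_genes[[enriched_cluster]]
  annotations <- build_snp_annotations(
    panel, gene_sets = list(enriched = enriched_genes),
    gene_coords = gene_coords, window_kb = 0)

  sumstats_raw <- simulate_gwas_sumstats(panel, annotations,
                                         tau_true = c(enriched = tau),
                                         N = N, seed = seed + 2L)

  cluster_metadata <- simulate_cluster_metadata(
    clusters, neurotransmitter_classes, region_labels,
    dominant_fraction = dominant_fraction, seed = seed + 3L)

  deg_table <- simulate_perturbation_sets(esim$truth, deg_cell_types,
                                          overlap_with_enriched = deg_overlap,
                                          set_size = deg_set_size,
                                          seed = seed + 4L)

  truth <- c(esim$truth,
             list(tau = stats::setNames(tau, "enriched"), N = N,
                  de_genes = attr(deg_table, "perturbed_sets")))
  structure(list(panel = panel, gene_coords = gene_coords,
                 expression = esim, cluster_metadata = cluster_metadata,
                 annotations = annotations, sumstats_raw = sumstats_raw,
                 deg_table = deg_table, truth = truth),
            class = "synthetic_study")
}
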