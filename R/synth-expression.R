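#' Simulate clustered single-cell expression with donor covariates
#'
#' Generates a genes-by-cells matrix on the log2(1 + TPM) scale with a known
#' marker structure: each cluster owns a disjoint set of marker genes whose
#' expression is elevated in that cluster by `log_fold_change` log2 units.
#' Cells are assigned to synthetic donors, and donor age and sex shift
#' expression additively (age enters as `(age - 55) / 10`, sex as a 0/1
#' code), emulating the donor covariates a specificity regression adjusts
#' for. Values are truncated at zero to stay on a valid log-TPM scale.
#'
#' @param n_genes Number of genes.
#' @param clusters Character vector of distinct cluster labels.
#' @param cells_per_cluster Cells simulated per cluster.
#' @param marker_fraction Fraction of all genes used as markers per cluster;
#'   `floor(marker_fraction * n_genes)` must be >= 1 and the marker sets of
#'   all clusters are disjoint.
#' @param log_fold_change Marker elevation in the marker's own cluster,
#'   log2 units.
#' @param covariate_effects Named numeric vector with elements `age` and
#'   `sex`: additive coefficients of the scaled donor covariates.
#' @param n_donors Number of synthetic donors cells are assigned to.
#' @param noise_sd Residual standard deviation of log2 expression.
#' @param seed Integer seed.
#'
#' @return A list with elements `expr` (an [expression_matrix()] on the
#'   `log2_tpm` scale), `covariates` (data frame `donor`, `age`, `sex`), and
#'   `truth` (list with `marker_genes`, a named list per cluster;
#'   `log_fold_change`; `genes`; `seed`).
#' @export
simulate_expression <- function(n_genes, clusters, cells_per_cluster,
                                marker_fraction = 0.01, log_fold_change = 2,
                                covariate_effects = c(age = 0, sex = 0),
                                n_donors = 8, noise_sd = 1, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  cells_per_cluster <- check_count(cells_per_cluster, "cells_per_cluster")
  clusters <- as.character(clusters)
  if (length(clusters) < 1L || anyDuplicated(clusters))
    stop_invalid("`clusters` must be distinct, nonempty labels")
  n_mark <- floor(check_proportion(marker_fraction, "marker_fraction") * n_genes)
  if (n_mark < 1L)
    stop_invalid("`marker_fraction` * `n_genes` must be >= 1")
  if (n_mark * length(clusters) > n_genes)
    stop_invalid("marker sets would exceed the gene universe; lower `marker_fraction`")
  b_age <- unname(covariate_effects["age"] %||% 0); b_age[is.na(b_age)] <- 0
  b_sex <- unname(covariate_effects["sex"] %||% 0); b_sex[is.na(b_sex)] <- 0

  genes <- sprintf("G%05d", seq_len(n_genes))
  n_cells <- cells_per_cluster * length(clusters)
  cell_cluster <- rep(clusters, each = cells_per_cluster)
  cell_id <- sprintf("cell%05d", seq_len(n_cells))

  seeded(seed, {
    perm <- sample.int(n_genes)
    marker_genes <- lapply(seq_along(clusters), function(i) {
      sort(genes[perm[seq.int((i - 1L) * n_mark + 1L, i * n_mark)]])
    })
    names(marker_genes) <- clusters

    donors <- sprintf("D%02d", seq_len(n_donors))
    covariates <- data.frame(
      donor = donors,
      age = sample(30:80, n_donors, replace = TRUE),
      sex = rep_len(c(0L, 1L), n_donors)[sample.int(n_donors)],
      stringsAsFactors = FALSE
    )
    cell_donor <- sample(donors, n_cells, replace = TRUE)

    mu <- stats::rexp(n_genes, rate = 0.5) # right-skewed baseline log2 means
    vals <- matrix(stats::rnorm(n_genes * n_cells, sd = noise_sd),
                   n_genes, n_cells, dimnames = list(genes, cell_id))
    vals <- vals + mu
    for (cl in clusters) {
      in_cl <- cell_cluster == cl
      vals[marker_genes[[cl]], in_cl] <-
        vals[marker_genes[[cl]], in_cl] + log_fold_change
    }
    age_z <- (covariates$age[match(cell_donor, donors)] - 55) / 10
    sex_c <- covariates$sex[match(cell_donor, donors)]
    vals <- vals + rep(b_age * age_z + b_sex * sex_c, each = n_genes)
    vals <- pmax(vals, 0)

    expr <- expression_matrix(vals,
                              cluster = stats::setNames(cell_cluster, cell_id),
                              donor = stats::setNames(cell_donor, cell_id),
                              scale = "log2_tpm")
    list(expr = expr, covariates = covariates,
         truth = list(marker_genes = marker_genes,
                      log_fold_change = log_fold_change,
                      genes = genes, seed = as.integer(seed)))
  })
}

#' Simulate cluster-level metadata (neurotransmitter class, region mixture)
#'
#' Assigns each cluster one neurotransmitter class and a per-region
#' cell-fraction vector: the dominant region receives `dominant_fraction`
#' and the remainder is split equally among the other regions, so the
#' fractions sum to one by construction.
#'
#' @param clusters Cluster labels (distinct, nonempty).
#' @param neurotransmitter_classes Labels to draw the per-cluster class from.
#' @param region_labels Region labels for the fraction vector.
#' @param dominant_fraction Fraction of each cluster's cells assigned to its
#'   dominant region, in `(0, 1]`.
#' @param seed Integer seed.
#'
#' @return A `cluster_annotation` data frame: `cluster`, `neurotransmitter`,
#'   `assigned_region` (by the strict majority rule, see [assign_region()]),
#'   and one `frac_<region>` column per region.
#' @export
simulate_cluster_metadata <- function(clusters, neurotransmitter_classes,
                                      region_labels, dominant_fraction = 0.8,
                                      seed = 1L) {
  clusters <- as.character(clusters)
  neurotransmitter_classes <- as.character(neurotransmitter_classes)
  region_labels <- as.character(region_labels)
  if (!length(clusters) || !length(neurotransmitter_classes) || !length(region_labels))
    stop_invalid("cluster, neurotransmitter and region label sets must be nonempty")
  if (anyDuplicated(clusters)) stop_invalid("`clusters` must be distinct")
  df <- check_proportion(dominant_fraction, "dominant_fraction")
  if (df == 0) stop_invalid("`dominant_fraction` must be in (0, 1]")

  seeded(seed, {
    nt <- sample(neurotransmitter_classes, length(clusters), replace = TRUE)
    dom <- sample(region_labels, length(clusters), replace = TRUE)
    fr <- matrix(0, length(clusters), length(region_labels),
                 dimnames = list(clusters, region_labels))
    for (i in seq_along(clusters)) {
      others <- setdiff(region_labels, dom[i])
      fr[i, dom[i]] <- df
      if (length(others)) fr[i, others] <- (1 - df) / length(others)
    }
    assigned <- apply(fr, 1L, function(f) assign_region(f))
    out <- data.frame(cluster = clusters, neurotransmitter = nt,
                      assigned_region = unname(assigned),
                      stringsAsFactors = FALSE)
    colnames(fr) <- paste0("frac_", region_labels)
    out <- cbind(out, as.data.frame(fr, row.names = NULL))
    class(out) <- c("cluster_annotation", "data.frame")
    out
  })
}

#' Simulate perturbation (DEG/DAR) tables with known ground truth
#'
#' Builds a differential-expression-style table per cell type: `set_size`
#' "perturbed" genes with FDR values below the selection cut, of which a
#' stated proportion is drawn from the genes of enriched-cluster marker sets
#' (i.e. genes whose variants carry planted heritability), plus an equal
#' number of decoy rows with FDR above the cut so that downstream filtering
#' is exercised.
#'
#' @param truth Truth list from [simulate_expression()] (or the `truth`
#'   element of [simulate_study()]), providing `genes`, `marker_genes` and,
#'   if available, `enriched_clusters`.
#' @param cell_types Labels of the perturbed cell types.
#' @param overlap_with_enriched Proportion of each set drawn from
#'   enriched-cluster marker genes, in `[0, 1]`.
#' @param set_size Perturbed genes per cell type (>= 1).
#' @param fdr_cut Selection threshold the synthetic FDR values straddle.
#' @param seed Integer seed.
#'
#' @return Data frame with columns `gene`, `cell_type`, `log_fold_change`,
#'   `fdr`; attribute `perturbed_sets` holds the true per-cell-type sets.
#' @export
simulate_perturbation_sets <- function(truth, cell_types,
                                       overlap_with_enriched = 1,
                                       set_size = 20, fdr_cut = 0.01,
                                       seed = 1L) {
  overlap_with_enriched <- check_proportion(overlap_with_enriched,
                                            "overlap_with_enriched")
  set_size <- check_count(set_size, "set_size")
  cell_types <- as.character(cell_types)
  genes <- truth$genes
  if (is.null(genes)) stop_invalid("`truth` must carry the gene universe in `genes`")
  if (set_size > length(genes)) stop_invalid("`set_size` exceeds the gene universe")
  enriched <- truth$enriched_clusters %||% character(0)
  enriched_genes <- sort(unique(unlist(truth$marker_genes[enriched])))
  background <- setdiff(genes, enriched_genes)

  seeded(seed, {
    rows <- lapply(cell_types, function(ct) {
      n_enr <- min(round(overlap_with_enriched * set_size), length(enriched_genes))
      picked <- c(if (n_enr > 0) sample(enriched_genes, n_enr),
                  sample(background, set_size - n_enr))
      decoys <- sample(setdiff(genes, picked), min(set_size, length(genes) - set_size))
      data.frame(
        gene = c(picked, decoys),
        cell_type = ct,
        log_fold_change = stats::rnorm(length(picked) + length(decoys), sd = 1.5),
        fdr = c(stats::runif(length(picked), 0, fdr_cut * 0.9),
                stats::runif(length(decoys), fdr_cut * 5, 0.5)),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    attr(out, "perturbed_sets") <- stats::setNames(
      lapply(rows, function(r) sort(r$gene[r$fdr < fdr_cut])), cell_types)
    out
  })
}
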