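#' Pipeline configuration
#'
#' Builds the validated configuration for [run_pipeline()]. Unknown keys
#' are rejected; defaults are resolved here so that the effective
#' configuration written alongside the outputs is complete. The defaults
#' match the package's reference synthetic study (see the methods
#' vignette); paper-scale runs typically raise `top_k` to 1000 and
#' `window_kb` to 100.
#'
#' @param bundle_dir Directory holding a fixture bundle (see
#'   [write_fixture_bundle()]); the pipeline's input.
#' @param out_dir Output directory for result tables and the report; `NULL`
#'   keeps results in memory only.
#' @param seed Seed used by every stochastic stage (GSEA permutations).
#' @param top_k Genes per cluster retained for the specificity gene sets.
#' @param window_kb Gene-span extension for SNP annotations, kb.
#' @param n_jackknife_blocks Jackknife blocks for the stratified regression.
#' @param fdr_alpha FDR significance threshold used throughout.
#' @param families Optional named vector mapping clusters to FDR families.
#' @param gsea_permutations Permutations for [preranked_gsea()].
#' @param deg_fdr_cut Differential FDR cut for perturbed-set enrichment.
#' @param gene_sig_cut Gene-association FDR cut for the overlap report.
#' @param overrep_universe `"all"` scored clusters, or `"annotated"` to
#'   restrict the hypergeometric universe to clusters with a
#'   neurotransmitter annotation.
#' @param stages Named logical vector toggling `specificity`, `sldsc`,
#'   `magma`, `concordance`, `overrep`, `heritability`, `gsea`,
#'   `perturbed`.
#' @param cache When TRUE and a report with the same configuration hash
#'   already exists in `out_dir`, reload it instead of recomputing.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(bundle_dir,
                            out_dir = NULL,
                            seed = 1L,
                            top_k = 80L,
                            window_kb = 0,
                            n_jackknife_blocks = 200L,
                            fdr_alpha = 0.05,
                            families = NULL,
                            gsea_permutations = 200L,
                            deg_fdr_cut = 0.01,
                            gene_sig_cut = 0.05,
                            overrep_universe = c("all", "annotated"),
                            stages = NULL,
                            cache = FALSE) {
  default_stages <- c(specificity = TRUE, sldsc = TRUE, magma = TRUE,
                      concordance = TRUE, overrep = TRUE,
                      heritability = TRUE, gsea = TRUE, perturbed = TRUE)
  if (!is.null(stages)) {
    unknown <- setdiff(names(stages), names(default_stages))
    if (length(unknown))
      stop_invalid("unknown stage(s): ", paste(unknown, collapse = ", "))
    default_stages[names(stages)] <- stages
  }
  cfg <- list(bundle_dir = bundle_dir, out_dir = out_dir,
              seed = as.integer(seed), top_k = check_count(top_k, "top_k"),
              window_kb = window_kb,
              n_jackknife_blocks = check_count(n_jackknife_blocks,
                                               "n_jackknife_blocks", min = 2L),
              fdr_alpha = check_proportion(fdr_alpha, "fdr_alpha"),
              families = families,
              gsea_permutations = check_count(gsea_permutations,
                                              "gsea_permutations", min = 100L),
              deg_fdr_cut = check_proportion(deg_fdr_cut, "deg_fdr_cut"),
              gene_sig_cut = check_proportion(gene_sig_cut, "gene_sig_cut"),
              overrep_universe = match.arg(overrep_universe),
              stages = default_stages, cache = isTRUE(cache))
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$cache <- NULL
  fnv1a_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"))
}

#' Load and validate the pipeline inputs
#'
#' Reads the fixture bundle named by the configuration through the format
#' readers (schema checks, chromosome-name normalization, Z/P consistency
#' checks, BED validation) and returns the in-memory tables.
#'
#' @param config A [pipeline_config()].
#' @return List of validated inputs (see [load_fixture_bundle()]).
#' @export
load_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$bundle_dir))
    stop_invalid("bundle directory not found: ", config$bundle_dir)
  load_fixture_bundle(config$bundle_dir)
}

#' Run the full cell-type heritability pipeline
#'
#' Executes the stages in dependency order: expression transform and
#' specificity regression, top-K gene sets, SNP annotations, LD scores and
#' the conditional cell-type heritability scan; positional gene mapping,
#' gene-level association, and the gene-property scan; dual-method
#' concordance; hypergeometric over-representation against
#' neurotransmitter and region annotations; gene-level heritability and
#' pre-ranked GSEA of the cluster gene sets; and QQ-slope enrichment of
#' the perturbed (DEG) sets. With `out_dir` set, result tables and a JSON
#' report are written; with `cache = TRUE` and an existing report whose
#' configuration hash matches, all stages are skipped and the report
#' reloaded.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list: `version`, `seed`, `config`,
#'   `config_hash`, `counts` (per-stage record counts and filter tallies),
#'   and the result tables (`scan`, `property`, `concordance_sizes`,
#'   `overrep_nt`, `overrep_region`, `herit`, `gsea`, `lambda`,
#'   `overlap_genes`), plus `wall_time_s`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  if (st[["concordance"]] && !(st[["sldsc"]] && st[["magma"]]))
    stop_invalid("concordance stage requires both sldsc and magma stages")
  if (st[["gsea"]] && !st[["heritability"]])
    stop_invalid("gsea stage requires the heritability stage")
  hash <- config_hash(config)
  if (config$cache && !is.null(config$out_dir)) {
    rp <- file.path(config$out_dir, "report.json")
    if (file.exists(rp)) {
      prev <- jsonlite::read_json(rp, simplifyVector = TRUE)
      if (identical(prev$config_hash, hash)) {
        message("configuration unchanged; reloading cached report")
        return(structure(prev, cached = TRUE, class = "run_report"))
      }
    }
  }
  t0 <- proc.time()[["elapsed"]]
  inputs <- load_inputs(config)
  counts <- list()
  report <- list(version = pkg_version(), seed = config$seed,
                 config = unclass(config), config_hash = hash)

  ss <- harmonize_and_filter_sumstats(
    inputs$sumstats_raw, mhc_interval = inputs$panel$mhc_interval)
  counts$sumstats_filter <- attr(ss, "filter_report")

  spec <- sets <- expr_log <- NULL
  if (st[["specificity"]]) {
    expr_log <- transform_and_aggregate(inputs$expr)
    spec <- specificity_regression(expr_log, covariates = inputs$covariates)
    sets <- top_k_gene_sets(spec, k = config$top_k)
    counts$specificity <- c(n_genes = nrow(expr_log$values),
                            n_clusters = length(sets))
  }

  scan <- NULL
  if (st[["sldsc"]]) {
    if (is.null(sets)) stop_invalid("sldsc stage requires the specificity stage")
    ann <- build_snp_annotations(inputs$panel, gene_sets = sets,
                                 gene_coords = inputs$gene_coords,
                                 window_kb = config$window_kb)
    scan <- celltype_heritability_scan(
      ss, inputs$panel, ann, families = config$families,
      n_jackknife_blocks = config$n_jackknife_blocks,
      fdr_alpha = config$fdr_alpha)
    counts$sldsc <- c(n_clusters = nrow(scan),
                      n_significant = sum(scan$significant))
    report$scan <- as.data.frame(scan)
  }

  mapping <- gene_assoc <- prop <- NULL
  if (st[["magma"]]) {
    mapping <- map_snps_to_genes(ss, inputs$gene_coords,
                                 mhc_interval = inputs$panel$mhc_interval)
    gene_assoc <- gene_association(ss, mapping, panel = inputs$panel)
    if (is.null(spec)) stop_invalid("magma stage requires the specificity stage")
    avg_expr <- rowMeans(expr_log$values)
    prop <- gene_property_scan(gene_assoc, spec, avg_expr)
    counts$magma <- c(n_genes_mapped = length(mapping$genes),
                      n_significant = sum(prop$q < config$fdr_alpha,
                                          na.rm = TRUE))
    report$property <- as.data.frame(prop)
    report$gene_assoc <- as.data.frame(gene_assoc)
  }

  if (st[["concordance"]]) {
    conc <- concordance_intersect(scan, prop, alpha = config$fdr_alpha)
    counts$concordance <- conc$sizes
    report$concordance <- conc$table
    report$concordance_sizes <- as.list(conc$sizes)
    report$concordant_clusters <-
      conc$table$cluster[conc$table$concordant]
  }

  if (st[["overrep"]] && !is.null(scan) && !is.null(inputs$cluster_metadata)) {
    md <- inputs$cluster_metadata
    universe <- if (config$overrep_universe == "annotated")
      md$cluster[!is.na(md$neurotransmitter)] else scan$cluster
    sig <- intersect(scan$cluster[scan$significant], universe)
    nt_cats <- split(md$cluster, md$neurotransmitter)
    nt_cats <- lapply(nt_cats, intersect, universe)
    report$overrep_nt <- hypergeom_overrep(sig, nt_cats, universe)
    if ("assigned_region" %in% names(md) && any(!is.na(md$assigned_region))) {
      rg <- md[!is.na(md$assigned_region), ]
      rg_cats <- lapply(split(rg$cluster, rg$assigned_region),
                        intersect, universe)
      report$overrep_region <- hypergeom_overrep(sig, rg_cats, universe)
    }
    counts$overrep <- c(n_significant = length(sig),
                        n_categories = length(nt_cats))
  }

  herit <- NULL
  if (st[["heritability"]]) {
    if (is.null(mapping))
      mapping <- map_snps_to_genes(ss, inputs$gene_coords,
                                   mhc_interval = inputs$panel$mhc_interval)
    herit <- gene_heritability_test(ss, mapping, inputs$panel)
    counts$heritability <- c(n_genes = nrow(herit),
                             n_significant = sum(herit$q < config$fdr_alpha))
    report$herit <- as.data.frame(herit)
  }

  if (st[["gsea"]]) {
    if (is.null(sets)) stop_invalid("gsea stage requires the specificity stage")
    ranking <- stats::setNames(herit$z, herit$gene)
    report$gsea <- preranked_gsea(ranking, sets,
                                  n_permutations = config$gsea_permutations,
                                  seed = config$seed)
    counts$gsea <- c(n_sets = nrow(report$gsea))
  }

  if (st[["perturbed"]] && !is.null(inputs$deg_table)) {
    if (is.null(gene_assoc)) stop_invalid("perturbed stage requires the magma stage")
    pert <- perturbed_set_enrichment(inputs$deg_table, gene_assoc,
                                     fdr_cut = config$deg_fdr_cut,
                                     gene_sig_cut = config$gene_sig_cut)
    report$lambda <- pert$lambda_table
    report$overlap_genes <- pert$overlap_genes
    counts$perturbed <- c(n_cell_types = nrow(pert$lambda_table))
  }

  report$counts <- counts
  report$wall_time_s <- round(proc.time()[["elapsed"]] - t0, 3)
  report <- structure(report, class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a run report and its result tables
#'
#' Emits tab-separated result tables (one per stage, each headed by a
#' comment line with the package version and configuration hash) and a
#' machine-readable JSON report at full numeric precision. The concordance
#' size identity |union| = |A| + |B| - |A&B| is re-verified before
#' writing.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param format `"tsv_bundle"` (tables + JSON, default) or `"json"` (JSON
#'   only).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, format = c("tsv_bundle", "json")) {
  format <- match.arg(format)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop_invalid("cannot create directory ", dir)
  if (!is.null(report$concordance_sizes)) {
    s <- report$concordance_sizes
    stopifnot(s$n_union == s$n_a + s$n_b - s$n_intersect)
  }
  stamp <- sprintf("scherit %s config=%s", report$version, report$config_hash)
  written <- character(0)
  if (format == "tsv_bundle") {
    tables <- c("scan", "property", "gene_assoc", "concordance", "overrep_nt",
                "overrep_region", "herit", "gsea", "lambda", "overlap_genes")
    for (nm in tables) {
      if (is.null(report[[nm]])) next
      f <- file.path(dir, paste0(nm, ".tsv"))
      write_tsv(as.data.frame(report[[nm]]), f, comment = stamp)
      written <- c(written, f)
    }
  }
  f <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), f, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  written <- c(written, f)
  invisible(written)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (scherit %s, seed %d, config %s)\n",
              x$version, x$seed, x$config_hash))
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    if (is.data.frame(v)) v <- stats::setNames(v$n, v$step)
    cat(sprintf("  %-16s %s\n", nm,
                paste(names(v), unlist(v), sep = "=", collapse = ", ")))
  }
  invisible(x)
}
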