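# End-to-end orchestration: configuration, stage sequencing (QC -> impute
# -> PCA -> screen -> graph -> classify -> validate), intermediate tables,
# and a JSON manifest. Every stage draws its randomness from the global
# seed plus a fixed stage offset, so a rerun with the same configuration
# reproduces every output bit-for-bit.

#' Pipeline configuration
#'
#' Stage parameters default to the study protocol: call-rate threshold 0.10,
#' MAF threshold 0.05, 10 genotype PCs, 100 screening repetitions with
#' 5-fold cross-fitting at P < 1e-4, Fisher-Z level 0.05.
#'
#' @param geno path to the dosage TSV/CSV (or VCF, by extension).
#' @param pheno path to the phenotype table.
#' @param out_dir output directory.
#' @param trait trait column name in the phenotype table.
#' @param max_missing,min_maf QC thresholds.
#' @param n_pcs number of PCs.
#' @param n_rep,n_folds,p_thresh,stability_pi screening settings.
#' @param alpha,max_cond structure-learning settings.
#' @param ancestral_include_undirected traverse undirected edges during
#'   ancestral pruning so unoriented upstream regulators are retained
#'   (the pipeline default; see the methods vignette).
#' @param residualize_graph regress each selected marker on the genotype PCs
#'   before structure learning (the pipeline default): with a
#'   structure-linked confounder, raw-dosage marginal dependencies can be
#'   masked or inflated, violating the causal-sufficiency premise of the
#'   constraint-based search.
#' @param uhs_min_out_degree hub threshold.
#' @param n_random_draws random panels in the validation stage.
#' @param seed global seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(geno = NULL, pheno = NULL, out_dir = "snpdag_out",
                            trait = "trait", max_missing = 0.10,
                            min_maf = 0.05, n_pcs = 10L, n_rep = 100L,
                            n_folds = 5L, p_thresh = 1e-4,
                            stability_pi = 0.8, alpha = 0.05, max_cond = 3L,
                            ancestral_include_undirected = TRUE,
                            residualize_graph = TRUE,
                            uhs_min_out_degree = 2L, n_random_draws = 20L,
                            seed = 1L) {
  structure(list(geno = geno, pheno = pheno, out_dir = out_dir,
                 trait = trait, max_missing = max_missing, min_maf = min_maf,
                 n_pcs = as.integer(n_pcs), n_rep = as.integer(n_rep),
                 n_folds = as.integer(n_folds), p_thresh = p_thresh,
                 stability_pi = stability_pi, alpha = alpha,
                 max_cond = as.integer(max_cond),
                 ancestral_include_undirected =
                   isTRUE(ancestral_include_undirected),
                 residualize_graph = isTRUE(residualize_graph),
                 uhs_min_out_degree = as.integer(uhs_min_out_degree),
                 n_random_draws = as.integer(n_random_draws),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

stage_banner <- function(name, ...) {
  message(sprintf("[snpdag] %-9s %s", name, sprintf(...)))
}

#' Run the full discovery pipeline
#'
#' Executes QC, imputation, PCA, the stability-selected DML screen, causal
#' graph learning over the selected markers, role classification with edge
#' weights, and predictive validation; writes every intermediate table
#' under `config$out_dir` plus a JSON manifest of parameters, seeds and
#' per-stage counts.
#'
#' @param config a [pipeline_config()].
#' @param dosages,phenotype optional in-memory inputs (bypass the path
#'   readers); `phenotype` is a named vector or a data.frame with
#'   `genotype_id` and the trait column.
#' @return invisibly, a list with every stage result and the manifest.
#' @export
run_all <- function(config, dosages = NULL, phenotype = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(config$out_dir, ...)

  if (is.null(dosages)) {
    if (is.null(config$geno)) stopf("no genotype input")
    dosages <- if (grepl("\\.vcf(\\.gz)?$", config$geno))
      read_dosage_vcf(config$geno) else read_dosage(config$geno)
  }
  if (is.null(phenotype)) {
    if (is.null(config$pheno)) stopf("no phenotype input")
    ph <- read_phenotype(config$pheno)
    if (all(c("row", "column") %in% names(ph))) {
      stage_banner("blup", "spatial row/column adjustment of plot values")
      sa <- spatial_adjust(ph, value = config$trait)
      phenotype <- sa$blups
      data.table::fwrite(data.table::data.table(
        genotype_id = names(phenotype), blup = as.numeric(phenotype)),
        pth("blups.tsv"), sep = "\t")
    } else {
      if (!config$trait %in% names(ph))
        stopf("trait column '%s' not found", config$trait)
      phenotype <- stats::setNames(ph[[config$trait]], ph$genotype_id)
    }
  }
  if (is.data.frame(phenotype))
    phenotype <- stats::setNames(phenotype[[config$trait]],
                                 phenotype$genotype_id)
  common <- intersect(rownames(dosages), names(phenotype))
  if (!length(common)) stopf("no individuals shared by genotypes and phenotype")
  dosages <- dosages[common, , drop = FALSE]
  phenotype <- phenotype[common]

  stage_banner("qc", "call-rate > %.2f then MAF < %.2f on %d markers",
               config$max_missing, config$min_maf, ncol(dosages))
  qc <- qc_filter(dosages, config$max_missing, config$min_maf)
  data.table::fwrite(data.table::data.table(
    marker_id = names(qc$report$maf),
    call_rate = qc$report$call_rate[names(qc$report$maf)],
    maf = qc$report$maf,
    removed = names(qc$report$maf) %in%
      c(qc$report$removed_call_rate, qc$report$removed_maf)),
    pth("qc_report.tsv"), sep = "\t")

  stage_banner("impute", "mean imputation of %d x %d matrix",
               nrow(qc$dosages), ncol(qc$dosages))
  ximp <- impute_mean(qc$dosages)

  stage_banner("pca", "top %d genotype principal components", config$n_pcs)
  pcs <- compute_pcs(ximp, k = config$n_pcs)
  data.table::fwrite(cbind(
    data.table::data.table(genotype_id = rownames(pcs$scores)),
    data.table::as.data.table(pcs$scores)), pth("pc_scores.tsv"), sep = "\t")

  stage_banner("screen", "%d reps x %d-fold DML over %d markers",
               config$n_rep, config$n_folds, ncol(ximp))
  scfg <- screen_config(n_rep = config$n_rep, n_folds = config$n_folds,
                        p_thresh = config$p_thresh,
                        stability_pi = config$stability_pi,
                        n_pcs = config$n_pcs, seed = config$seed + 100L)
  screen <- run_screen(ximp, phenotype, pcs, scfg)
  data.table::fwrite(screen, pth("screening.tsv"), sep = "\t", na = "NA")
  screening_report(screen, out_dir = pth("plots"))
  selected <- screen$marker_id[screen$selected]
  stage_banner("screen", "%d markers selected (stability >= %.2f)",
               length(selected), config$stability_pi)

  graph <- NULL; roles <- NULL; ew <- NULL; report <- NULL
  if (length(selected) >= 1L) {
    stage_banner("graph", "PC-stable over %d nodes, alpha = %.3g, max |S| = %d",
                 length(selected) + 1L, config$alpha, config$max_cond)
    gdata <- cbind(ximp[, selected, drop = FALSE],
                   stats::setNames(data.frame(phenotype), config$trait))
    gdata <- as.matrix(gdata)
    graph <- learn_graph(gdata, config$trait, alpha = config$alpha,
                         max_cond = config$max_cond,
                         include_undirected =
                           config$ancestral_include_undirected,
                         residualize = config$residualize_graph,
                         covariates = if (config$residualize_graph)
                           pcs$scores else NULL)
    stage_banner("classify", "roles and edge weights over %d retained nodes",
                 length(graph$nodes))
    roles <- classify_roles(graph, config$trait,
                            uhs_min_out_degree = config$uhs_min_out_degree)
    ew <- edge_weights(graph, gdata, roles)
    roles <- ew$roles
    data.table::fwrite(roles, pth("roles.tsv"), sep = "\t", na = "NA")
    write_graphml(graph, pth("graph.graphml"), roles, ew$weights)
    write_edgelist(graph, pth("graph_edges.tsv"), ew$weights)
    write_dot(graph, pth("graph.dot"))
    data.table::fwrite(concentric_layout(roles, config$trait),
                       pth("layout.tsv"), sep = "\t")
    if (any(roles$role == "DPS")) {
      stage_banner("validate", "out-of-fold R2 of DPS/UHS/random panels")
      report <- compare_feature_sets(
        ximp, phenotype, roles, graph,
        n_random_draws = config$n_random_draws,
        seed = config$seed + 500L, full_selected = selected,
        trait_label = config$trait)
      data.table::fwrite(report, pth("validation.tsv"), sep = "\t", na = "NA")
    } else stage_banner("validate", "skipped: no direct parents found")
  } else stage_banner("graph", "skipped: no markers selected")

  manifest <- list(
    package = "snpdag",
    version = as.character(utils::packageVersion("snpdag")),
    seed = config$seed,
    parameters = unclass(config),
    counts = list(
      individuals = nrow(ximp),
      markers_in = qc$report$n_markers_in,
      markers_removed_call_rate = qc$report$n_removed_call_rate,
      markers_removed_maf = qc$report$n_removed_maf,
      markers_qc = qc$report$n_markers_out,
      markers_screened = nrow(screen),
      markers_selected = length(selected),
      graph_nodes = if (is.null(graph)) 0L else length(graph$nodes),
      graph_edges = if (is.null(graph)) 0L else nrow(cpdag_edges(graph)),
      dps = if (is.null(roles)) 0L else sum(roles$role == "DPS"),
      uhs = if (is.null(roles)) 0L else sum(roles$role == "UHS")))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(qc = qc, dosages = ximp, pcs = pcs, screen = screen,
                 graph = graph, roles = roles, edge_weights = ew,
                 validation = report, manifest = manifest))
}
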