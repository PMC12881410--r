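#' Simulation configuration for a synthetic autotetraploid cohort
#'
#' Defines the study conditions emulated by the simulator: an admixed panel of
#' autotetraploid individuals genotyped at allele-dosage markers (0-4), with
#' local LD blocks, a small set of markers directly affecting the trait, hub
#' markers acting only through mediator markers, and an ancestry-linked
#' confounder contributing to the trait.
#'
#' Defaults mirror the regime the package targets: 500 individuals, 2,000
#' markers in two admixed subpopulations, five direct-parent markers with
#' per-dosage effect 0.25 (single-test power near 0.9 at P < 1e-4 under unit
#' residual noise), two hubs each driving two mediators, and a unit ancestry
#' effect on the trait.
#'
#' @param n_individuals number of individuals.
#' @param n_markers number of dosage markers.
#' @param n_subpops number of ancestral subpopulations.
#' @param admixture_conc Dirichlet concentration of individual ancestry
#'   proportions; small values give near-discrete subpopulations.
#' @param diff_frac fraction of markers whose ancestral allele frequencies are
#'   drawn independently per subpopulation (differentiated markers).
#' @param ld_block_size number of consecutive markers per LD block.
#' @param ld_copy_prob probability that a (non-leading) marker inside a block
#'   copies its predecessor's latent allele frequencies, plus jitter.
#' @param ld_jitter_sd standard deviation of the frequency jitter applied when
#'   copying within an LD block.
#' @param n_direct_parents number of (non-mediator) markers with a direct
#'   effect on the trait.
#' @param n_hubs number of hub markers; hubs influence the trait only through
#'   their mediators.
#' @param mediators_per_hub mediators regenerated per hub.
#' @param mediators_are_parents if `TRUE` (default) mediators also carry a
#'   direct effect on the trait, so hubs are trait ancestors at distance >= 2.
#' @param beta_parent absolute per-dosage-unit trait effect of each direct
#'   parent (signs are drawn at random per parent — coherently for the
#'   mediators of one hub — and recorded in the truth object).
#' @param plant_maf_min minimum observed MAF for a marker to be eligible as
#'   a planted parent/hub/mediator, default 0.2: effects sit on common
#'   variants whose dosage variance supports the intended detection power.
#' @param beta_confounder effect of the ancestry score (proportion of
#'   subpopulation 1) on the trait.
#' @param hub_transfer latent-scale strength of the hub to mediator
#'   dependence, in (0, 1). The default 0.7 balances two competing powers:
#'   the hub's marginal detectability (rises with the transfer) against the
#'   mediator's conditional signal given its hub (falls with it).
#' @param noise_sd residual standard deviation of the trait.
#' @param missing_rate completely-at-random genotype missingness probability.
#' @param trait_name name of the trait node in graphs and tables.
#' @param seed integer seed; the entire cohort is reproducible bit-for-bit.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 500L, n_markers = 2000L,
                       n_subpops = 2L, admixture_conc = 0.5, diff_frac = 0.5,
                       ld_block_size = 10L, ld_copy_prob = 0.8,
                       ld_jitter_sd = 0.02,
                       n_direct_parents = 5L, n_hubs = 2L,
                       mediators_per_hub = 2L, mediators_are_parents = TRUE,
                       beta_parent = 0.35, plant_maf_min = 0.2,
                       beta_confounder = 1,
                       hub_transfer = 0.7, noise_sd = 1,
                       missing_rate = 0.02, trait_name = "trait", seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_markers = as.integer(n_markers),
              n_subpops = as.integer(n_subpops),
              admixture_conc = admixture_conc, diff_frac = diff_frac,
              ld_block_size = as.integer(ld_block_size),
              ld_copy_prob = ld_copy_prob, ld_jitter_sd = ld_jitter_sd,
              n_direct_parents = as.integer(n_direct_parents),
              n_hubs = as.integer(n_hubs),
              mediators_per_hub = as.integer(mediators_per_hub),
              mediators_are_parents = isTRUE(mediators_are_parents),
              beta_parent = beta_parent, plant_maf_min = plant_maf_min,
              beta_confounder = beta_confounder,
              hub_transfer = hub_transfer, noise_sd = noise_sd,
              missing_rate = missing_rate, trait_name = trait_name,
              seed = as.integer(seed))
  counts <- cfg[c("n_individuals", "n_markers", "n_subpops",
                  "n_direct_parents", "n_hubs", "mediators_per_hub")]
  if (any(vapply(counts, function(v) is.na(v) || v < 0L, logical(1))))
    stopf("counts must be non-negative integers")
  if (cfg$n_individuals < 1L || cfg$n_markers < 1L || cfg$n_subpops < 1L)
    stopf("n_individuals, n_markers and n_subpops must be positive")
  planted <- cfg$n_direct_parents + cfg$n_hubs * (1L + cfg$mediators_per_hub)
  if (planted > cfg$n_markers)
    stopf("planted markers (%d) exceed n_markers (%d)", planted, cfg$n_markers)
  for (p in c("diff_frac", "ld_copy_prob", "missing_rate"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("%s must lie in [0, 1]", p)
  if (cfg$hub_transfer < 0 || cfg$hub_transfer >= 1)
    stopf("hub_transfer must lie in [0, 1)")
  if (cfg$noise_sd < 0 || cfg$admixture_conc <= 0)
    stopf("noise_sd must be >= 0 and admixture_conc > 0")
  structure(cfg, class = "sim_config")
}

# marker IDs chr{c}.1_{pos}: markers split over 8 chromosomes contiguously,
# positions strictly increasing within a chromosome
sim_marker_ids <- function(m, n_chrom = 8L) {
  chrom <- rep(seq_len(n_chrom), each = ceiling(m / n_chrom))[seq_len(m)]
  pos <- unlist(lapply(split(seq_len(m), chrom),
                       function(ix) seq_along(ix) * 1371L + 100L),
                use.names = FALSE)
  sprintf("chr%d.1_%d", chrom, pos)
}

#' Simulate autotetraploid allele-dosage genotypes
#'
#' Ancestral allele frequencies are drawn per subpopulation (Beta(0.5, 0.5),
#' independently per subpopulation for a `diff_frac` fraction of markers and
#' shared otherwise). Within LD blocks, a marker copies its predecessor's
#' frequencies with probability `ld_copy_prob` (plus Gaussian jitter), so
#' adjacent markers are correlated. Individual ancestry proportions follow a
#' symmetric Dirichlet; each dosage is Binomial(4, p) with p the
#' ancestry-weighted allele frequency. Missing calls are inserted completely
#' at random.
#'
#' @param config a [sim_config()].
#' @return list with `dosages` (individuals x markers, `NA` for missing),
#'   `subpop_labels` (modal ancestry component per individual), and
#'   `ancestry` (individuals x subpopulations Dirichlet proportions).
#' @export
simulate_genotypes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals; m <- config$n_markers; k <- config$n_subpops
  with_seed(config$seed, {
    freqs <- matrix(0, k, m)
    for (j in seq_len(m)) {
      in_block <- config$ld_block_size > 1L &&
        (j - 1L) %% config$ld_block_size != 0L
      if (in_block && stats::runif(1) < config$ld_copy_prob) {
        freqs[, j] <- pmin(pmax(freqs[, j - 1L] +
          stats::rnorm(k, 0, config$ld_jitter_sd), 0.01), 0.99)
      } else if (stats::runif(1) < config$diff_frac) {
        freqs[, j] <- stats::rbeta(k, 0.5, 0.5)
      } else {
        freqs[, j] <- rep(stats::rbeta(1, 0.5, 0.5), k)
      }
    }
    q <- matrix(stats::rgamma(n * k, shape = config$admixture_conc), n, k)
    # guard against all-zero gamma draws at tiny concentrations
    q[rowSums(q) == 0, ] <- 1
    q <- q / rowSums(q)
    p <- q %*% freqs
    d <- matrix(stats::rbinom(n * m, 4L, p), n, m)
    if (config$missing_rate > 0)
      d[matrix(stats::runif(n * m) < config$missing_rate, n, m)] <- NA_integer_
    dimnames(d) <- list(sprintf("ind%04d", seq_len(n)), sim_marker_ids(m))
    rownames(q) <- rownames(d)
    list(dosages = d, subpop_labels = max.col(q, ties.method = "first"),
         ancestry = q, freqs = freqs)
  })
}

# replace the non-missing entries of `new_latent`'s marker by a rank-matched
# permutation of the original non-missing dosages (marginal preserved exactly)
rank_match <- function(orig, latent) {
  out <- orig
  obs <- which(!is.na(orig))
  out[obs][order(latent[obs])] <- sort(orig[obs])
  out
}

#' Simulate a trait with planted causal architecture
#'
#' Selects disjoint parent, hub and mediator markers (among markers common
#' enough to survive quality control: observed MAF >= 0.1). Each mediator's
#' dosages are regenerated as a noisy monotone function of its hub: a latent
#' Gaussian `z = hub_transfer * std(hub) + sqrt(1 - hub_transfer^2) * eps` is
#' mapped back to dosages by rank-matching against the mediator's original
#' values, so the hub-mediator dependence is planted while the mediator's
#' marginal dosage distribution is preserved exactly. The trait is the sum of
#' direct-parent effects (mediators included when
#' `mediators_are_parents = TRUE`), an ancestry confounder, and Gaussian
#' noise.
#'
#' @param dosages dosage matrix from [simulate_genotypes()] (missing allowed;
#'   means are imputed internally for trait construction).
#' @param subpop_labels per-individual subpopulation labels.
#' @param config a [sim_config()].
#' @param ancestry optional individuals x subpopulations ancestry matrix; its
#'   first column is the continuous confounder score. Falls back to the
#'   indicator of subpopulation 1.
#' @return list with `phenotype` (named vector), `dosages` (with mediator
#'   columns regenerated), and `truth` (a `sim_truth` object: parent/hub ids,
#'   mediator map, signed effects, the trait DAG edge list, the confounder
#'   score used).
#' @export
simulate_trait <- function(dosages, subpop_labels, config = sim_config(),
                           ancestry = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_dosages(dosages)
  n <- nrow(dosages)
  ids <- colnames(dosages)
  anc <- if (!is.null(ancestry)) ancestry[, 1] else as.numeric(subpop_labels == 1L)
  n_med <- config$n_hubs * config$mediators_per_hub
  n_plant <- config$n_direct_parents + config$n_hubs + n_med
  with_seed(config$seed + 1L, {
    cm <- colMeans(dosages, na.rm = TRUE)
    maf <- pmin(cm / 4, 1 - cm / 4)
    callrate_ok <- colMeans(is.na(dosages)) <= 0.1
    maf_min <- config$plant_maf_min
    eligible <- which(!is.na(maf) & maf >= maf_min & callrate_ok)
    if (length(eligible) < n_plant && maf_min > 0.1) {
      warnf("relaxing plant_maf_min to 0.1: only %d eligible markers",
            length(eligible))
      eligible <- which(!is.na(maf) & maf >= 0.1 & callrate_ok)
    }
    if (length(eligible) < n_plant)
      stopf("only %d markers eligible for planting, need %d",
            length(eligible), n_plant)
    picked <- sample(eligible, n_plant)
    parents <- picked[seq_len(config$n_direct_parents)]
    hubs <- picked[config$n_direct_parents + seq_len(config$n_hubs)]
    mediators <- picked[config$n_direct_parents + config$n_hubs + seq_len(n_med)]
    stopifnot(!anyDuplicated(picked))  # planted sets must be disjoint

    med_map <- split(mediators, rep(seq_along(hubs),
                                    each = config$mediators_per_hub))
    names(med_map) <- ids[hubs]
    med_map <- lapply(med_map, function(ix) ids[ix])

    # regenerate mediators from their hub through a latent Gaussian
    t <- config$hub_transfer
    for (h in seq_along(hubs)) {
      hub_col <- dosages[, hubs[h]]
      hub_imp <- ifelse(is.na(hub_col), mean(hub_col, na.rm = TRUE), hub_col)
      hub_std <- as.numeric(scale(hub_imp))
      if (all(!is.finite(hub_std))) hub_std <- rep(0, n)
      for (mcol in med_map[[h]]) {
        z <- t * hub_std + sqrt(1 - t^2) * stats::rnorm(n)
        dosages[, mcol] <- rank_match(dosages[, mcol], z)
      }
    }

    direct <- if (config$mediators_are_parents) c(parents, mediators) else parents
    # one random sign per pure parent; one shared sign per hub's mediator
    # block, so sibling mediators never cancel their hub's marginal signal
    signs <- sample(c(-1, 1), length(parents), replace = TRUE)
    if (config$mediators_are_parents && n_med > 0L) {
      hub_signs <- sample(c(-1, 1), config$n_hubs, replace = TRUE)
      signs <- c(signs, rep(hub_signs, each = config$mediators_per_hub))
    }
    beta <- config$beta_parent * signs
    names(beta) <- ids[direct]

    d_imp <- dosages[, direct, drop = FALSE]
    if (anyNA(d_imp))
      for (j in seq_len(ncol(d_imp))) {
        miss <- is.na(d_imp[, j])
        d_imp[miss, j] <- mean(d_imp[, j], na.rm = TRUE)
      }
    y <- as.numeric(d_imp %*% beta) + config$beta_confounder * anc +
      stats::rnorm(n, 0, config$noise_sd)
    names(y) <- rownames(dosages)

    dag <- rbind(
      if (length(direct))
        data.frame(from = ids[direct], to = config$trait_name,
                   stringsAsFactors = FALSE),
      if (n_med > 0L)
        data.frame(from = rep(ids[hubs], each = config$mediators_per_hub),
                   to = ids[mediators], stringsAsFactors = FALSE))
    if (is.null(dag))
      dag <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
    truth <- structure(list(
      parent_ids = ids[direct], pure_parent_ids = ids[parents],
      hub_ids = ids[hubs], mediator_map = med_map,
      trait_dag = dag, subpop_labels = subpop_labels,
      effects = beta, confounder = anc, trait_name = config$trait_name),
      class = "sim_truth")
    list(phenotype = y, dosages = dosages, truth = truth)
  })
}

#' Simulate a complete cohort (genotypes + trait + ground truth)
#'
#' @param config a [sim_config()].
#' @return object of class `sim_cohort`: list with `dosages`, `phenotype`,
#'   `truth`, `ancestry`, `subpop_labels`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  g <- simulate_genotypes(config)
  tr <- simulate_trait(g$dosages, g$subpop_labels, config,
                       ancestry = g$ancestry)
  structure(list(dosages = tr$dosages, phenotype = tr$phenotype,
                 truth = tr$truth, ancestry = g$ancestry,
                 subpop_labels = g$subpop_labels, config = config),
            class = "sim_cohort")
}

#' @method print sim_cohort
#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d individuals x %d markers\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  direct parents: %d (%d mediators), hubs: %d\n",
              length(x$truth$parent_ids),
              length(unlist(x$truth$mediator_map)), length(x$truth$hub_ids)))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the dosage matrix (TSV, first column `genotype_id`), the phenotype
#' table, and the truth graph as an edge-list TSV plus GraphML.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- file.path(dir, "dosages.tsv")
  write_dosage(cohort$dosages, geno)
  ph <- file.path(dir, "phenotype.tsv")
  data.table::fwrite(data.table::data.table(
    genotype_id = names(cohort$phenotype),
    trait = as.numeric(cohort$phenotype)), ph, sep = "\t")
  edges <- file.path(dir, "truth_edges.tsv")
  data.table::fwrite(cohort$truth$trait_dag, edges, sep = "\t")
  gml <- file.path(dir, "truth.graphml")
  ig <- igraph::graph_from_data_frame(cohort$truth$trait_dag, directed = TRUE)
  igraph::write_graph(ig, gml, format = "graphml")
  invisible(c(geno, ph, edges, gml))
}
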