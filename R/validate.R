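# Predictive-specificity validation: out-of-fold R-squared of the direct
# parent, upstream hub and size-matched random marker sets, plus
# structure-recovery metrics against simulation ground truth.

#' Out-of-fold R-squared of a marker panel
#'
#' K-fold cross-validation: an ordinary least squares model of the
#' phenotype on the selected dosage columns is fit on the training folds,
#' predictions are pooled over held-out folds, and
#' `R2 = 1 - SS_res / SS_tot` with `SS_tot` taken about each fold's training
#' mean. Out-of-sample R-squared may be negative (worse than predicting the
#' mean). If a training fold has more features than observations, a ridge
#' solve with penalty 1e-6 is used instead.
#'
#' @param dosages complete dosage matrix.
#' @param phenotype aligned trait vector.
#' @param feature_ids marker IDs to use as predictors (non-empty).
#' @param n_folds folds, default 5.
#' @param seed integer seed for the fold split.
#' @return scalar out-of-fold R-squared.
#' @export
predictive_r2 <- function(dosages, phenotype, feature_ids, n_folds = 5L,
                          seed = 1L) {
  if (!length(feature_ids)) stopf("feature_ids is empty")
  bad <- setdiff(feature_ids, colnames(dosages))
  if (length(bad)) stopf("unknown markers: %s", paste(bad, collapse = ", "))
  y <- if (!is.null(names(phenotype)))
    as.numeric(phenotype[rownames(dosages)]) else as.numeric(phenotype)
  if (anyNA(y)) stopf("phenotype missing for some genotyped individuals")
  x <- dosages[, feature_ids, drop = FALSE]
  n <- length(y)
  folds <- fold_assign(n, n_folds, seed)
  ss_res <- ss_tot <- 0
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    xtr <- cbind(1, x[tr, , drop = FALSE])
    fit_ok <- sum(tr) > ncol(xtr)
    coefs <- if (fit_ok) {
      cf <- stats::lm.fit(xtr, y[tr])$coefficients
      if (anyNA(cf)) { fit_ok <- FALSE; NULL } else cf
    } else NULL
    if (!fit_ok) {
      xtx <- crossprod(xtr) + diag(1e-6, ncol(xtr))
      coefs <- as.numeric(solve(xtx, crossprod(xtr, y[tr])))
    }
    pred <- as.numeric(cbind(1, x[!tr, , drop = FALSE]) %*% coefs)
    ss_res <- ss_res + sum((y[!tr] - pred)^2)
    ss_tot <- ss_tot + sum((y[!tr] - mean(y[tr]))^2)
  }
  1 - ss_res / ss_tot
}

#' Compare predictive power of DPS, UHS and random marker panels
#'
#' Evaluates [predictive_r2()] for the direct-parent set, for the hub set
#' truncated/padded to the same size via the out-degree ranking, and for
#' `n_random_draws` random panels of equal size sampled without replacement
#' from markers outside the DPS and UHS sets (relaxed with a warning when
#' too few remain). Optionally also scores the full stability-selected set.
#'
#' @param dosages complete dosage matrix (all QC'd markers — the random
#'   panels are drawn from these).
#' @param phenotype aligned trait vector.
#' @param roles a `role_table` with at least one DPS.
#' @param graph optional `cpdag`, used to pad the UHS panel from the
#'   out-degree ranking when fewer hubs than parents exist.
#' @param n_random_draws number of random panels, default 20.
#' @param n_folds folds for each evaluation, default 5.
#' @param seed integer seed.
#' @param full_selected optional character vector of all stability-selected
#'   markers, scored as a fourth feature set.
#' @param trait_label trait name recorded in the report, default "trait".
#' @return data.frame of class `validation_report`: one row per feature set
#'   with `trait`, `feature_set`, `n_features`, `r2`, `n_random_draws`,
#'   `r2_random_mean`, `r2_random_sd`.
#' @export
compare_feature_sets <- function(dosages, phenotype, roles, graph = NULL,
                                 n_random_draws = 20L, n_folds = 5L,
                                 seed = 1L, full_selected = NULL,
                                 trait_label = "trait") {
  dps <- roles$marker_id[roles$role == "DPS"]
  if (!length(dps)) stopf("no direct parent SNPs in role table")
  uhs <- roles$marker_id[roles$role == "UHS"]
  k <- length(dps)
  if (length(uhs) > k) uhs <- uhs[seq_len(k)]  # role_table is rank-ordered
  if (length(uhs) < k && !is.null(graph)) {
    pad <- out_degree_ranking(graph)$marker_id
    pad <- setdiff(pad, c(dps, uhs))
    uhs <- c(uhs, utils::head(pad, k - length(uhs)))
  }
  if (length(uhs) < k)
    warnf("UHS panel has %d markers, fewer than the %d DPSs", length(uhs), k)

  r2_dps <- predictive_r2(dosages, phenotype, dps, n_folds, seed)
  r2_uhs <- if (length(uhs))
    predictive_r2(dosages, phenotype, uhs, n_folds, seed) else NA_real_

  pool <- setdiff(colnames(dosages), c(dps, uhs))
  if (length(pool) < k) {
    warnf("too few markers outside DPS/UHS; sampling from all markers")
    pool <- colnames(dosages)
  }
  r2_rand <- with_seed(seed + 10000L, vapply(seq_len(n_random_draws),
    function(d) predictive_r2(dosages, phenotype, sample(pool, k), n_folds,
                              seed + d), numeric(1)))

  rows <- data.frame(
    trait = trait_label,
    feature_set = c("DPS", "UHS", "random"),
    n_features = c(length(dps), length(uhs), k),
    r2 = c(r2_dps, r2_uhs, mean(r2_rand)),
    n_random_draws = c(0L, 0L, as.integer(n_random_draws)),
    r2_random_mean = c(NA_real_, NA_real_, mean(r2_rand)),
    r2_random_sd = c(NA_real_, NA_real_, stats::sd(r2_rand)),
    stringsAsFactors = FALSE)
  if (!is.null(full_selected) && length(full_selected)) {
    rows <- rbind(rows, data.frame(
      trait = trait_label, feature_set = "full_selected",
      n_features = length(full_selected),
      r2 = predictive_r2(dosages, phenotype, full_selected, n_folds, seed),
      n_random_draws = 0L, r2_random_mean = NA_real_,
      r2_random_sd = NA_real_, stringsAsFactors = FALSE))
  }
  class(rows) <- c("validation_report", "data.frame")
  rows
}

# precision with the empty-prediction convention: an empty predicted set has
# precision 1 (no false positives were asserted)
prec_rec <- function(predicted, truth) {
  tp <- length(intersect(predicted, truth))
  precision <- if (!length(predicted)) 1 else tp / length(predicted)
  recall <- if (!length(truth)) 1 else tp / length(truth)
  c(precision = precision, recall = recall)
}

#' Structure-recovery metrics against simulation ground truth
#'
#' Precision and recall of the inferred direct-parent set against the
#' planted parents, of the inferred hub set against the planted hubs, and
#' the structural Hamming distance between the inferred graph and the CPDAG
#' of the planted DAG.
#'
#' @param roles inferred `role_table`.
#' @param truth a `sim_truth`.
#' @param graph optional inferred `cpdag` for the SHD component.
#' @return list of class `recovery_metrics`: `parent_precision`,
#'   `parent_recall`, `hub_precision`, `hub_recall`, `shd` (`NA` when no
#'   graph given).
#' @export
recovery_metrics <- function(roles, truth, graph = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  dps <- roles$marker_id[roles$role == "DPS"]
  uhs <- roles$marker_id[roles$role == "UHS"]
  pp <- prec_rec(dps, truth$parent_ids)
  hp <- prec_rec(uhs, truth$hub_ids)
  shd_val <- NA_integer_
  if (!is.null(graph)) {
    nodes <- unique(c(truth$trait_dag$from, truth$trait_dag$to))
    amat <- matrix(0L, length(nodes), length(nodes),
                   dimnames = list(nodes, nodes))
    for (e in seq_len(nrow(truth$trait_dag)))
      amat[truth$trait_dag$from[e], truth$trait_dag$to[e]] <- 1L
    shd_val <- shd(graph, dag_to_cpdag(amat))
  }
  structure(list(parent_precision = unname(pp["precision"]),
                 parent_recall = unname(pp["recall"]),
                 hub_precision = unname(hp["precision"]),
                 hub_recall = unname(hp["recall"]),
                 shd = shd_val), class = "recovery_metrics")
}

#' @method print recovery_metrics
#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf(
    "recovery: parents P=%.2f R=%.2f; hubs P=%.2f R=%.2f; SHD=%s\n",
    x$parent_precision, x$parent_recall, x$hub_precision, x$hub_recall,
    ifelse(is.na(x$shd), "NA", x$shd)))
  invisible(x)
}
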