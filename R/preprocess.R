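#' Remove markers with excessive missingness
#'
#' Markers whose missing fraction is *strictly greater* than `max_missing`
#' are dropped (a marker with exactly the threshold fraction is retained).
#' Marker order is preserved.
#'
#' @param x dosage matrix (individuals x markers).
#' @param max_missing maximum tolerated missing fraction, default 0.10.
#' @return list with `dosages` (filtered matrix), `removed_ids`, and
#'   `call_rate` (named per-marker call-rate vector for the input markers).
#' @export
filter_call_rate <- function(x, max_missing = 0.10) {
  validate_dosages(x, allow_fractional = TRUE)
  if (max_missing < 0 || max_missing > 1) stopf("max_missing must be in [0,1]")
  miss <- colMeans(is.na(x))
  drop <- miss > max_missing
  list(dosages = x[, !drop, drop = FALSE],
       removed_ids = colnames(x)[drop],
       call_rate = stats::setNames(1 - miss, colnames(x)))
}

#' Remove markers with low minor allele frequency
#'
#' The alternative-allele frequency is estimated from non-missing dosages as
#' `mean(dosage) / 4`; MAF is `min(p, 1 - p)`. Markers with MAF *strictly
#' below* `min_maf` are removed (MAF exactly at the threshold is retained).
#' Markers with all entries missing are removed with a warning.
#'
#' @param x dosage matrix, call-rate filter already applied.
#' @param min_maf minimum minor allele frequency, default 0.05.
#' @return list with `dosages`, `removed_ids`, and `maf` (named per-marker
#'   MAF for the input markers, `NA` when all entries are missing).
#' @export
filter_maf <- function(x, min_maf = 0.05) {
  validate_dosages(x, allow_fractional = TRUE)
  if (min_maf < 0 || min_maf > 0.5) stopf("min_maf must be in [0, 0.5]")
  p <- colMeans(x, na.rm = TRUE) / 4
  maf <- pmin(p, 1 - p)
  all_miss <- is.na(maf)
  if (any(all_miss))
    warnf("%d markers with no observed calls removed", sum(all_miss))
  drop <- all_miss | (!all_miss & maf < min_maf)
  list(dosages = x[, !drop, drop = FALSE],
       removed_ids = colnames(x)[drop],
       maf = stats::setNames(maf, colnames(x)))
}

#' Run the full marker quality-control sequence
#'
#' Applies the call-rate filter first, then the MAF filter, and returns the
#' filtered matrix together with a QC report.
#'
#' @param x raw dosage matrix.
#' @param max_missing call-rate threshold (strict `>` removal), default 0.10.
#' @param min_maf MAF threshold (strict `<` removal), default 0.05.
#' @return list with `dosages` and `report` (class `qc_report`): marker
#'   counts per step plus per-marker call rate and MAF.
#' @export
qc_filter <- function(x, max_missing = 0.10, min_maf = 0.05) {
  cr <- filter_call_rate(x, max_missing)
  mf <- filter_maf(cr$dosages, min_maf)
  report <- structure(list(
    n_markers_in = ncol(x),
    n_removed_call_rate = length(cr$removed_ids),
    n_removed_maf = length(mf$removed_ids),
    n_markers_out = ncol(mf$dosages),
    removed_call_rate = cr$removed_ids, removed_maf = mf$removed_ids,
    call_rate = cr$call_rate, maf = mf$maf,
    max_missing = max_missing, min_maf = min_maf), class = "qc_report")
  stopifnot(report$n_markers_out ==
              report$n_markers_in - report$n_removed_call_rate -
              report$n_removed_maf)
  list(dosages = mf$dosages, report = report)
}

#' @method print qc_report
#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "qc_report: %d markers in; %d removed by call rate (>%g missing), %d by MAF (<%g); %d retained\n",
    x$n_markers_in, x$n_removed_call_rate, x$max_missing,
    x$n_removed_maf, x$min_maf, x$n_markers_out))
  invisible(x)
}

#' Mean-impute missing dosages
#'
#' Missing entries are replaced by the marker's non-missing mean, making the
#' dosage quasi-continuous; column means are unchanged. Markers with all
#' entries missing are an error (they should have been filtered).
#'
#' @param x dosage matrix.
#' @return complete numeric matrix.
#' @export
impute_mean <- function(x) {
  validate_dosages(x, allow_fractional = TRUE)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  cm <- colMeans(x, na.rm = TRUE)
  if (anyNA(cm)) stopf("markers with all entries missing: run QC first")
  idx <- which(miss, arr.ind = TRUE)
  x[idx] <- cm[idx[, 2L]]
  x
}

#' Principal components of the genotype matrix
#'
#' Markers are centred and unit-variance scaled (constant markers are left at
#' zero), then the leading `k` left singular directions scaled by their
#' singular values give the scores: the standard structure-confounder proxy.
#' Column signs are fixed by convention (the largest-magnitude loading of
#' each component is positive), so results are fully deterministic.
#'
#' @param x complete (imputed) dosage matrix.
#' @param k number of components, default 10.
#' @return list of class `pc_matrix`: `scores` (n x k, rownames preserved),
#'   `explained_variance_ratio` (length k), `loadings`, `k`.
#' @export
compute_pcs <- function(x, k = 10L) {
  validate_dosages(x, allow_fractional = TRUE)
  if (anyNA(x)) stopf("dosage matrix must be complete (impute first)")
  n <- nrow(x); m <- ncol(x)
  if (k > min(n - 1L, m))
    stopf("k = %d exceeds min(n - 1, M) = %d", k, min(n - 1L, m))
  xs <- standardize_cols(x)$x
  sv <- svd(xs, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u, 2L, sv$d[seq_len(k)] * flip, "*")
  loadings <- sweep(sv$v, 2L, flip, "*")
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  evr <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  structure(list(scores = scores, explained_variance_ratio = evr,
                 loadings = loadings, k = k), class = "pc_matrix")
}

#' Spatially adjusted genotype BLUPs from plot-level phenotypes
#'
#' Fits the row-column mixed model `y = mu + genotype + row + col + error`
#' with independent random effects for genotype, field row and field column
#' (REML via [lme4::lmer()]), and returns the best linear unbiased
#' predictions of the genotype effects on the trait scale
#' (intercept + genotype BLUP). This is a deliberately simplified spatial
#' adjustment: no autoregressive residuals or spline trends.
#'
#' @param plots data.frame with columns `genotype_id`, `row`, `column`, and
#'   the trait value column named by `value`.
#' @param value name of the trait column, default "value".
#' @return list with `blups` (named per-genotype vector, trait scale) and
#'   `varcomp` (named vector: genotype, row, column, residual variances).
#' @export
spatial_adjust <- function(plots, value = "value") {
  need <- c("genotype_id", "row", "column", value)
  if (!all(need %in% names(plots)))
    stopf("plots needs columns: %s", paste(need, collapse = ", "))
  if (nrow(plots) < 2L) stopf("need more than one plot")
  d <- data.frame(g = factor(plots$genotype_id), r = factor(plots$row),
                  c = factor(plots$column), y = plots[[value]])
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ 1 + (1 | g) + (1 | r) + (1 | c), data = d,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  varcomp <- c(genotype = unname(varcomp["g"]), row = unname(varcomp["r"]),
               column = unname(varcomp["c"]),
               residual = unname(varcomp["Residual"]))
  g_eff <- lme4::ranef(fit)$g
  blups <- stats::setNames(lme4::fixef(fit)[["(Intercept)"]] + g_eff[[1L]],
                           rownames(g_eff))
  # sort by genotype label for a stable, input-order-independent result
  blups <- blups[order(names(blups))]
  list(blups = blups, varcomp = varcomp)
}
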