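# De-confounded per-SNP effect estimation: cross-fitted double machine
# learning on the partially linear model
#   Y = theta * D + g(X) + zeta,   D = m(X) + nu,
# with X the genotype principal components. The partialling-out score gives
#   theta_hat = sum(nu_hat * ytil) / sum(nu_hat^2),  ytil = Y - g_hat(X),
# with the sandwich variance sum(psi^2) / (sum(nu_hat^2))^2,
# psi = nu_hat * (ytil - theta_hat * nu_hat), and normal-approximation
# p-values (cross-fitting theory).

# vectorised DML statistics from stacked out-of-fold residuals; df_spent is
# the degrees of freedom consumed by the nuisance fits (2 regressions of
# k + 1 coefficients each): the sandwich variance carries the standard
# small-sample correction n / (n - df_spent), without which the normal
# approximation is anti-conservative by O(k/n)
dml_stats <- function(ytil, nu, df_spent = 0L) {
  nu <- as.matrix(nu)
  n <- nrow(nu)
  s2 <- colSums(nu^2)
  degenerate <- s2 < 1e-10
  s2safe <- ifelse(degenerate, 1, s2)
  theta <- colSums(nu * ytil) / s2safe
  psi <- nu * (ytil - sweep(nu, 2L, theta, "*"))
  infl <- n / max(n - df_spent, ceiling(n / 2))
  se <- sqrt(infl * colSums(psi^2)) / s2safe
  z <- ifelse(se > 0, abs(theta) / se, Inf)
  p <- 2 * stats::pnorm(-z)
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  theta[degenerate] <- 0
  se[degenerate] <- NA_real_
  p[degenerate] <- 1
  data.frame(theta = theta, se = se, p = p,
             ci_low = theta - 1.96 * se, ci_high = theta + 1.96 * se,
             degenerate = degenerate)
}

#' Double machine learning effect of a single SNP on a trait
#'
#' Cross-fitted partialling-out estimator for the partially linear model:
#' both nuisance regressions (trait on covariates, dosage on covariates) are
#' fit with cross-validated lasso on each fold's complement, residuals are
#' stacked over folds, and the de-confounded effect `theta` is the ratio
#' `sum(nu * ytil) / sum(nu^2)` with a sandwich standard error. A marker
#' whose residual treatment variance vanishes (dosage fully explained by the
#' covariates, e.g. a constant column) is returned as a degenerate record
#' with `theta = 0`, `p = 1`.
#'
#' @param y numeric trait vector.
#' @param d numeric dosage vector for one marker.
#' @param x covariate matrix (typically PC scores), complete.
#' @param n_folds number of cross-fitting folds, default 5.
#' @param seed integer seed controlling the fold split.
#' @return object of class `plr_fit`: `theta`, `se`, `p`, `ci_low`,
#'   `ci_high`, `n_eff`, `degenerate`.
#' @export
dml_plr_single <- function(y, d, x, n_folds = 5L, seed = 1L) {
  y <- as.numeric(y); d <- as.numeric(d); x <- as.matrix(x)
  n <- length(y)
  if (length(d) != n || nrow(x) != n) stopf("y, d, X lengths differ")
  if (anyNA(y) || anyNA(d) || anyNA(x)) stopf("inputs must be complete")
  if (n <= n_folds) stopf("need n > n_folds")
  cf <- crossfit_nuisance(y, matrix(d, ncol = 1L), x, n_folds, seed)
  st <- dml_stats(cf$ytil, cf$nu, df_spent = 2L * (ncol(x) + 1L))
  structure(c(as.list(st[1L, ]), list(n_eff = n)), class = "plr_fit")
}

#' @method print plr_fit
#' @export
print.plr_fit <- function(x, ...) {
  cat(sprintf("plr_fit: theta = %.4f (se %.4f), p = %.3g, 95%% CI [%.4f, %.4f]%s\n",
              x$theta, x$se, x$p, x$ci_low, x$ci_high,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Screening configuration
#'
#' @param n_rep number of stability-selection repetitions (re-randomised
#'   cross-fitting splits), default 100.
#' @param n_folds cross-fitting folds per repetition, default 5.
#' @param p_thresh per-repetition significance threshold, default 1e-4.
#' @param stability_pi minimum fraction of repetitions in which a marker must
#'   pass `p_thresh` to be selected, default 0.8 (set to 1 for the literal
#'   "significant in every split" reading).
#' @param n_pcs number of genotype PCs used as confounding proxies, default 10.
#' @param seed integer seed; repetition `r` derives its fold split from
#'   `seed + r`.
#' @return object of class `screen_config`.
#' @export
screen_config <- function(n_rep = 100L, n_folds = 5L, p_thresh = 1e-4,
                          stability_pi = 0.8, n_pcs = 10L, seed = 1L) {
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  if (n_rep < 1L) stopf("n_rep must be >= 1")
  if (p_thresh <= 0 || p_thresh >= 1 || stability_pi <= 0 || stability_pi > 1)
    stopf("thresholds must lie in (0, 1)")
  structure(list(n_rep = as.integer(n_rep), n_folds = as.integer(n_folds),
                 p_thresh = p_thresh, stability_pi = stability_pi,
                 n_pcs = as.integer(n_pcs), seed = as.integer(seed)),
            class = "screen_config")
}

#' Genome-wide de-confounded screen with stability selection
#'
#' Runs the cross-fitted DML estimator for every marker, repeated `n_rep`
#' times with re-randomised fold splits. A marker's stability frequency is
#' the fraction of repetitions with `p < p_thresh`; markers at or above
#' `stability_pi` are selected. The reported per-marker effect, standard
#' error and p-value come from the repetition whose p-value is the (lower)
#' median across repetitions — a stable summary that avoids the optimistic
#' minimum-p choice. Degenerate markers are retained in the table but never
#' selected.
#'
#' @param dosages QC'd, imputed dosage matrix.
#' @param phenotype named numeric vector aligned with `rownames(dosages)`.
#' @param pcs PC score matrix (from [compute_pcs()]) or `NULL` to compute
#'   `config$n_pcs` components internally.
#' @param config a [screen_config()].
#' @return data.frame of class `screening_table`, sorted by genome position:
#'   `marker_id`, `chrom`, `pos`, `theta`, `se`, `p`, `ci_low`, `ci_high`,
#'   `stability_freq`, `selected`, `degenerate`.
#' @export
run_screen <- function(dosages, phenotype, pcs = NULL,
                       config = screen_config()) {
  validate_dosages(dosages, allow_fractional = TRUE)
  if (anyNA(dosages)) stopf("dosages must be imputed before screening")
  if (is.null(names(phenotype)))
    names(phenotype) <- rownames(dosages)
  if (!all(rownames(dosages) %in% names(phenotype)))
    stopf("phenotype is missing individuals present in the dosage matrix")
  y <- as.numeric(phenotype[rownames(dosages)])
  if (anyNA(y)) stopf("phenotype has missing values for genotyped individuals")
  if (is.null(pcs)) pcs <- compute_pcs(dosages, k = config$n_pcs)
  x <- if (inherits(pcs, "pc_matrix")) pcs$scores else as.matrix(pcs)
  if (!is.null(rownames(x))) {
    if (!all(rownames(dosages) %in% rownames(x)))
      stopf("PC scores are missing individuals present in the dosage matrix")
    x <- x[rownames(dosages), , drop = FALSE]
  }

  m <- ncol(dosages)
  pm <- tm <- sm <- matrix(NA_real_, config$n_rep, m)
  degm <- matrix(FALSE, config$n_rep, m)
  for (r in seq_len(config$n_rep)) {
    cf <- crossfit_nuisance(y, dosages, x, config$n_folds, config$seed + r)
    st <- dml_stats(cf$ytil, cf$nu, df_spent = 2L * (ncol(x) + 1L))
    pm[r, ] <- st$p; tm[r, ] <- st$theta; sm[r, ] <- st$se
    degm[r, ] <- st$degenerate
  }
  stability <- colMeans(pm < config$p_thresh)
  med_idx <- vapply(seq_len(m), function(j)
    order(pm[, j])[floor((config$n_rep + 1) / 2)], integer(1))
  pick <- cbind(med_idx, seq_len(m))
  theta <- tm[pick]; se <- sm[pick]; p <- pm[pick]
  degenerate <- apply(degm, 2L, any)
  selected <- stability >= config$stability_pi & !degenerate

  ids <- colnames(dosages)
  parsed <- suppressWarnings(parse_marker_ids(ids))
  tab <- data.frame(marker_id = ids, chrom = parsed$chrom, pos = parsed$pos,
                    theta = theta, se = se, p = p,
                    ci_low = theta - 1.96 * se, ci_high = theta + 1.96 * se,
                    stability_freq = stability, selected = selected,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  tab <- tab[genome_order(ids), ]
  rownames(tab) <- NULL
  class(tab) <- c("screening_table", "data.frame")
  attr(tab, "config") <- config
  tab
}

#' Naive unadjusted single-marker scan
#'
#' Simple-regression slope and p-value of the trait on each marker with no
#' confounder adjustment: the comparison arm for quantifying how much
#' structure-driven inflation the DML screen removes.
#'
#' @param dosages complete dosage matrix.
#' @param phenotype aligned trait vector.
#' @return data.frame with `marker_id`, `beta`, `p`.
#' @export
naive_scan <- function(dosages, phenotype) {
  y <- if (!is.null(names(phenotype)))
    as.numeric(phenotype[rownames(dosages)]) else as.numeric(phenotype)
  n <- nrow(dosages)
  sdx <- apply(dosages, 2L, stats::sd)
  ok <- sdx > 0
  r <- rep(NA_real_, ncol(dosages))
  r[ok] <- as.numeric(stats::cor(dosages[, ok, drop = FALSE], y))
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  beta <- r * stats::sd(y) / ifelse(ok, sdx, NA_real_)
  p[!ok] <- 1; beta[!ok] <- 0
  data.frame(marker_id = colnames(dosages), beta = beta, p = p,
             stringsAsFactors = FALSE)
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(qchisq(p, df = 1, lower.tail = FALSE)) / 0.4549364`,
#' the median observed association chi-square over the null chi-square(1)
#' median. Values near 1 indicate calibrated tests; inflation above 1 signals
#' residual confounding.
#'
#' @param pvals vector of p-values in (0, 1]; zeros are clamped to the
#'   smallest positive double with a warning.
#' @return scalar inflation factor.
#' @export
genomic_inflation <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) stopf("no p-values supplied")
  if (any(pvals < 0 | pvals > 1)) stopf("p-values must lie in [0, 1]")
  if (any(pvals == 0)) {
    warnf("p-values of 0 clamped to the smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Bonferroni-corrected genome-wide significance threshold
#'
#' @param n_markers number of tests.
#' @param alpha family-wise error rate, default 0.05.
#' @return `alpha / n_markers`.
#' @export
bonferroni_threshold <- function(n_markers, alpha = 0.05) {
  if (any(n_markers < 1)) stopf("n_markers must be >= 1")
  alpha / n_markers
}

#' Plot-ready diagnostic tables from a screening table
#'
#' Emits the four standard screening diagnostics as data frames (and
#' optionally TSV files): Manhattan (`chrom`, `pos`, `neglog10p`), Q-Q
#' (expected vs observed `-log10 p`, with the genomic inflation factor as an
#' attribute and column), volcano (`theta` vs `neglog10p`, significance flag
#' at `p < 0.05`), and forest (top `top_k` selected markers with `theta` and
#' 95% confidence bounds).
#'
#' @param table a `screening_table`.
#' @param top_k number of markers in the forest table, default 20.
#' @param out_dir optional directory; when given, the four tables are written
#'   as `manhattan.tsv`, `qq.tsv`, `volcano.tsv`, `forest.tsv`.
#' @return named list of the four data frames.
#' @export
screening_report <- function(table, top_k = 20L, out_dir = NULL) {
  if (!nrow(table)) stopf("screening table is empty")
  manhattan <- data.frame(marker_id = table$marker_id, chrom = table$chrom,
                          pos = table$pos, neglog10p = -log10(table$p))
  lam <- genomic_inflation(table$p)
  obs <- sort(table$p)
  qq <- data.frame(expected = -log10(stats::ppoints(length(obs))),
                   observed = -log10(obs), lambda_gc = lam)
  volcano <- data.frame(marker_id = table$marker_id, chrom = table$chrom,
                        theta = table$theta, neglog10p = -log10(table$p),
                        significant = table$p < 0.05)
  sel <- table[table$selected, , drop = FALSE]
  sel <- sel[order(sel$p), , drop = FALSE]
  forest <- utils::head(sel[, c("marker_id", "theta", "ci_low", "ci_high", "p")],
                        top_k)
  out <- list(manhattan = manhattan, qq = qq, volcano = volcano,
              forest = forest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      data.table::fwrite(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t")
  }
  attr(out, "lambda_gc") <- lam
  out
}
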