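# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library calls never perturb the
#' caller's random stream. All exported stochastic functions route their
#' randomness through this helper.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Deterministic k-fold assignment
#' @param n number of observations.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold labels in `1:k`.
#' @keywords internal
fold_assign <- function(n, k, seed) {
  if (k < 2L) stopf("need at least 2 folds")
  if (n <= k) stopf("need more observations (%d) than folds (%d)", n, k)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Parse marker identifiers of the form chr{C}.{H}_{POS}
#'
#' Both `chr4.1_6473437` and the dotted variant `chr4.1.6473437` are accepted.
#' Unparseable identifiers keep their input order (chrom/pos set to `NA`) with
#' a single warning.
#'
#' @param ids character vector of marker identifiers.
#' @return data.frame with columns `marker_id`, `chrom`, `homolog`, `pos`.
#' @export
parse_marker_ids <- function(ids) {
  m <- regmatches(ids, regexec("^chr([0-9]+)\\.([0-9]+)[._]([0-9]+)$", ids))
  ok <- lengths(m) == 4L
  chrom <- homolog <- pos <- rep(NA_integer_, length(ids))
  if (any(ok)) {
    parsed <- do.call(rbind, lapply(m[ok], function(x) as.integer(x[2:4])))
    chrom[ok] <- parsed[, 1]; homolog[ok] <- parsed[, 2]; pos[ok] <- parsed[, 3]
  }
  if (any(!ok))
    warnf("%d marker IDs do not match chr{C}.{H}_{POS}; falling back to input order",
          sum(!ok))
  data.frame(marker_id = ids, chrom = chrom, homolog = homolog, pos = pos,
             stringsAsFactors = FALSE)
}

# order key for genome sorting; unparseable ids keep input position
genome_order <- function(ids) {
  p <- suppressWarnings(parse_marker_ids(ids))
  order(is.na(p$chrom), p$chrom, p$pos, seq_along(ids))
}

#' Validate a dosage matrix
#'
#' A dosage matrix is a plain numeric matrix, individuals in rows and markers
#' in columns, entries in \{0,1,2,3,4\} or `NA`, with unique row and column
#' names.
#'
#' @param x object to validate.
#' @param allow_fractional allow non-integer entries (post-imputation).
#' @return `x`, invisibly, after validation.
#' @export
validate_dosages <- function(x, allow_fractional = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("dosages must be a numeric matrix")
  if (nrow(x) == 0L || ncol(x) == 0L) stopf("dosage matrix is empty")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("dosage matrix needs individual (row) and marker (column) names")
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stopf("duplicate individual or marker IDs")
  v <- x[!is.na(x)]
  if (length(v) && (min(v) < 0 || max(v) > 4))
    stopf("dosage values must lie in [0, 4]")
  if (!allow_fractional && length(v) && any(v != round(v)))
    stopf("raw dosage values must be integers 0..4")
  invisible(x)
}

# center/scale columns; zero-variance columns get scale 1 (stay zero)
standardize_cols <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  xc <- sweep(x, 2L, center, "-")
  if (is.null(scale)) {
    scale <- sqrt(colSums(xc^2) / max(1, nrow(x) - 1L))
    scale[scale < .Machine$double.eps^0.5] <- 1
  }
  list(x = sweep(xc, 2L, scale, "/"), center = center, scale = scale)
}
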