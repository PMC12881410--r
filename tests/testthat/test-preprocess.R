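make_mat <- function(vals, n = NULL) {
  # vals: list of marker columns
  m <- do.call(cbind, vals)
  rownames(m) <- sprintf("ind%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("chr1.1_%d", seq_len(ncol(m)) * 1000L)
  m
}

test_that("the call-rate filter removes strictly above the threshold", {
  n <- 500L
  col0 <- rep(2, n)
  col50 <- c(rep(NA, 50), rep(2, n - 50))    # exactly 10% missing
  col51 <- c(rep(NA, 51), rep(2, n - 51))    # 10.2% missing
  x <- make_mat(list(col0, col50, col51))
  f <- filter_call_rate(x, max_missing = 0.10)
  expect_identical(colnames(f$dosages), colnames(x)[1:2])
  expect_identical(f$removed_ids, colnames(x)[3L])

  # hand-counted toy: missing fractions {0, 0.05, 0.2} at threshold 0.10
  n <- 100L
  x2 <- make_mat(list(rep(1, n), c(rep(NA, 5), rep(1, 95)),
                      c(rep(NA, 20), rep(1, 80))))
  expect_identical(ncol(filter_call_rate(x2)$dosages), 2L)
})

test_that("the MAF filter uses mean dosage / 4 and removes strictly below", {
  x <- make_mat(list(rep(0, 4), rep(4, 4), c(1, 2, 3, 2), c(0, 1, 0, 0)))
  f <- filter_maf(x, min_maf = 0.05)
  # monomorphic columns (MAF 0) go; (1,2,3,2) has p = 8/16 = 0.5 and stays;
  # (0,1,0,0) has p = 1/16 = 0.0625 and stays at the 0.05 threshold
  expect_identical(f$removed_ids, colnames(x)[1:2])
  expect_equal(unname(f$maf[3L]), 0.5)
  expect_true(all(f$maf >= 0 & f$maf <= 0.5))
  # a marker with no observed calls is removed with a warning
  x2 <- make_mat(list(c(1, 2, 1, 2), rep(NA_real_, 4)))
  expect_warning(f2 <- filter_maf(x2), "no observed calls")
  expect_identical(ncol(f2$dosages), 1L)
})

test_that("quality control is idempotent and its report is consistent", {
  coh <- small_cohort(seed = 31)
  qc <- qc_filter(coh$dosages)
  r <- qc$report
  expect_identical(r$n_markers_out,
                   r$n_markers_in - r$n_removed_call_rate - r$n_removed_maf)
  again <- qc_filter(qc$dosages)
  expect_identical(again$report$n_removed_call_rate, 0L)
  expect_identical(again$report$n_removed_maf, 0L)
  expect_identical(again$dosages, qc$dosages)
})

test_that("mean imputation fills missing entries without moving column means", {
  x <- make_mat(list(c(0, 4, NA), c(1, 1, 1)))
  xi <- impute_mean(x)
  expect_equal(unname(xi[3L, 1L]), 2.0)
  expect_equal(colMeans(xi), colMeans(x, na.rm = TRUE))
  # complete input is returned unchanged
  expect_identical(impute_mean(xi), xi)
  # an all-missing marker is an error, not silent propagation
  expect_error(impute_mean(make_mat(list(c(1, 2, 1), rep(NA_real_, 3)))),
               "all entries missing")
})

test_that("PC scores match a brute-force eigendecomposition", {
  coh <- small_cohort(seed = 17)
  xi <- impute_mean(qc_filter(coh$dosages)$dosages)
  k <- 6L
  pcs <- compute_pcs(xi, k = k)
  # oracle: eigendecomposition of the correlation (scaled covariance) matrix
  xs <- scale(xi)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  ev <- eigen(stats::cov(xs), symmetric = TRUE)
  oracle <- xs %*% ev$vectors[, seq_len(k)]
  for (j in seq_len(k)) {
    s <- sign(sum(pcs$scores[, j] * oracle[, j]))
    expect_lt(max(abs(pcs$scores[, j] - s * oracle[, j])), 1e-6)
  }
  expect_true(all(abs(colMeans(pcs$scores)) < 1e-8))
  expect_true(all(diff(pcs$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(pcs$explained_variance_ratio), 1 + 1e-12)
})

test_that("degenerate PCA inputs are handled", {
  x <- matrix(rep(c(0, 2, 4, 1), each = 5), nrow = 5,
              dimnames = list(paste0("i", 1:5), paste0("chr1.1_", 1:4)))
  pcs <- compute_pcs(x, k = 2L)
  expect_true(all(abs(pcs$scores) < 1e-10))  # identical rows: no variance
  expect_error(compute_pcs(x, k = 5L), "exceeds")
})

test_that("spatial BLUPs reduce to genotype means without field effects", {
  set.seed(41)
  gmeans <- stats::setNames(stats::rnorm(60, 10, 1), sprintf("g%02d", 1:60))
  plots <- expand.grid(genotype_id = names(gmeans), replicate = 1:3,
                       stringsAsFactors = FALSE)
  plots$row <- rep(1:18, length.out = nrow(plots))
  plots$column <- rep(1:10, length.out = nrow(plots))
  plots$value <- gmeans[plots$genotype_id] + stats::rnorm(nrow(plots), 0, 1e-4)
  sa <- spatial_adjust(plots)
  expect_equal(unname(sa$blups[names(gmeans)]), unname(gmeans),
               tolerance = 1e-2)
  # permuting plot order leaves the BLUPs unchanged
  sa2 <- spatial_adjust(plots[sample(nrow(plots)), ])
  expect_equal(sa$blups, sa2$blups, tolerance = 1e-6)
})

test_that("spatial variance components are recovered on simulated plots", {
  set.seed(77)
  ng <- 500L; nrep <- 3L
  g <- stats::rnorm(ng, 0, 1)                      # sigma2_g = 1
  rows <- stats::rnorm(50, 0, sqrt(0.5))           # sigma2_r = 0.5
  cols <- stats::rnorm(30, 0, sqrt(0.5))           # sigma2_c = 0.5
  plots <- expand.grid(genotype_id = sprintf("g%03d", seq_len(ng)),
                       replicate = seq_len(nrep), stringsAsFactors = FALSE)
  plots$row <- sample(1:50, nrow(plots), replace = TRUE)
  plots$column <- sample(1:30, nrow(plots), replace = TRUE)
  gi <- as.integer(sub("g", "", plots$genotype_id))
  plots$value <- 5 + g[gi] + rows[plots$row] + cols[plots$column] +
    stats::rnorm(nrow(plots), 0, 1)                # sigma2_e = 1
  sa <- spatial_adjust(plots)
  expect_lt(abs(sa$varcomp[["genotype"]] - 1), 0.25)
  expect_lt(abs(sa$varcomp[["row"]] - 0.5), 0.25 * 0.5 + 0.15)
  expect_lt(abs(sa$varcomp[["column"]] - 0.5), 0.25 * 0.5 + 0.15)
  expect_lt(abs(sa$varcomp[["residual"]] - 1), 0.25)
  expect_error(spatial_adjust(plots[1L, ]), "more than one plot")
})
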