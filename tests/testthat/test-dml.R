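test_that("the batched lasso solves glmnet's objective at fixed penalty", {
  set.seed(10)
  n <- 250L; p <- 8L
  x <- matrix(stats::rnorm(n * p), n, p)
  d <- 0.6 * x[, 1L] - 0.3 * x[, 4L] + stats::rnorm(n)
  sx <- snpdag:::std_pop(x)
  dc <- d - mean(d)
  G <- crossprod(sx$x) / n
  C <- crossprod(sx$x, matrix(dc)) / n
  for (lam in c(0.2, 0.05, 0.01)) {
    mine <- snpdag:::lasso_path_cov(G, C, matrix(lam, 1L, 1L))[, 1L, 1L]
    ref <- glmnet::glmnet(sx$x, dc, lambda = lam, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-14)
    expect_lt(max(abs(mine - as.numeric(ref$beta))), 1e-6)
  }
})

test_that("batched and single-response cross-fitting agree", {
  set.seed(11)
  n <- 150L
  x <- matrix(stats::rnorm(n * 5L), n, 5L)
  d3 <- cbind(x[, 1L] + stats::rnorm(n), stats::rnorm(n),
              0.5 * x[, 2L] + stats::rnorm(n))
  y <- d3[, 1L] + stats::rnorm(n)
  cf <- snpdag:::crossfit_nuisance(y, d3, x, n_folds = 5L, seed = 77L)
  st <- snpdag:::dml_stats(cf$ytil, cf$nu, df_spent = 2L * (ncol(x) + 1L))
  for (j in 1:3) {
    single <- dml_plr_single(y, d3[, j], x, n_folds = 5L, seed = 77L)
    expect_equal(single$theta, st$theta[j], tolerance = 1e-10)
    expect_equal(single$se, st$se[j], tolerance = 1e-10)
  }
})

test_that("a noiseless linear effect is recovered exactly", {
  set.seed(12)
  n <- 300L
  x <- matrix(stats::rnorm(n * 5L), n, 5L)
  d <- stats::rnorm(n)
  fit <- dml_plr_single(0.5 * d, d, x, seed = 3L)
  expect_equal(fit$theta, 0.5, tolerance = 5e-3)
  expect_true(fit$ci_low > 0 || fit$ci_high < 0)  # CI excludes zero
  expect_false(fit$degenerate)
})

test_that("zero residual treatment variance yields the degenerate record", {
  set.seed(13)
  n <- 120L
  x <- matrix(stats::rnorm(n * 4L), n, 4L)
  fit <- dml_plr_single(stats::rnorm(n), rep(2, n), x, seed = 5L)
  expect_true(fit$degenerate)
  expect_identical(fit$theta, 0)
  expect_identical(fit$p, 1)
})

test_that("DML removes confounding bias that naive regression keeps", {
  # y = c + eps, d = c + eta, true effect of d is 0; c observed in X
  set.seed(14)
  n <- 400L; reps <- 40L
  cover <- logical(reps); naive <- numeric(reps)
  for (r in seq_len(reps)) {
    cc <- stats::rnorm(n)
    d <- cc + stats::rnorm(n)
    y <- cc + stats::rnorm(n)
    x <- cbind(cc, matrix(stats::rnorm(n * 4L), n, 4L))
    fit <- dml_plr_single(y, d, x, seed = r)
    cover[r] <- abs(fit$theta) < 2 * fit$se
    naive[r] <- stats::coef(stats::lm(y ~ d))[["d"]]
  }
  expect_gte(mean(cover), 0.9)
  # naive slope concentrates near Var(c)/(Var(c)+Var(eta)) = 0.5
  expect_gt(abs(mean(naive)), 0.4)
})

test_that("the stability screen flags planted signals and their signs", {
  set.seed(15)
  n <- 200L; m <- 40L
  d <- matrix(stats::rbinom(n * m, 4L, 0.5), n, m,
              dimnames = list(sprintf("i%03d", 1:n),
                              sprintf("chr%d.1_%d", rep(1:4, each = 10),
                                      rep(1:10 * 500, 4))))
  y <- 1.0 * d[, 5L] - 0.8 * d[, 20L] + stats::rnorm(n, 0, 0.8)
  tab <- run_screen(d, stats::setNames(y, rownames(d)), pcs = NULL,
                    config = screen_config(n_rep = 5L, n_pcs = 3L, seed = 2L))
  hits <- tab[tab$marker_id %in% colnames(d)[c(5L, 20L)], ]
  expect_true(all(hits$stability_freq == 1))
  expect_true(all(hits$selected))
  expect_identical(sign(hits$theta[order(hits$marker_id)]),
                   sign(c(1, -0.8)[order(colnames(d)[c(5L, 20L)])]))
  # null markers almost never pass the 1e-4 per-repetition threshold
  nulls <- tab[!tab$marker_id %in% colnames(d)[c(5L, 20L)], ]
  expect_lt(mean(nulls$stability_freq), 0.05)
  expect_true(all(tab$stability_freq >= 0 & tab$stability_freq <= 1))
  # table is genome-sorted
  expect_identical(tab$marker_id,
                   tab$marker_id[order(tab$chrom, tab$pos)])
  # selection implies the stability threshold
  expect_true(all(tab$stability_freq[tab$selected] >= 0.8))
})

test_that("run_screen is deterministic and validates alignment", {
  coh <- small_cohort(seed = 51)
  xi <- impute_mean(qc_filter(coh$dosages)$dosages)
  cfg <- screen_config(n_rep = 2L, n_pcs = 5L, seed = 6L)
  t1 <- run_screen(xi, coh$phenotype, NULL, cfg)
  t2 <- run_screen(xi, coh$phenotype, NULL, cfg)
  expect_identical(t1, t2)
  expect_error(run_screen(xi, coh$phenotype[-1L], NULL, cfg), "missing")
})

test_that("the genomic inflation factor behaves analytically", {
  expect_equal(genomic_inflation(rep(0.5, 100L)), 1, tolerance = 1e-12)
  set.seed(16)
  expect_equal(genomic_inflation(stats::runif(10000L)), 1, tolerance = 0.03)
  expect_warning(l <- genomic_inflation(c(0, 0.5, 0.7)), "clamped")
  expect_true(is.finite(l))
  expect_error(genomic_inflation(numeric(0)), "no p-values")
})

test_that("the Bonferroni threshold is alpha over the marker count", {
  expect_equal(bonferroni_threshold(2434L), 0.05 / 2434)
  expect_equal(bonferroni_threshold(1L), 0.05)
  ms <- c(10L, 100L, 1000L, 10000L)
  expect_true(all(diff(bonferroni_threshold(ms)) < 0))
})

test_that("screening diagnostics are internally consistent", {
  coh <- small_cohort(seed = 52)
  xi <- impute_mean(qc_filter(coh$dosages)$dosages)
  tab <- run_screen(xi, coh$phenotype, NULL,
                    screen_config(n_rep = 2L, n_pcs = 5L, seed = 4L))
  rep_dir <- withr::local_tempdir()
  rep4 <- screening_report(tab, top_k = 5L, out_dir = rep_dir)
  expect_identical(nrow(rep4$qq), nrow(tab))
  expect_identical(rep4$volcano$significant, tab$p < 0.05)
  expect_true(all(abs(rep4$forest$ci_low -
                        (rep4$forest$theta - 1.96 *
                           tab$se[match(rep4$forest$marker_id,
                                        tab$marker_id)])) < 1e-12))
  expect_true(all(file.exists(file.path(
    rep_dir, c("manhattan.tsv", "qq.tsv", "volcano.tsv", "forest.tsv")))))
})
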