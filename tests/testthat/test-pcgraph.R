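test_that("partial correlation matches the regression-residual oracle", {
  set.seed(20)
  n <- 500L
  x <- matrix(stats::rnorm(n * 5L), n, 5L)
  x[, 2L] <- 0.6 * x[, 1L] + stats::rnorm(n)
  x[, 3L] <- -0.4 * x[, 2L] + 0.3 * x[, 1L] + stats::rnorm(n)
  colnames(x) <- paste0("v", 1:5)
  corr <- stats::cor(x)
  # S empty: the marginal correlation, exactly
  expect_identical(partial_correlation(corr, "v1", "v3"), corr["v1", "v3"])
  # regression-residual oracle for conditioning sets of size 1 and 2
  for (S in list("v2", c("v2", "v4"), c("v2", "v4", "v5"))) {
    r1 <- stats::lm.fit(cbind(1, x[, S, drop = FALSE]), x[, "v1"])$residuals
    r3 <- stats::lm.fit(cbind(1, x[, S, drop = FALSE]), x[, "v3"])$residuals
    expect_equal(partial_correlation(corr, "v1", "v3", S),
                 stats::cor(r1, r3), tolerance = 1e-10)
  }
})

test_that("a Gaussian chain is conditionally independent given its middle", {
  set.seed(21)
  n <- 2000L
  x <- stats::rnorm(n)
  z <- 0.8 * x + stats::rnorm(n)
  y <- 0.7 * z + stats::rnorm(n)
  corr <- stats::cor(cbind(x = x, z = z, y = y))
  expect_lt(abs(partial_correlation(corr, "x", "y", "z")), 0.05)
  expect_gt(abs(partial_correlation(corr, "x", "y")), 0.3)
})

test_that("Fisher's Z test reproduces its closed form", {
  nodes <- c("a", "b", "c")
  corr <- diag(3); dimnames(corr) <- list(nodes, nodes)
  ctx <- structure(list(corr = corr, n = 100L, alpha = 0.05, max_cond = 3L,
                        nodes = nodes), class = "ci_context")
  t0 <- fisher_z_test(ctx, "a", "b", "c")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  expect_true(t0$independent)

  ctx$corr["a", "b"] <- ctx$corr["b", "a"] <- 0.5
  t1 <- fisher_z_test(ctx, "a", "b", "c")
  expect_equal(t1$statistic, sqrt(96) * atanh(0.5), tolerance = 1e-9)
  expect_equal(t1$statistic, 5.382, tolerance = 1e-3)
  expect_equal(t1$p, 7.4e-8, tolerance = 0.02)
  expect_false(t1$independent)

  # p decreases monotonically in |rho| at fixed n and |S|
  ps <- vapply(seq(0.05, 0.9, by = 0.05), function(r) {
    ctx$corr["a", "b"] <- ctx$corr["b", "a"] <- r
    fisher_z_test(ctx, "a", "b", "c")$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("skeleton search recovers colliders and prunes chains", {
  set.seed(22)
  n <- 2000L
  a <- stats::rnorm(n); b <- stats::rnorm(n)
  yv <- 0.9 * a + 0.9 * b + stats::rnorm(n)
  sk <- learn_skeleton(cbind(A = a, B = b, Y = yv))
  expect_true(sk$adj["A", "Y"] && sk$adj["B", "Y"] && !sk$adj["A", "B"])
  expect_identical(sk$sepsets[["A|B"]], character(0))
  g <- orient_v_structures(sk)
  expect_true(snpdag:::is_directed_edge(g, "A", "Y"))
  expect_true(snpdag:::is_directed_edge(g, "B", "Y"))

  chain_b <- 0.9 * a + stats::rnorm(n)
  chain_y <- 0.9 * chain_b + stats::rnorm(n)
  sk2 <- learn_skeleton(cbind(A = a, B = chain_b, Y = chain_y))
  expect_true(sk2$adj["A", "B"] && sk2$adj["B", "Y"] && !sk2$adj["A", "Y"])
  expect_identical(sk2$sepsets[["A|Y"]], "B")
  g2 <- apply_meek_rules(orient_v_structures(sk2))
  expect_true(snpdag:::is_undirected_edge(g2, "A", "B"))
  expect_true(snpdag:::is_undirected_edge(g2, "B", "Y"))
})

test_that("mutually independent variables give a near-empty skeleton", {
  set.seed(23)
  edges <- vapply(1:40, function(i) {
    x <- matrix(stats::rnorm(600L * 3L), 600L, 3L,
                dimnames = list(NULL, c("a", "b", "c")))
    sum(learn_skeleton(x)$adj) / 2
  }, numeric(1))
  # each of the 3 pairs keeps its edge with prob ~alpha = 0.05
  expect_lt(mean(edges > 0), 0.35)
  expect_lt(mean(edges), 0.4)
})

test_that("Meek rules close orientations and are idempotent", {
  # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
  g <- cpdag_from_edges(c("a", "b", "c"),
                        directed = rbind(c("a", "b")),
                        undirected = rbind(c("b", "c")))
  m <- apply_meek_rules(g)
  expect_true(snpdag:::is_directed_edge(m, "b", "c"))
  # R2: a -> b -> c with a - c  =>  a -> c
  g2 <- cpdag_from_edges(c("a", "b", "c"),
                         directed = rbind(c("a", "b"), c("b", "c")),
                         undirected = rbind(c("a", "c")))
  m2 <- apply_meek_rules(g2)
  expect_true(snpdag:::is_directed_edge(m2, "a", "c"))
  # closure is a fixpoint
  expect_identical(apply_meek_rules(m2)$amat, m2$amat)
})

test_that("trait constraints forbid trait-outgoing edges", {
  g <- cpdag_from_edges(c("s1", "s2", "s3", "trait"),
                        directed = rbind(c("trait", "s1"), c("s2", "trait")),
                        undirected = rbind(c("s3", "trait")),
                        trait = "trait")
  e <- enforce_trait_constraints(g)
  expect_false(snpdag:::adjacent(e, "trait", "s1"))     # artifact deleted
  expect_true(snpdag:::is_directed_edge(e, "s2", "trait"))
  expect_true(snpdag:::is_directed_edge(e, "s3", "trait"))  # oriented inward
  expect_identical(sum(e$amat["trait", ]), 0L)
  expect_match(paste(e$log, collapse = ";"), "reverse edge")
  # a graph with no trait edges passes through unchanged
  g0 <- cpdag_from_edges(c("a", "b", "trait"),
                         directed = rbind(c("a", "b")), trait = "trait")
  expect_identical(enforce_trait_constraints(g0)$amat, g0$amat)
})

test_that("ancestral pruning keeps exactly the directed-path ancestors", {
  g <- cpdag_from_edges(c("A", "B", "C", "D", "trait"),
                        directed = rbind(c("A", "B"), c("B", "trait"),
                                         c("C", "D")),
                        trait = "trait")
  sub <- ancestral_subgraph(g)
  expect_setequal(sub$nodes, c("A", "B", "trait"))
  # star of parents: everything is retained
  star <- cpdag_from_edges(c("p1", "p2", "p3", "trait"),
                           directed = cbind(c("p1", "p2", "p3"), "trait"),
                           trait = "trait")
  expect_setequal(ancestral_subgraph(star)$nodes, star$nodes)
  # a node tied to the trait only through undirected edges is pruned under
  # the strict rule but retained under the permissive variant
  und <- cpdag_from_edges(c("u", "m", "trait"),
                          directed = rbind(c("m", "trait")),
                          undirected = rbind(c("u", "m")), trait = "trait")
  expect_setequal(ancestral_subgraph(und)$nodes, c("m", "trait"))
  expect_setequal(ancestral_subgraph(und, include_undirected = TRUE)$nodes,
                  c("u", "m", "trait"))
  iso <- cpdag_from_edges(c("a", "trait"), trait = "trait")
  expect_warning(s2 <- ancestral_subgraph(iso), "isolated")
  expect_identical(s2$nodes, "trait")
})

test_that("with a d-separation oracle the learner is exact on random DAGs", {
  set.seed(24)
  for (n in c(4L, 5L)) {
    for (rep in 1:15) {
      a <- random_dag(n, p_edge = 0.45)
      g <- learn_cpdag(indep = ci_oracle(a), nodes = rownames(a),
                       max_cond = n - 2L)
      expect_true(cpdag_equal(g, brute_cpdag(a)),
                  label = sprintf("oracle CPDAG, n=%d rep=%d", n, rep))
    }
  }
})

test_that("an LD proxy is screened off by its causal neighbour", {
  set.seed(25)
  n <- 2000L
  causal <- stats::rnorm(n)
  proxy <- 0.8 * causal + 0.6 * stats::rnorm(n)   # r ~ 0.8
  yv <- 0.5 * causal + stats::rnorm(n)
  g <- learn_graph(cbind(causal = causal, proxy = proxy, trait = yv),
                   "trait", include_undirected = TRUE)
  expect_false("proxy" %in% g$nodes &&
                 snpdag:::adjacent(g, "proxy", "trait"))
  expect_true(snpdag:::is_directed_edge(g, "causal", "trait"))
})

test_that("pure-noise markers leave the trait essentially isolated", {
  set.seed(26)
  n <- 800L
  x <- matrix(stats::rnorm(n * 8L), n, 8L,
              dimnames = list(NULL, paste0("s", 1:8)))
  dat <- cbind(x, trait = stats::rnorm(n))
  g <- learn_graph(dat, "trait", include_undirected = TRUE)
  # expected false-parent count ~ alpha * k; allow a small margin
  expect_lte(length(g$nodes) - 1L, 3L)
})

test_that("consistent extension orients every edge without new colliders", {
  g <- cpdag_from_edges(c("h", "m1", "m2", "trait"),
                        directed = rbind(c("m1", "trait"), c("m2", "trait")),
                        undirected = rbind(c("h", "m1"), c("h", "m2")))
  dag <- consistent_extension(g)
  und <- sum(dag$amat == 1L & t(dag$amat) == 1L)
  expect_identical(und, 0L)
  expect_true(is_acyclic(dag$amat))
  # no new v-structure at h's neighbours: m1 and m2 must not both point at h
  expect_false(snpdag:::is_directed_edge(dag, "m1", "h") &&
                 snpdag:::is_directed_edge(dag, "m2", "h"))
})

test_that("structural Hamming distance counts pairwise edge differences", {
  g1 <- cpdag_from_edges(c("a", "b", "c"), directed = rbind(c("a", "b")))
  expect_identical(shd(g1, g1), 0L)
  g2 <- cpdag_from_edges(c("a", "b", "c"), directed = rbind(c("b", "a")))
  expect_identical(shd(g1, g2), 1L)               # reorientation
  g3 <- cpdag_from_edges(c("a", "b", "c"),
                         directed = rbind(c("a", "b"), c("b", "c")))
  expect_identical(shd(g1, g3), 1L)               # insertion
})
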