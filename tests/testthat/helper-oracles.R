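# Independent oracles and small fixtures, built in code at test time.

# ---- DAG enumeration / sampling -------------------------------------------

# all labelled DAGs on n nodes (feasible for n <= 4): every unordered pair is
# absent, low->high, or high->low; keep the acyclic ones
enumerate_dags <- function(n) {
  nodes <- paste0("n", seq_len(n))
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  out <- list()
  for (code in 0:(3^np - 1)) {
    a <- matrix(0L, n, n, dimnames = list(nodes, nodes))
    c0 <- code
    for (p in seq_len(np)) {
      s <- c0 %% 3; c0 <- c0 %/% 3
      i <- pairs[1, p]; j <- pairs[2, p]
      if (s == 1) a[i, j] <- 1L else if (s == 2) a[j, i] <- 1L
    }
    if (is_acyclic(a)) out[[length(out) + 1L]] <- a
  }
  out
}

random_dag <- function(n, p_edge = 0.4) {
  nodes <- paste0("n", seq_len(n))
  a <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  perm <- sample(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p_edge) a[perm[i], perm[j]] <- 1L
  a
}

# repeatedly strip sinks; a cycle leaves a sink-free nonempty subgraph
is_acyclic <- function(a) {
  a <- (a != 0) * 1L
  while (nrow(a) > 0) {
    sinks <- which(rowSums(a) == 0)
    if (!length(sinks)) return(FALSE)
    a <- a[-sinks, -sinks, drop = FALSE]
  }
  TRUE
}

# ---- brute-force Markov-equivalence oracle --------------------------------

v_structures_of <- function(a) {
  nodes <- rownames(a)
  out <- character(0)
  for (k in seq_len(ncol(a))) {
    pa <- which(a[, k] == 1L)
    if (length(pa) < 2L) next
    for (u in seq_along(pa)) for (v in seq_along(pa)) {
      if (u >= v) next
      i <- pa[u]; j <- pa[v]
      if (a[i, j] == 0L && a[j, i] == 0L) {
        ij <- sort(c(nodes[i], nodes[j]))
        out <- c(out, paste(ij[1], nodes[k], ij[2], sep = ">"))
      }
    }
  }
  sort(out)
}

# CPDAG of a DAG by enumerating every acyclic orientation of its skeleton
# with identical v-structures and taking the union of edge marks — fully
# independent of the package's Meek-rule implementation
brute_cpdag <- function(a) {
  nodes <- rownames(a)
  n <- nrow(a)
  idx <- which((a + t(a)) > 0 & upper.tri(a), arr.ind = TRUE)
  ne <- nrow(idx)
  vs <- v_structures_of(a)
  marks <- matrix(0L, n, n, dimnames = dimnames(a))
  for (code in 0:(2^ne - 1)) {
    cand <- matrix(0L, n, n, dimnames = dimnames(a))
    c0 <- code
    for (e in seq_len(ne)) {
      b <- c0 %% 2; c0 <- c0 %/% 2
      i <- idx[e, 1]; j <- idx[e, 2]
      if (b == 0) cand[i, j] <- 1L else cand[j, i] <- 1L
    }
    if (!is_acyclic(cand)) next
    if (!identical(v_structures_of(cand), vs)) next
    marks <- pmax(marks, cand)
  }
  snpdag::cpdag(nodes, amat = marks)
}

cpdag_equal <- function(g1, g2) {
  identical(sort(g1$nodes), sort(g2$nodes)) &&
    all(g1$amat[g1$nodes, g1$nodes] == g2$amat[g1$nodes, g1$nodes])
}

# ---- shared small cohorts --------------------------------------------------

small_cohort <- function(seed = 1, ...) {
  simulate_cohort(sim_config(n_individuals = 200L, n_markers = 300L,
                             seed = seed, ...))
}
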