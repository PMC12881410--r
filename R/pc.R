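# Constraint-based structure learning: Fisher-Z conditional-independence
# testing on (partial) correlations, PC-stable skeleton discovery,
# v-structure orientation from separation sets, Meek closure, and the
# end-to-end learner over selected markers plus the trait.

#' Conditional-independence test context
#'
#' @param data numeric matrix (columns = nodes); columns are standardised
#'   internally before the correlation matrix is formed.
#' @param alpha test level, default 0.05.
#' @param max_cond maximum conditioning-set size, default 3.
#' @return object of class `ci_context` holding the correlation matrix,
#'   sample size, level and conditioning bound.
#' @export
ci_context <- function(data, alpha = 0.05, max_cond = 3L) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) colnames(data) <- paste0("V", seq_len(ncol(data)))
  n <- nrow(data)
  if (n <= max_cond + 3L) stopf("need n > max_cond + 3 (n = %d)", n)
  corr <- stats::cor(standardize_cols(data)$x)
  corr[!is.finite(corr)] <- 0
  structure(list(corr = corr, n = n, alpha = alpha,
                 max_cond = as.integer(max_cond), nodes = colnames(data)),
            class = "ci_context")
}

#' Partial correlation from a correlation matrix
#'
#' Partial correlation of nodes `i` and `j` given the set `S`, via inversion
#' of the (i, j, S) correlation submatrix:
#' `rho = -Omega_ij / sqrt(Omega_ii * Omega_jj)`. The result is clamped away
#' from +/-1. A numerically singular submatrix is treated as degenerate and
#' returns 0 (independence), matching the conservative convention for
#' collinear conditioning sets.
#'
#' @param corr correlation matrix with dimnames.
#' @param i,j node names or indices.
#' @param S conditioning nodes (names or indices), excluding `i` and `j`.
#' @return partial correlation in (-1, 1).
#' @export
partial_correlation <- function(corr, i, j, S = character(0)) {
  if (!length(S)) {
    rho <- corr[i, j]
  } else {
    sub <- corr[c(i, j, S), c(i, j, S), drop = FALSE]
    omega <- tryCatch(solve(sub), error = function(e) NULL)
    if (is.null(omega) || !all(is.finite(omega))) return(0)
    rho <- -omega[1L, 2L] / sqrt(omega[1L, 1L] * omega[2L, 2L])
    if (!is.finite(rho)) return(0)
  }
  max(min(rho, 1 - 1e-12), -1 + 1e-12)
}

#' Fisher's Z conditional-independence test
#'
#' Tests `i` independent of `j` given `S` through the variance-stabilised
#' partial correlation: `z = atanh(rho)`,
#' `statistic = sqrt(n - |S| - 3) * |z|`, two-sided normal p-value.
#' Independence is declared when `p > alpha`.
#'
#' @param ctx a [ci_context()].
#' @param i,j node names.
#' @param S conditioning set (character vector).
#' @return list with `statistic`, `p`, `independent`, `rho`.
#' @export
fisher_z_test <- function(ctx, i, j, S = character(0)) {
  df <- ctx$n - length(S) - 3L
  if (df <= 0L) stopf("sample size too small for |S| = %d", length(S))
  rho <- partial_correlation(ctx$corr, i, j, S)
  z <- atanh(rho)
  statistic <- sqrt(df) * abs(z)
  p <- 2 * stats::pnorm(-statistic)
  list(statistic = statistic, p = p, independent = p > ctx$alpha, rho = rho)
}

# all size-ell subsets of `pool`, in lexicographic order, as a list
subsets_of <- function(pool, ell) {
  if (ell == 0L) return(list(character(0)))
  if (length(pool) < ell) return(list())
  cmb <- utils::combn(pool, ell, simplify = FALSE)
  cmb
}

#' PC-stable skeleton search with a pluggable CI test
#'
#' For conditioning sizes `ell = 0..max_cond`, every currently adjacent pair
#' is tested against all size-`ell` subsets of the level-frozen adjacency
#' sets of each endpoint; an edge is removed (and the separating set
#' recorded) at the first independence. Freezing adjacencies per level makes
#' the result independent of node ordering; nodes are processed in input
#' order and subsets lexicographically, so the search is deterministic.
#'
#' @param nodes character node names.
#' @param indep `function(i, j, S)` returning `TRUE` for independence.
#' @param max_cond maximum conditioning-set size.
#' @return object of class `skeleton`: `nodes`, symmetric logical `adj`, and
#'   `sepsets` keyed "i|j".
#' @export
learn_skeleton_ci <- function(nodes, indep, max_cond = 3L) {
  if (length(nodes) < 2L) stopf("need at least 2 nodes")
  nn <- length(nodes)
  adj <- matrix(TRUE, nn, nn, dimnames = list(nodes, nodes))
  diag(adj) <- FALSE
  sepsets <- list()
  for (ell in 0:max_cond) {
    frozen <- adj
    if (max(colSums(frozen)) - 1L < ell) break
    for (ii in seq_len(nn)) for (jj in seq_len(nn)) {
      if (ii == jj || !adj[ii, jj]) next
      i <- nodes[ii]; j <- nodes[jj]
      pool <- nodes[frozen[ii, ]]
      pool <- setdiff(pool, j)
      done <- FALSE
      for (S in subsets_of(pool, ell)) {
        if (indep(i, j, S)) {
          adj[ii, jj] <- adj[jj, ii] <- FALSE
          sepsets[[sepset_key(i, j)]] <- S
          done <- TRUE
          break
        }
      }
      if (done) next
    }
  }
  structure(list(nodes = nodes, adj = adj, sepsets = sepsets),
            class = "skeleton")
}

#' Skeleton discovery from data with Fisher's Z tests
#'
#' @param data matrix over candidate nodes (and the trait), complete.
#' @param alpha test level, default 0.05.
#' @param max_cond maximum conditioning-set size, default 3.
#' @return a `skeleton` (with the `ci_context` attached as an attribute).
#' @export
learn_skeleton <- function(data, alpha = 0.05, max_cond = 3L) {
  ctx <- ci_context(data, alpha = alpha, max_cond = max_cond)
  indep <- function(i, j, S) fisher_z_test(ctx, i, j, S)$independent
  sk <- learn_skeleton_ci(ctx$nodes, indep, max_cond = max_cond)
  attr(sk, "ctx") <- ctx
  sk
}

#' Orient v-structures from separation sets
#'
#' For every unshielded triple i - k - j (i, j non-adjacent), orients
#' `i -> k <- j` iff `k` is absent from sepset(i, j). Conflicting
#' orientations between overlapping v-structures are resolved
#' first-writer-wins in deterministic node order; conflicts are logged on
#' the returned graph.
#'
#' @param skel a `skeleton`.
#' @return a `cpdag` with v-structures directed, remaining edges undirected.
#' @export
orient_v_structures <- function(skel) {
  nodes <- skel$nodes
  g <- cpdag(nodes, amat = skel$adj * 1L, sepsets = skel$sepsets)
  nn <- length(nodes)
  for (kk in seq_len(nn)) {
    nb <- which(skel$adj[kk, ])
    if (length(nb) < 2L) next
    for (u in seq_along(nb)) for (v in seq_along(nb)) {
      if (u >= v) next
      ii <- nb[u]; jj <- nb[v]
      if (skel$adj[ii, jj]) next  # shielded
      i <- nodes[ii]; j <- nodes[jj]; k <- nodes[kk]
      ss <- skel$sepsets[[sepset_key(i, j)]]
      if (!is.null(ss) && k %in% ss) next
      for (arm in c(i, j)) {
        if (is_undirected_edge(g, arm, k)) {
          g$amat[k, arm] <- 0L  # arm -> k
        } else if (is_directed_edge(g, k, arm)) {
          g$log <- c(g$log,
            sprintf("v-structure conflict at %s: kept %s -> %s", k, k, arm))
        }
      }
    }
  }
  g
}

#' Learn the CPDAG over a set of variables
#'
#' Skeleton discovery, v-structure orientation and Meek closure; no trait
#' constraints. With a conditional-independence oracle in place of the
#' Fisher-Z test (`indep` argument), this recovers the exact Markov
#' equivalence class of the generating DAG.
#'
#' @param data matrix over the nodes (ignored when `indep` is supplied
#'   together with `nodes`).
#' @param alpha Fisher-Z level, default 0.05.
#' @param max_cond maximum conditioning-set size, default 3.
#' @param indep optional CI-test function `(i, j, S) -> logical` (e.g. from
#'   [ci_oracle()]).
#' @param nodes node names, required when `indep` is supplied without data.
#' @return a `cpdag`.
#' @export
learn_cpdag <- function(data = NULL, alpha = 0.05, max_cond = 3L,
                        indep = NULL, nodes = NULL) {
  sk <- if (is.null(indep)) {
    learn_skeleton(data, alpha = alpha, max_cond = max_cond)
  } else {
    if (is.null(nodes)) nodes <- colnames(data)
    learn_skeleton_ci(nodes, indep, max_cond = max_cond)
  }
  apply_meek_rules(orient_v_structures(sk))
}

#' End-to-end causal graph over selected markers and the trait
#'
#' Runs the full constraint-based pipeline: PC-stable skeleton with Fisher-Z
#' tests, v-structure orientation, Meek closure, trait-direction constraints
#' (no trait-outgoing edges), and ancestral-subgraph extraction. Fully
#' deterministic.
#'
#' @param data matrix whose columns are the selected markers plus the trait.
#' @param trait trait column name.
#' @param alpha Fisher-Z level, default 0.05.
#' @param max_cond maximum conditioning-set size, default 3.
#' @param include_undirected traverse undirected edges during ancestral
#'   pruning (permissive variant), default `FALSE` (strict directed paths).
#' @param residualize regress each marker column on `covariates` before
#'   graph learning, default `FALSE` (raw dosages).
#' @param covariates optional covariate matrix for `residualize`.
#' @return a `cpdag` containing the trait and its (generalised) ancestors.
#' @export
learn_graph <- function(data, trait, alpha = 0.05, max_cond = 3L,
                        include_undirected = FALSE, residualize = FALSE,
                        covariates = NULL) {
  data <- as.matrix(data)
  if (!trait %in% colnames(data)) stopf("trait column '%s' not in data", trait)
  if (residualize) {
    if (is.null(covariates)) stopf("residualize = TRUE needs covariates")
    xmat <- cbind(1, as.matrix(covariates))
    for (j in setdiff(colnames(data), trait))
      data[, j] <- stats::lm.fit(xmat, data[, j])$residuals
  }
  g <- learn_cpdag(data, alpha = alpha, max_cond = max_cond)
  g$trait <- trait
  g <- enforce_trait_constraints(g, trait)
  ancestral_subgraph(g, trait, include_undirected = include_undirected)
}
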