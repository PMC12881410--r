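# Partially directed graph (CPDAG) machinery. The adjacency matrix `amat`
# uses arrowhead marks: amat[i, j] == 1 means the edge mark i -> j is
# present. A directed edge i -> j has amat[i, j] == 1, amat[j, i] == 0; an
# undirected edge has both marks set.

#' Construct a partially directed graph
#'
#' @param nodes character vector of node names.
#' @param amat optional square 0/1 mark matrix (see details in the package
#'   vignette); defaults to the empty graph.
#' @param sepsets optional separation-set list keyed "i|j" (sorted).
#' @param trait optional distinguished trait node name.
#' @return object of class `cpdag`.
#' @export
cpdag <- function(nodes, amat = NULL, sepsets = list(), trait = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stopf("duplicate node names")
  if (is.null(amat)) {
    amat <- matrix(0L, length(nodes), length(nodes),
                   dimnames = list(nodes, nodes))
  } else {
    amat <- as.matrix(amat) * 1L
    dimnames(amat) <- list(nodes, nodes)
    diag(amat) <- 0L
  }
  structure(list(nodes = nodes, amat = amat, sepsets = sepsets,
                 trait = trait, log = character(0)), class = "cpdag")
}

sepset_key <- function(i, j) paste(sort(c(i, j)), collapse = "|")

#' Build a cpdag from explicit edge lists
#'
#' @param nodes node names.
#' @param directed two-column matrix/data.frame of directed edges (from, to).
#' @param undirected two-column matrix/data.frame of undirected edges.
#' @param trait optional trait node.
#' @return a `cpdag`.
#' @export
cpdag_from_edges <- function(nodes, directed = NULL, undirected = NULL,
                             trait = NULL) {
  g <- cpdag(nodes, trait = trait)
  if (!is.null(directed) && NROW(directed)) {
    directed <- as.matrix(directed)
    for (e in seq_len(nrow(directed)))
      g$amat[directed[e, 1], directed[e, 2]] <- 1L
  }
  if (!is.null(undirected) && NROW(undirected)) {
    undirected <- as.matrix(undirected)
    for (e in seq_len(nrow(undirected))) {
      g$amat[undirected[e, 1], undirected[e, 2]] <- 1L
      g$amat[undirected[e, 2], undirected[e, 1]] <- 1L
    }
  }
  g
}

adjacent <- function(g, i, j) g$amat[i, j] == 1L || g$amat[j, i] == 1L
is_directed_edge <- function(g, i, j) g$amat[i, j] == 1L && g$amat[j, i] == 0L
is_undirected_edge <- function(g, i, j) g$amat[i, j] == 1L && g$amat[j, i] == 1L

#' Edge table of a cpdag
#'
#' @param g a `cpdag`.
#' @return data.frame with `from`, `to`, `directed`; undirected edges appear
#'   once with lexicographically sorted endpoints.
#' @export
cpdag_edges <- function(g) {
  a <- g$amat
  out <- list()
  nodes <- g$nodes
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (a[i, j] == 1L && a[j, i] == 0L)
      out[[length(out) + 1L]] <- data.frame(from = nodes[i], to = nodes[j],
                                            directed = TRUE)
    else if (i < j && a[i, j] == 1L && a[j, i] == 1L)
      out[[length(out) + 1L]] <- data.frame(from = nodes[i], to = nodes[j],
                                            directed = FALSE)
  }
  if (!length(out))
    return(data.frame(from = character(0), to = character(0),
                      directed = logical(0)))
  do.call(rbind, out)
}

#' @method print cpdag
#' @export
print.cpdag <- function(x, ...) {
  e <- cpdag_edges(x)
  cat(sprintf("cpdag: %d nodes, %d directed / %d undirected edges%s\n",
              length(x$nodes), sum(e$directed), sum(!e$directed),
              if (!is.null(x$trait)) paste0(" (trait: ", x$trait, ")") else ""))
  invisible(x)
}

# directed-part reachability: can we reach `to` from `from` along directed
# edges (optionally also undirected ones)?
reachable_to <- function(g, to, include_undirected = FALSE) {
  a <- g$amat
  dir_in <- a == 1L & t(a) == 0L          # dir_in[i, j]: i -> j
  und <- a == 1L & t(a) == 1L
  step <- dir_in | (if (include_undirected) und | t(und) else FALSE)
  # nodes with a path  v -> ... -> to ; BFS backwards from `to`
  seen <- stats::setNames(rep(FALSE, length(g$nodes)), g$nodes)
  queue <- to
  seen[to] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    preds <- g$nodes[step[, cur]]
    new <- preds[!seen[preds]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  names(seen)[seen]
}

has_directed_path <- function(g, from, to) from %in% reachable_to(g, to)

# would orienting i -> j (on an existing undirected edge) create a directed
# cycle, i.e. is there already a directed path j => i?
creates_cycle <- function(g, i, j) has_directed_path(g, j, i)

#' Apply Meek's orientation rules to closure
#'
#' Propagates edge orientations (rules R1-R4) until no rule fires, never
#' creating a new v-structure or a directed cycle. Safe to call repeatedly
#' (idempotent once closed).
#'
#' @param g a `cpdag` with v-structures (and any background orientations)
#'   already in place.
#' @return the closed `cpdag`.
#' @export
apply_meek_rules <- function(g) {
  n <- length(g$nodes)
  repeat {
    changed <- FALSE
    a <- g$amat
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (!(a[i, j] == 1L && a[j, i] == 1L)) next  # need undirected i - j
      orient <- FALSE
      # R1: k -> i, i - j, k and j non-adjacent  =>  i -> j
      for (k in seq_len(n)) {
        if (a[k, i] == 1L && a[i, k] == 0L &&
            a[k, j] == 0L && a[j, k] == 0L) { orient <- TRUE; break }
      }
      # R2: i -> k -> j and i - j  =>  i -> j
      if (!orient) for (k in seq_len(n)) {
        if (a[i, k] == 1L && a[k, i] == 0L &&
            a[k, j] == 1L && a[j, k] == 0L) { orient <- TRUE; break }
      }
      # R3: i - k, i - l, k -> j, l -> j, k and l non-adjacent  =>  i -> j
      if (!orient) {
        ks <- which(a[i, ] == 1L & a[, i] == 1L &
                    a[, j] == 1L & a[j, ] == 0L)
        if (length(ks) >= 2L) {
          for (u in seq_along(ks)) for (v in seq_along(ks)) {
            if (u < v && a[ks[u], ks[v]] == 0L && a[ks[v], ks[u]] == 0L) {
              orient <- TRUE; break
            }
          }
        }
      }
      # R4: i - k (adjacent), k -> l, l -> j, i adjacent to l,
      #     k and j non-adjacent  =>  i -> j
      if (!orient) {
        for (k in seq_len(n)) {
          if (!(a[i, k] == 1L || a[k, i] == 1L)) next
          if (a[k, j] == 1L || a[j, k] == 1L) next
          ls <- which(a[k, ] == 1L & a[, k] == 0L &   # k -> l
                      a[, j] == 1L & a[j, ] == 0L &   # l -> j
                      (a[i, ] == 1L | a[, i] == 1L))  # i adjacent l
          if (length(ls)) { orient <- TRUE; break }
        }
      }
      if (orient && !creates_cycle(g, g$nodes[i], g$nodes[j])) {
        g$amat[g$nodes[j], g$nodes[i]] <- 0L
        changed <- TRUE
        a <- g$amat
      }
    }
    if (!changed) break
  }
  g
}

#' Remove trait-outgoing edges and orient trait-adjacent edges
#'
#' Germline genotypes cannot be altered by the phenotype, so any directed
#' trait-to-SNP edge is a statistical artifact: such edges are deleted
#' (logged), every undirected trait-SNP edge is oriented SNP-to-trait, and
#' Meek's rules are re-applied. The trait has out-degree 0 afterwards.
#'
#' @param g a `cpdag`.
#' @param trait trait node name (defaults to `g$trait`).
#' @return the constrained `cpdag`.
#' @export
enforce_trait_constraints <- function(g, trait = g$trait) {
  if (is.null(trait) || !trait %in% g$nodes) stopf("trait node not in graph")
  for (s in setdiff(g$nodes, trait)) {
    if (is_directed_edge(g, trait, s)) {
      g$amat[trait, s] <- 0L
      g$log <- c(g$log, sprintf("removed reverse edge %s -> %s", trait, s))
    } else if (is_undirected_edge(g, trait, s)) {
      g$amat[trait, s] <- 0L  # keep s -> trait
    }
  }
  g <- apply_meek_rules(g)
  g$trait <- trait
  g
}

#' Ancestral subgraph of the trait
#'
#' Keeps the trait plus every node with a path to the trait. By default only
#' directed edges are traversed (the strict reading of "a directed path to
#' the phenotype"); `include_undirected = TRUE` also traverses undirected
#' CPDAG edges, the permissive variant that retains upstream nodes whose
#' edges are unoriented within the equivalence class.
#'
#' @param g a `cpdag` with trait constraints enforced.
#' @param trait trait node name.
#' @param include_undirected traverse undirected edges too, default `FALSE`.
#' @return the induced `cpdag` on the retained nodes.
#' @export
ancestral_subgraph <- function(g, trait = g$trait,
                               include_undirected = FALSE) {
  if (is.null(trait) || !trait %in% g$nodes) stopf("trait node not in graph")
  keep <- reachable_to(g, trait, include_undirected = include_undirected)
  if (identical(keep, trait))
    warnf("trait is isolated: ancestral subgraph contains only the trait")
  keep <- g$nodes[g$nodes %in% keep]
  out <- cpdag(keep, amat = g$amat[keep, keep, drop = FALSE],
               sepsets = g$sepsets, trait = trait)
  out$log <- g$log
  out
}

#' Deterministic consistent extension of a CPDAG to a DAG
#'
#' Orients every undirected edge without creating directed cycles or new
#' v-structures where possible (Dor-Tarsi sink elimination, processing nodes
#' in name order). If no valid sink exists at some step, the
#' lexicographically smallest remaining undirected edge is oriented
#' low-to-high and the event is logged.
#'
#' @param g a `cpdag`.
#' @return a `cpdag` whose edges are all directed.
#' @export
consistent_extension <- function(g) {
  a <- g$amat
  nodes <- g$nodes
  remaining <- nodes
  res <- a
  while (length(remaining)) {
    picked <- NULL
    for (x in remaining) {
      others <- setdiff(remaining, x)
      # sink: no directed out-edge within remaining
      out_dir <- others[a[x, others] == 1L & a[others, x] == 0L]
      if (length(out_dir)) next
      und <- others[a[x, others] == 1L & a[others, x] == 1L]
      adj <- others[a[x, others] == 1L | a[others, x] == 1L]
      ok <- all(vapply(und, function(u)
        all(vapply(setdiff(adj, u), function(v)
          a[u, v] == 1L || a[v, u] == 1L, logical(1))), logical(1)))
      if (ok) { picked <- x; break }
    }
    if (is.null(picked)) {
      # degenerate input (not extendable): orient smallest undirected edge
      und_idx <- which(a == 1L & t(a) == 1L, arr.ind = TRUE)
      und_idx <- und_idx[und_idx[, 1] < und_idx[, 2], , drop = FALSE]
      if (!nrow(und_idx)) break
      i <- und_idx[1, 1]; j <- und_idx[1, 2]
      res[nodes[j], nodes[i]] <- 0L; a[nodes[j], nodes[i]] <- 0L
      g$log <- c(g$log, sprintf("non-extendable PDAG: forced %s -> %s",
                                nodes[i], nodes[j]))
      next
    }
    others <- setdiff(remaining, picked)
    und <- others[a[picked, others] == 1L & a[others, picked] == 1L]
    for (u in und) res[picked, u] <- 0L  # orient u -> picked
    remaining <- setdiff(remaining, picked)
    a <- res
    gone <- !(nodes %in% remaining)
    a[gone, ] <- 0L
    a[, gone] <- 0L
  }
  out <- g
  out$amat <- res
  out
}

#' d-separation in a DAG
#'
#' Classic moralisation test: restrict to the ancestors of `i`, `j` and `S`,
#' moralise (marry parents of common children, drop directions), remove `S`,
#' and test connectivity of `i` and `j`.
#'
#' @param amat DAG adjacency matrix (`amat[i, j] = 1` for edge i -> j) with
#'   dimnames.
#' @param i,j node names.
#' @param S character vector of conditioning nodes (may be empty).
#' @return `TRUE` if `i` and `j` are d-separated given `S`.
#' @export
dseparated <- function(amat, i, j, S = character(0)) {
  nodes <- rownames(amat)
  anc <- function(targets) {
    seen <- targets
    queue <- targets
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      pa <- nodes[amat[, cur] == 1L]
      new <- setdiff(pa, seen)
      seen <- c(seen, new); queue <- c(queue, new)
    }
    seen
  }
  keep <- anc(unique(c(i, j, S)))
  a <- amat[keep, keep, drop = FALSE]
  moral <- (a + t(a)) > 0
  # marry parents of each node
  for (v in seq_len(ncol(a))) {
    pa <- which(a[, v] == 1L)
    if (length(pa) >= 2L) moral[pa, pa] <- TRUE
  }
  diag(moral) <- FALSE
  keep2 <- setdiff(keep, S)
  moral <- moral[keep2, keep2, drop = FALSE]
  # connectivity between i and j
  seen <- i
  queue <- i
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    nb <- keep2[moral[cur, ]]
    if (j %in% nb) return(FALSE)
    new <- setdiff(nb, seen)
    seen <- c(seen, new); queue <- c(queue, new)
  }
  TRUE
}

#' Conditional-independence oracle from a known DAG
#'
#' Wraps [dseparated()] as a CI-test function usable by the PC skeleton
#' search, for structure-recovery benchmarking against a known truth graph.
#'
#' @param amat DAG adjacency matrix with dimnames.
#' @return `function(i, j, S)` returning `TRUE` when `i` and `j` are
#'   independent (d-separated) given `S`.
#' @export
ci_oracle <- function(amat) {
  force(amat)
  function(i, j, S = character(0)) dseparated(amat, i, j, S)
}

#' CPDAG of a DAG
#'
#' Computes the Markov equivalence class representative of a DAG: skeleton
#' plus v-structures, closed under Meek's rules.
#'
#' @param amat DAG adjacency matrix (`amat[i, j] = 1` for i -> j).
#' @return a `cpdag`.
#' @export
dag_to_cpdag <- function(amat) {
  nodes <- rownames(amat)
  g <- cpdag(nodes)
  g$amat <- ((amat + t(amat)) > 0) * 1L  # skeleton, all undirected
  # orient v-structures i -> k <- j with i, j non-adjacent
  for (k in seq_along(nodes)) {
    pa <- which(amat[, k] == 1L)
    if (length(pa) < 2L) next
    for (u in seq_along(pa)) for (v in seq_along(pa)) {
      if (u >= v) next
      i <- pa[u]; j <- pa[v]
      if (amat[i, j] == 0L && amat[j, i] == 0L) {
        g$amat[k, i] <- 0L
        g$amat[k, j] <- 0L
      }
    }
  }
  apply_meek_rules(g)
}

#' Structural Hamming distance between two partially directed graphs
#'
#' Counts node pairs whose edge status differs (absent / undirected /
#' directed either way), over the union of the two node sets.
#'
#' @param g1,g2 `cpdag` objects.
#' @return non-negative integer.
#' @export
shd <- function(g1, g2) {
  nodes <- union(g1$nodes, g2$nodes)
  code <- function(g) {
    a <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    a[g$nodes, g$nodes] <- g$amat
    a
  }
  a1 <- code(g1); a2 <- code(g2)
  d <- 0L
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    e1 <- c(a1[i, j], a1[j, i]); e2 <- c(a2[i, j], a2[j, i])
    if (!all(e1 == e2)) d <- d + 1L
  }
  d
}

#' Convert a cpdag to an igraph object
#'
#' Directed edges become arcs; undirected edges become single arcs (sorted
#' endpoints) flagged with edge attribute `directed = FALSE`.
#'
#' @param g a `cpdag`.
#' @return an igraph directed graph.
#' @export
as_igraph <- function(g) {
  e <- cpdag_edges(g)
  ig <- igraph::graph_from_data_frame(e, directed = TRUE,
                                      vertices = data.frame(name = g$nodes))
  ig
}
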