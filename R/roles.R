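# Topological role classification of the final graph: direct parent SNPs
# (DPSs, the trait's Markov blanket once the trait has no children) versus
# upstream hub SNPs (UHSs, high out-degree regulators acting through
# mediators), plus Table-style edge weights and out-degree rankings.

# out-degree used for hub ranking: directed out-edges plus undirected
# (orientable) incident edges, excluding any edge involving the trait.
node_out_degree <- function(g, node, trait = g$trait) {
  others <- setdiff(g$nodes, c(node, trait))
  sum(vapply(others, function(v)
    is_directed_edge(g, node, v) || is_undirected_edge(g, node, v),
    logical(1)))
}

node_total_degree <- function(g, node) {
  sum(vapply(setdiff(g$nodes, node), function(v) adjacent(g, node, v),
             logical(1)))
}

#' Classify graph nodes into direct parents and upstream hubs
#'
#' Direct parent SNPs (DPSs) are the nodes with a directed edge into the
#' trait; with the trait constrained to have no children, they are its
#' Markov blanket. Upstream hub SNPs (UHSs) are non-parent nodes with
#' out-degree at least `uhs_min_out_degree`, where out-degree counts
#' directed out-edges plus undirected incident edges (orientable outward
#' within the equivalence class), never edges involving the trait. Remaining
#' nodes are labelled `other`. Ties are broken deterministically by
#' (out-degree desc, total degree desc, marker id asc).
#'
#' @param g final `cpdag` (trait constraints enforced).
#' @param trait trait node name.
#' @param uhs_min_out_degree minimum out-degree for the hub label, default 2.
#' @return data.frame of class `role_table`: `marker_id`, `role`
#'   (`DPS`/`UHS`/`other`), `out_degree`, `edge_weight_to_child` (filled by
#'   [edge_weights()]), `rank` (within role).
#' @export
classify_roles <- function(g, trait = g$trait, uhs_min_out_degree = 2L) {
  if (is.null(trait) || !trait %in% g$nodes) stopf("trait node not in graph")
  snps <- setdiff(g$nodes, trait)
  dps <- snps[vapply(snps, function(s) is_directed_edge(g, s, trait),
                     logical(1))]
  outd <- vapply(snps, function(s) node_out_degree(g, s, trait), numeric(1))
  totd <- vapply(snps, function(s) node_total_degree(g, s), numeric(1))
  role <- ifelse(snps %in% dps, "DPS",
                 ifelse(outd >= uhs_min_out_degree, "UHS", "other"))
  ord <- order(-outd, -totd, snps)
  tab <- data.frame(marker_id = snps[ord], role = role[ord],
                    out_degree = as.integer(outd[ord]),
                    edge_weight_to_child = NA_real_,
                    stringsAsFactors = FALSE)
  tab$rank <- stats::ave(seq_len(nrow(tab)), tab$role, FUN = seq_along)
  class(tab) <- c("role_table", "data.frame")
  attr(tab, "trait") <- trait
  tab
}

#' Annotate graph edges with standardised effect weights
#'
#' The CPDAG is first extended to one member DAG ([consistent_extension()],
#' deterministic, logged). Each child node is then regressed on its DAG
#' parents with all variables standardised; the weight of an edge is the
#' absolute standardised coefficient of its parent — a direct-effect
#' magnitude comparable across edges. Collinear parent sets fall back to a
#' ridge solve (penalty 1e-6, logged).
#'
#' @param g final `cpdag`.
#' @param data complete data matrix containing every graph node as a column.
#' @param roles optional `role_table` to fill `edge_weight_to_child` (for
#'   DPS nodes, the weight of their edge into the trait; for other nodes,
#'   their largest outgoing edge weight).
#' @return list with `weights` (data.frame `from`, `to`, `weight`), `dag`
#'   (the extension, a `cpdag`), and `roles` (annotated, when supplied).
#' @export
edge_weights <- function(g, data, roles = NULL) {
  data <- as.matrix(data)
  missing_cols <- setdiff(g$nodes, colnames(data))
  if (length(missing_cols))
    stopf("data lacks columns: %s", paste(missing_cols, collapse = ", "))
  dag <- consistent_extension(g)
  a <- dag$amat
  zs <- standardize_cols(data[, g$nodes, drop = FALSE])$x
  out <- list()
  for (child in g$nodes) {
    pa <- g$nodes[a[, child] == 1L & a[child, ] == 0L]
    if (!length(pa)) next
    xp <- zs[, pa, drop = FALSE]
    yc <- zs[, child]
    coefs <- tryCatch({
      fit <- stats::lm.fit(cbind(`(I)` = 1, xp), yc)
      if (any(is.na(fit$coefficients))) stop("collinear")
      fit$coefficients[-1L]
    }, error = function(e) {
      dag$log <<- c(dag$log, sprintf("ridge fallback for parents of %s", child))
      xtx <- crossprod(xp) + diag(1e-6, ncol(xp))
      as.numeric(solve(xtx, crossprod(xp, yc)))
    })
    out[[length(out) + 1L]] <- data.frame(from = pa, to = child,
                                          weight = abs(unname(coefs)),
                                          stringsAsFactors = FALSE)
  }
  weights <- if (length(out)) do.call(rbind, out) else
    data.frame(from = character(0), to = character(0), weight = numeric(0))
  rownames(weights) <- NULL
  if (!is.null(roles)) {
    for (r in seq_len(nrow(roles))) {
      id <- roles$marker_id[r]
      w <- weights$weight[weights$from == id]
      if (roles$role[r] == "DPS") {
        wt <- weights$weight[weights$from == id & weights$to == g$trait]
        roles$edge_weight_to_child[r] <- if (length(wt)) wt[1L] else
          if (length(w)) max(w) else NA_real_
      } else if (length(w)) {
        roles$edge_weight_to_child[r] <- max(w)
      }
    }
  }
  list(weights = weights, dag = dag, roles = roles)
}

#' Nodes ranked by out-degree
#'
#' @param g a `cpdag`.
#' @param trait trait node excluded from the ranking and from degree counts
#'   (defaults to `g$trait`; pass `NULL` to rank all nodes).
#' @return data.frame `marker_id`, `out_degree`, sorted by the deterministic
#'   tie-break (out-degree desc, total degree desc, id asc).
#' @export
out_degree_ranking <- function(g, trait = g$trait) {
  snps <- setdiff(g$nodes, trait)
  if (!length(snps))
    return(data.frame(marker_id = character(0), out_degree = integer(0)))
  outd <- vapply(snps, function(s) node_out_degree(g, s, trait), numeric(1))
  totd <- vapply(snps, function(s) node_total_degree(g, s), numeric(1))
  ord <- order(-outd, -totd, snps)
  data.frame(marker_id = snps[ord], out_degree = as.integer(outd[ord]),
             stringsAsFactors = FALSE)
}

#' Concentric layout coordinates for the sunflower rendering
#'
#' Trait at the origin, direct parents on a ring of radius 1, hubs on a ring
#' of radius 2, other nodes on radius 3.
#'
#' @param roles a `role_table`.
#' @param trait trait node name.
#' @return data.frame `node`, `ring`, `x`, `y`.
#' @export
concentric_layout <- function(roles, trait = attr(roles, "trait")) {
  ring_of <- c(DPS = 1, UHS = 2, other = 3)
  rows <- list(data.frame(node = trait, ring = 0, x = 0, y = 0))
  for (rl in names(ring_of)) {
    ids <- roles$marker_id[roles$role == rl]
    if (!length(ids)) next
    ang <- 2 * pi * (seq_along(ids) - 1L) / length(ids)
    rows[[length(rows) + 1L]] <- data.frame(
      node = ids, ring = ring_of[[rl]],
      x = ring_of[[rl]] * cos(ang), y = ring_of[[rl]] * sin(ang))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
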