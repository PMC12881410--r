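# Readers and writers for the pipeline's plain-text formats: dosage
# TSV/CSV (first column = individual ID, header = marker IDs), optional
# VCF with a DS dosage field or tetraploid GT calls, phenotype/plot
# tables, graph exports (GraphML, DOT, edge-list TSV).

#' Read a dosage matrix from TSV/CSV
#'
#' @param path file path; the delimiter is sniffed by extension (`.csv` vs
#'   tab) and by data.table's auto-detection otherwise.
#' @return numeric dosage matrix with individual row names and marker
#'   column names.
#' @export
read_dosage <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1L]])
  x <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  validate_dosages(x, allow_fractional = TRUE)
}

#' Write a dosage matrix as TSV
#'
#' @param x dosage matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage <- function(x, path) {
  dt <- data.table::data.table(genotype_id = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(x))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present; otherwise sums alternative
#' alleles across the (tetraploid) `GT` call. Requires the vcfR package.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return numeric dosage matrix (individuals x markers).
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1L]]) > 0L)
    })
  }
  ids <- v@fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("chr", v@fix[, "CHROM"], ".1_",
                                         v@fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(ds) <- ids
  x <- t(ds)
  validate_dosages(x, allow_fractional = TRUE)
}

#' Read a phenotype table
#'
#' Expects a `genotype_id` column (or first column treated as such) plus one
#' column per trait; plot-level tables additionally carry `row`, `column`
#' and optionally `replicate`.
#'
#' @param path TSV/CSV path.
#' @return data.frame.
#' @export
read_phenotype <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!"genotype_id" %in% names(dt)) names(dt)[1L] <- "genotype_id"
  dt$genotype_id <- as.character(dt$genotype_id)
  dt
}

#' Write a cpdag as GraphML
#'
#' Node attributes: `role` and `out_degree` when a role table is given;
#' edge attributes: `directed` flag and `weight` when annotated.
#'
#' @param g a `cpdag`.
#' @param path output path.
#' @param roles optional `role_table`.
#' @param weights optional edge-weight data.frame (`from`, `to`, `weight`).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path, roles = NULL, weights = NULL) {
  e <- cpdag_edges(g)
  if (!is.null(weights) && nrow(e)) {
    key <- paste(e$from, e$to)
    wkey <- paste(weights$from, weights$to)
    e$weight <- weights$weight[match(key, wkey)]
    rev <- is.na(e$weight)
    e$weight[rev] <- weights$weight[match(paste(e$to, e$from)[rev], wkey)]
  }
  vert <- data.frame(name = g$nodes, stringsAsFactors = FALSE)
  if (!is.null(roles)) {
    vert$role <- ifelse(vert$name == (g$trait %||% ""), "trait",
                        roles$role[match(vert$name, roles$marker_id)])
    vert$out_degree <- roles$out_degree[match(vert$name, roles$marker_id)]
    vert$role[is.na(vert$role)] <- "other"
    vert$out_degree[is.na(vert$out_degree)] <- 0L
  }
  ig <- igraph::graph_from_data_frame(e, directed = TRUE, vertices = vert)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write a cpdag as an edge-list TSV
#'
#' Columns: `source`, `target`, `directed`, `weight` (NA when unannotated).
#'
#' @inheritParams write_graphml
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path, weights = NULL) {
  e <- cpdag_edges(g)
  out <- data.frame(source = e$from, target = e$to, directed = e$directed,
                    weight = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(weights) && nrow(out)) {
    wkey <- paste(weights$from, weights$to)
    out$weight <- weights$weight[match(paste(out$source, out$target), wkey)]
    rev <- is.na(out$weight)
    out$weight[rev] <-
      weights$weight[match(paste(out$target, out$source)[rev], wkey)]
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read an edge-list TSV back into a cpdag
#'
#' @param path edge-list path written by [write_edgelist()].
#' @param nodes optional full node set (isolated nodes are not recoverable
#'   from edges alone).
#' @param trait optional trait node name.
#' @return a `cpdag`.
#' @export
read_edgelist <- function(path, nodes = NULL, trait = NULL) {
  e <- data.table::fread(path, data.table = FALSE)
  nodes <- nodes %||% unique(c(e$source, e$target, trait))
  cpdag_from_edges(nodes,
                   directed = e[e$directed, c("source", "target")],
                   undirected = e[!e$directed, c("source", "target")],
                   trait = trait)
}

#' Write a cpdag in DOT format for rendering
#'
#' @param g a `cpdag`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(g, path) {
  e <- cpdag_edges(g)
  lines <- c("digraph cpdag {",
             sprintf("  \"%s\";", g$nodes),
             if (nrow(e)) sprintf("  \"%s\" -> \"%s\"%s;", e$from, e$to,
                                  ifelse(e$directed, "", " [dir=none]")),
             "}")
  writeLines(lines, path)
  invisible(path)
}
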