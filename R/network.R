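#' Build the bipartite species-habitat network
#'
#' Two-mode weighted graph with habitat patches and species as the two node
#' sets; a link connects species s to patch i with weight equal to the
#' number of individuals of s observed at i. Zero counts are absent links.
#'
#' @param x an [abundance_matrix()].
#' @return An object of class `"bipartite_network"`: list with `counts`
#'   (the weight matrix, patches on rows), `habitat`, and derived fields
#'   `row_strengths` (per-patch total abundance), `col_strengths`
#'   (per-species total abundance), `n_links` (nonzero cells) and
#'   `total_weight`.
#' @export
build_bipartite <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  m <- x$counts
  if (!length(m)) stop("empty abundance matrix", call. = FALSE)
  structure(list(
    counts = m,
    habitat = x$habitat,
    row_strengths = rowSums(m),
    col_strengths = colSums(m),
    n_links = sum(m > 0),
    total_weight = sum(m)
  ), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "Bipartite species-habitat network: %d patches x %d species, %d links, total weight %d\n",
    nrow(x$counts), ncol(x$counts), x$n_links, x$total_weight))
  cat(sprintf("Connectance: %.3f\n", connectance(x)))
  invisible(x)
}

#' Project the bipartite network onto patches
#'
#' One-mode patch graph in which two patches are linked when at least one
#' species occurs (count > 0) at both; the edge weight is the number of
#' such shared species (presence-based, not abundance-based). Patch pairs
#' sharing no species get no edge.
#'
#' @param net a `bipartite_network` (or an `abundance_matrix`).
#' @return An object of class `"unipartite_network"`: list with `graph`
#'   (a weighted undirected [igraph][igraph::igraph-package] graph whose
#'   vertices carry a `habitat` attribute), `habitat`, and the per-patch
#'   `degree` and `strength` vectors.
#' @export
project_unipartite <- function(net) {
  if (inherits(net, "abundance_matrix")) net <- build_bipartite(net)
  stopifnot(inherits(net, "bipartite_network"))
  inc <- net$counts > 0
  shared <- tcrossprod(inc * 1L)     # patches x patches shared-species counts
  diag(shared) <- 0
  g <- igraph::graph_from_adjacency_matrix(shared, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$habitat <- unname(net$habitat[igraph::V(g)$name])
  structure(list(
    graph = g,
    habitat = net$habitat,
    degree = igraph::degree(g),
    strength = igraph::strength(g)
  ), class = "unipartite_network")
}

#' @export
print.unipartite_network <- function(x, ...) {
  cat(sprintf(
    "Unipartite patch network: %d patches, %d edges (weight = shared species)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Export a network to a plain-text graph format
#'
#' Writes a weighted edge list (TSV: `node1`, `node2`, `weight`) or GraphML.
#' GraphML carries the `habitat` vertex attribute of unipartite networks and
#' a two-level `mode` attribute (`"patch"`/`"species"`) for bipartite ones,
#' so that a write-read round trip preserves labels, attributes and weights.
#'
#' @param net a `unipartite_network` or `bipartite_network`.
#' @param path output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  g <- as_igraph(net)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(g)
    df <- data.frame(node1 = el[, 1], node2 = el[, 2],
                     weight = igraph::E(g)$weight,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [export_graph()]
#'
#' @param path file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return A weighted [igraph][igraph::igraph-package] graph.
#' @export
import_graph <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(df, directed = FALSE)
  } else {
    igraph::read_graph(path, format = "graphml")
  }
}

# Internal: coerce either network class to igraph.
as_igraph <- function(net) {
  if (inherits(net, "unipartite_network")) return(net$graph)
  if (inherits(net, "bipartite_network")) {
    g <- igraph::graph_from_biadjacency_matrix(net$counts, weighted = TRUE)
    igraph::V(g)$mode <- ifelse(igraph::V(g)$type, "species", "patch")
    igraph::V(g)$habitat <- ifelse(
      igraph::V(g)$type, NA_character_,
      unname(net$habitat[igraph::V(g)$name]))
    return(g)
  }
  stop("unsupported network object", call. = FALSE)
}
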