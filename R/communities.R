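#' Community detection on the patch network
#'
#' Clusters patches by the butterfly species they share, using one of three
#' weighted algorithms: `"multilevel"` (Louvain greedy modularity
#' optimization), `"walktrap"` (agglomeration of short random walks,
#' 4 steps by default) or `"spinglass"` (simulated annealing of a Potts
#' spin model; requires a connected graph). All three use the edge weights
#' (numbers of shared species) and are made reproducible through `seed`.
#'
#' @param net a `unipartite_network`.
#' @param algorithm one of `"multilevel"`, `"walktrap"`, `"spinglass"`.
#' @param seed integer seed for the stochastic algorithms, or `NULL`.
#' @param steps walktrap random-walk length.
#' @param spins,gamma spinglass parameters.
#' @return An object of class `"partition"`: list with `membership` (named
#'   module ids, contiguous from 0), `n_communities`, `quality` (the
#'   Newman-Girvan weighted modularity of the partition), `algorithm` and
#'   `seed`.
#' @export
detect_communities <- function(net,
                               algorithm = c("multilevel", "walktrap",
                                             "spinglass"),
                               seed = NULL, steps = 4L, spins = 25L,
                               gamma = 1) {
  stopifnot(inherits(net, "unipartite_network"))
  algorithm <- match.arg(algorithm)
  g <- net$graph
  if (algorithm == "spinglass" && !igraph::is_connected(g)) {
    stop("spinglass requires a connected graph; analyse each connected ",
         "component separately", call. = FALSE)
  }
  cl <- with_seed(seed, switch(
    algorithm,
    multilevel = igraph::cluster_louvain(g, weights = igraph::E(g)$weight),
    walktrap = igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                        steps = steps),
    spinglass = igraph::cluster_spinglass(g, weights = igraph::E(g)$weight,
                                          spins = spins, gamma = gamma)
  ))
  memb <- igraph::membership(cl)
  q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  new_partition(stats::setNames(as.integer(memb), igraph::V(g)$name),
                quality = q, algorithm = algorithm, seed = seed)
}

#' Construct a patch partition from a labelling
#'
#' Wraps any node labelling (e.g. the a-priori habitat types) as a
#' `partition` object comparable with detected communities.
#'
#' @param labels vector of group labels named by patch.
#' @param net optional `unipartite_network` used to attach the
#'   Newman-Girvan weighted modularity of the labelling.
#' @param algorithm tag stored in the partition.
#' @return A `partition` object.
#' @export
as_partition <- function(labels, net = NULL, algorithm = "labels") {
  memb <- stats::setNames(as.integer(factor(labels)), names(labels))
  q <- if (!is.null(net)) {
    g <- net$graph
    igraph::modularity(g, memb[igraph::V(g)$name],
                       weights = igraph::E(g)$weight)
  } else NA_real_
  new_partition(memb, quality = q, algorithm = algorithm, seed = NULL)
}

new_partition <- function(membership, quality, algorithm, seed) {
  memb <- as.integer(factor(membership)) - 1L
  names(memb) <- names(membership)
  structure(list(
    membership = memb,
    n_communities = length(unique(memb)),
    quality = quality,
    algorithm = algorithm,
    seed = seed
  ), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition (%s): %d communities, modularity = %.4f\n",
              x$algorithm, x$n_communities, x$quality))
  invisible(x)
}

#' Mixing parameter of a partition
#'
#' Average fraction of a patch's links that leave its own community. For
#' each node the external fraction is computed twice: from the edge counts
#' (k_ext / k) and from the edge weights (s_ext / s); `mu_degree` and
#' `mu_strength` are the unweighted averages over all connected nodes
#' (isolated nodes are excluded). Both lie in \[0, 1\]: 0 when communities
#' are disconnected from each other, approaching 1 when all edges cross
#' community boundaries.
#'
#' @param net a `unipartite_network`.
#' @param partition a `partition` covering every patch.
#' @return An object of class `"mixing_report"`: list with the per-node
#'   table `nodes` (`patch`, `community`, `k`, `k_ext`, `s`, `s_ext`) and
#'   the two averages `mu_degree` and `mu_strength`.
#' @export
mixing_parameter <- function(net, partition) {
  stopifnot(inherits(net, "unipartite_network"))
  memb <- partition$membership
  if (is.null(memb) || !length(memb)) {
    stop("empty partition", call. = FALSE)
  }
  g <- net$graph
  vn <- igraph::V(g)$name
  miss <- setdiff(vn, names(memb))
  if (length(miss)) {
    stop("partition is missing node(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  memb <- memb[vn]
  el <- igraph::as_edgelist(g)
  wt <- igraph::E(g)$weight
  ext <- memb[el[, 1]] != memb[el[, 2]]
  k_ext <- s_ext <- stats::setNames(numeric(length(vn)), vn)
  for (side in 1:2) {
    agg_k <- tapply(ext, el[, side], sum)
    agg_s <- tapply(wt * ext, el[, side], sum)
    k_ext[names(agg_k)] <- k_ext[names(agg_k)] + agg_k
    s_ext[names(agg_s)] <- s_ext[names(agg_s)] + agg_s
  }
  k <- net$degree[vn]
  s <- net$strength[vn]
  keep <- k > 0
  nodes <- data.frame(patch = vn, community = unname(memb),
                      k = unname(k), k_ext = unname(k_ext),
                      s = unname(s), s_ext = unname(s_ext),
                      stringsAsFactors = FALSE)
  structure(list(
    nodes = nodes,
    mu_degree = mean(k_ext[keep] / k[keep]),
    mu_strength = mean(s_ext[keep] / s[keep])
  ), class = "mixing_report")
}

#' @export
print.mixing_report <- function(x, ...) {
  cat(sprintf("Mixing parameter: mu = %.3f (degree-based), %.3f (strength-based)\n",
              x$mu_degree, x$mu_strength))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same node set:
#' 1 for identical partitions, expectation 0 for independent random ones
#' under the permutation model (negative values are possible).
#'
#' @param a,b `partition` objects, or bare label vectors named by node.
#' @return The adjusted Rand index.
#' @references Hubert L., Arabie P. (1985) Comparing partitions. Journal of
#'   Classification 2, 193-218.
#' @export
partition_agreement <- function(a, b) {
  la <- if (inherits(a, "partition")) a$membership else a
  lb <- if (inherits(b, "partition")) b$membership else b
  if (is.null(names(la)) || is.null(names(lb)) ||
      !setequal(names(la), names(lb))) {
    stop("partitions must cover the same named node set", call. = FALSE)
  }
  lb <- lb[names(la)]
  tab <- table(la, lb)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == max_index, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}
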