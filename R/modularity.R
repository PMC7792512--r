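#' Barber bipartite modularity
#'
#' Quality of a joint partition of patches and species into modules, for a
#' weighted two-mode network:
#' \deqn{Q = \frac{1}{W} \sum_{i,s} \left(w_{is} - \frac{s_i t_s}{W}\right)
#'   \delta(g_i, g_s)}
#' where \eqn{w_{is}} is the abundance of species s at patch i, \eqn{s_i}
#' and \eqn{t_s} are the patch and species strengths (marginal totals),
#' \eqn{W} the total weight, and \eqn{g} the module assignment. Q is 0 when
#' all nodes share one module and is bounded by \[-0.5, 1\].
#'
#' @param net a `bipartite_network` (or `abundance_matrix`).
#' @param partition a `bipartite_partition` (see [optimize_modularity()]) or
#'   a list with named integer vectors `patches` and `species` assigning
#'   every node to a module.
#' @return The modularity score Q.
#' @references Barber M.J. (2007) Modularity and community detection in
#'   bipartite networks. Physical Review E 76, 066102.
#' @export
barber_modularity <- function(net, partition) {
  if (inherits(net, "abundance_matrix")) net <- build_bipartite(net)
  stopifnot(inherits(net, "bipartite_network"))
  m <- net$counts
  gp <- partition$patches
  gs <- partition$species
  if (is.null(gp) || is.null(gs)) {
    stop("partition must carry `patches` and `species` assignments",
         call. = FALSE)
  }
  miss <- c(setdiff(rownames(m), names(gp)), setdiff(colnames(m), names(gs)))
  if (length(miss)) {
    stop("partition is missing node(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  gp <- gp[rownames(m)]
  gs <- gs[colnames(m)]
  w <- net$total_weight
  b <- m - outer(net$row_strengths, net$col_strengths) / w
  sum(b[outer(gp, gs, "==")]) / w
}

#' Optimize Barber modularity by weighted bipartite label propagation
#'
#' Searches for the patch/species module partition maximizing Barber
#' modularity with a label-propagation heuristic followed by agglomerative
#' module merging (the LPAwb+ strategy), repeated over random restarts; the
#' best partition found is returned. The search is stochastic but fully
#' reproducible given `seed`. Because the single-module partition (Q = 0)
#' and any supplied initial partitions are always among the candidates, the
#' returned Q is never below 0 nor below the score of an `init` partition.
#'
#' @param net a `bipartite_network` (or `abundance_matrix`).
#' @param seed integer seed for the restart streams, or `NULL`.
#' @param n_restarts number of random restarts (default 20).
#' @param init optional list of starting partitions (each a list with
#'   `patches` and `species` integer vectors) refined alongside the random
#'   restarts, e.g. the habitat labelling.
#' @return An object of class `"bipartite_partition"`: list with `patches`
#'   and `species` (named module ids, contiguous from 0), `n_communities`,
#'   `quality` (the Q at the returned partition), `algorithm` and `seed`.
#' @references Beckett S.J. (2016) Improved community detection in weighted
#'   bipartite networks. Royal Society Open Science 3, 140536.
#' @export
optimize_modularity <- function(net, seed = NULL, n_restarts = 20L,
                                init = NULL) {
  if (inherits(net, "abundance_matrix")) net <- build_bipartite(net)
  stopifnot(inherits(net, "bipartite_network"))
  m <- net$counts
  with_seed(seed, {
    best <- NULL
    starts <- c(
      list(seq_len(nrow(m))),                     # every patch its own module
      lapply(seq_len(max(n_restarts - 1L, 0L)), function(r) {
        k <- sample.int(nrow(m), 1L)
        sample.int(k, nrow(m), replace = TRUE)
      })
    )
    for (s0 in starts) {
      cand <- lpa_refine(m, row_labels = s0)
      if (is.null(best) || cand$quality > best$quality) best <- cand
    }
    for (p0 in init) {
      joint <- as.integer(factor(c(p0$patches[rownames(m)],
                                   p0$species[colnames(m)])))
      cand <- lpa_refine(m, row_labels = joint[seq_len(nrow(m))],
                         col_labels = joint[nrow(m) + seq_len(ncol(m))])
      if (is.null(best) || cand$quality > best$quality) best <- cand
    }
    make_bipartite_partition(m, best$rows, best$cols, best$quality,
                             algorithm = "lpawb+", seed = seed)
  })
}

# One LPAwb+ run: alternating greedy label updates for columns and rows,
# then agglomerative merging, looped until Q stops improving.
lpa_refine <- function(m, row_labels, col_labels = NULL) {
  w <- sum(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  gr <- as.integer(factor(row_labels))
  gc <- col_labels
  if (is.null(gc)) gc <- greedy_assign(t(m), cs, rs, gr, w)
  q <- barber_q(m, gr, gc, rs, cs, w)
  repeat {
    for (it in seq_len(100L)) {
      gc_new <- greedy_assign(t(m), cs, rs, gr, w)
      gr_new <- greedy_assign(m, rs, cs, gc_new, w)
      if (identical(gr_new, gr) && identical(gc_new, gc)) break
      gr <- gr_new; gc <- gc_new
    }
    merged <- agglomerate(m, gr, gc, rs, cs, w)
    gr <- merged$rows; gc <- merged$cols
    q_new <- barber_q(m, gr, gc, rs, cs, w)
    if (q_new <= q + 1e-12) break
    q <- q_new
  }
  list(rows = gr, cols = gc, quality = max(q, 0))
}

# Assign each row of `m` to the opposite-side module maximizing its Barber-Q
# contribution; a node whose best score is negative opens a fresh module.
greedy_assign <- function(m, own_strength, other_strength, other_labels, w) {
  mods <- sort(unique(other_labels))
  ind <- outer(other_labels, mods, "==") * 1
  score <- m %*% ind - outer(own_strength, drop(crossprod(ind, other_strength))) / w
  pick <- mods[max.col(score, ties.method = "first")]
  neg <- score[cbind(seq_len(nrow(score)), max.col(score, ties.method = "first"))] < 0
  if (any(neg)) pick[neg] <- max(mods) + seq_len(sum(neg))
  pick
}

barber_q <- function(m, gr, gc, rs, cs, w) {
  b <- m - outer(rs, cs) / w
  sum(b[outer(gr, gc, "==")]) / w
}

# Greedily merge module pairs while any merge increases Q.
agglomerate <- function(m, gr, gc, rs, cs, w) {
  repeat {
    labs <- sort(unique(c(gr, gc)))
    if (length(labs) < 2L) break
    ri <- outer(gr, labs, "==") * 1
    ci <- outer(gc, labs, "==") * 1
    e <- t(ri) %*% m %*% ci                    # module-to-module weight
    x <- outer(drop(crossprod(ri, rs)), drop(crossprod(ci, cs))) / w
    gain <- (e + t(e)) - (x + t(x))            # symmetric merge gains
    diag(gain) <- -Inf
    i <- which.max(gain)
    if (gain[i] <= 1e-12) break
    a <- labs[(i - 1) %% length(labs) + 1]
    b <- labs[(i - 1) %/% length(labs) + 1]
    gr[gr == b] <- a
    gc[gc == b] <- a
  }
  list(rows = gr, cols = gc)
}

make_bipartite_partition <- function(m, gr, gc, quality, algorithm, seed) {
  joint <- as.integer(factor(c(gr, gc))) - 1L
  gp <- joint[seq_len(nrow(m))]
  gs <- joint[nrow(m) + seq_len(ncol(m))]
  names(gp) <- rownames(m)
  names(gs) <- colnames(m)
  structure(list(
    patches = gp, species = gs,
    n_communities = length(unique(joint)),
    quality = quality,
    algorithm = algorithm,
    seed = seed
  ), class = "bipartite_partition")
}

#' @export
print.bipartite_partition <- function(x, ...) {
  cat(sprintf("Bipartite partition (%s): %d modules, Q = %.4f\n",
              x$algorithm, x$n_communities, x$quality))
  invisible(x)
}
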