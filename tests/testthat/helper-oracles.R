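# Independent oracles and small fixtures used across the suite. Each oracle
# is written as a direct, naive transcription of the definition, separate
# from the package's vectorized implementations.

toy_matrix <- function(counts, habitat = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- LETTERS[seq_len(nrow(counts))]
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  }
  abundance_matrix(counts,
                   habitat %||% rep("h1", nrow(counts)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force shared-species counts between all site pairs.
naive_shared_species <- function(counts) {
  n <- nrow(counts)
  out <- matrix(0L, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- which(counts[i, ] > 0)
    b <- which(counts[j, ] > 0)
    out[i, j] <- length(intersect(a, b))
  }
  out
}

# Naive weighted NODF: explicit loops over every ordered pair of rows and of
# columns of the sorted matrix, under either decrease condition.
naive_wnodf <- function(m, condition = "fill") {
  keyfun <- if (condition == "fill") {
    function(v) sum(v > 0)
  } else {
    sum
  }
  rk <- apply(m, 1, keyfun)
  ck <- apply(m, 2, keyfun)
  m <- m[order(rk, rowSums(m), decreasing = TRUE),
         order(ck, colSums(m), decreasing = TRUE), drop = FALSE]
  pair_sum <- function(mat) {
    tot <- 0
    np <- 0
    for (i in seq_len(nrow(mat) - 1)) for (j in (i + 1):nrow(mat)) {
      np <- np + 1
      if (keyfun(mat[j, ]) >= keyfun(mat[i, ])) next  # tie or increase: 0
      fill_j <- sum(mat[j, ] > 0)
      if (fill_j == 0) next
      overlap <- 0
      for (k in seq_len(ncol(mat))) {
        if (mat[j, k] > 0 && mat[j, k] < mat[i, k]) overlap <- overlap + 1
      }
      tot <- tot + 100 * overlap / fill_j
    }
    c(tot, np)
  }
  r <- pair_sum(m)
  c2 <- pair_sum(t(m))
  (r[1] + c2[1]) / (r[2] + c2[2])
}

# Direct Newman-Girvan weighted modularity of a partition of an undirected
# weighted graph, from the definition.
naive_newman_modularity <- function(graph, membership) {
  el <- igraph::as_edgelist(graph)
  w <- igraph::E(graph)$weight
  two_m <- 2 * sum(w)
  s <- igraph::strength(graph)
  q <- 0
  vn <- igraph::V(graph)$name
  for (i in vn) for (j in vn) {
    wij <- 0
    hit <- (el[, 1] == i & el[, 2] == j) | (el[, 1] == j & el[, 2] == i)
    if (any(hit)) wij <- sum(w[hit])
    if (membership[i] == membership[j]) {
      q <- q + (wij - s[i] * s[j] / two_m)
    }
  }
  q / two_m
}

# All set partitions of n elements (restricted growth strings), for
# exhaustive modularity searches on tiny graphs.
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      grow(c(prefix, lab), max(maxlab, lab))
    }
  }
  grow(integer(0), 0L)
  out
}

# Exhaustive Barber modularity maximum over all joint partitions of the
# patch and species nodes of a small matrix.
exhaustive_barber <- function(counts) {
  n <- nrow(counts) + ncol(counts)
  best <- -Inf
  net <- build_bipartite(toy_matrix(counts))
  for (p in all_partitions(n)) {
    gp <- p[seq_len(nrow(counts))]
    gs <- p[nrow(counts) + seq_len(ncol(counts))]
    names(gp) <- rownames(net$counts)
    names(gs) <- colnames(net$counts)
    q <- barber_modularity(net, list(patches = gp, species = gs))
    if (q > best) best <- q
  }
  best
}

# Closed-form adjusted Rand index from the contingency table.
naive_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  exp_ <- sa * sb / choose(n, 2)
  mx <- (sa + sb) / 2
  if (mx == exp_) return(if (sij == mx) 1 else 0)
  (sij - exp_) / (mx - exp_)
}

# Small random count matrix with no empty rows/columns.
random_count_matrix <- function(nr, nc, max_count = 5, p_zero = 0.4) {
  repeat {
    m <- matrix(ifelse(stats::runif(nr * nc) < p_zero, 0L,
                       sample.int(max_count, nr * nc, replace = TRUE)),
                nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  rownames(m) <- paste0("r", seq_len(nr))
  colnames(m) <- paste0("c", seq_len(nc))
  m
}
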