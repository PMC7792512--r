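# Two 4-patch cliques sharing many species within and one species across.
two_clique_matrix <- function() {
  counts <- matrix(0L, 8, 11,
                   dimnames = list(paste0("p", 1:8), paste0("s", 1:11)))
  counts[1:4, 1:5] <- 1L      # clique 1: five shared species
  counts[5:8, 6:10] <- 1L     # clique 2: five shared species
  counts[4:5, 11] <- 1L       # single bridging species
  abundance_matrix(counts, rep(c("left", "right"), each = 4))
}

test_that("all three algorithms split two bridged cliques", {
  uni <- project_unipartite(two_clique_matrix())
  for (alg in c("multilevel", "walktrap", "spinglass")) {
    part <- detect_communities(uni, alg, seed = 5)
    expect_identical(part$n_communities, 2L)
    expect_equal(partition_agreement(part, as_partition(uni$habitat)), 1)
  }
})

test_that("a uniform complete graph is a single community", {
  counts <- matrix(1L, 5, 6, dimnames = list(paste0("p", 1:5),
                                             paste0("s", 1:6)))
  uni <- project_unipartite(abundance_matrix(counts, rep("h", 5)))
  part <- detect_communities(uni, "multilevel", seed = 1)
  expect_identical(part$n_communities, 1L)
})

test_that("spinglass refuses disconnected graphs", {
  counts <- rbind(A = c(1L, 0L), B = c(1L, 0L), C = c(0L, 1L),
                  D = c(0L, 1L))
  colnames(counts) <- c("s1", "s2")
  uni <- project_unipartite(abundance_matrix(counts, rep("h", 4)))
  expect_error(detect_communities(uni, "spinglass"), "connected")
})

test_that("attached modularity equals the direct Newman-Girvan evaluation", {
  # structured graph: a partition with genuinely positive modularity
  uni <- project_unipartite(two_clique_matrix())
  part <- detect_communities(uni, "walktrap", seed = 1)
  expect_gt(part$quality, 0.3)
  expect_lt(abs(part$quality -
                  naive_newman_modularity(uni$graph, part$membership)),
            1e-12)
  # and arbitrary partitions of random graphs (absolute comparison: the
  # direct sum can carry 1e-17-scale float noise around zero)
  set.seed(25)
  for (rep in 1:4) {
    counts <- random_count_matrix(7, 10)
    g <- project_unipartite(toy_matrix(counts))
    memb <- stats::setNames(sample.int(3, 7, TRUE),
                            rownames(counts))
    lab <- as_partition(memb, net = g)
    expect_lt(abs(lab$quality -
                    naive_newman_modularity(g$graph, lab$membership)),
              1e-12)
  }
})

test_that("community detection is reproducible under a seed", {
  uni <- project_unipartite(two_clique_matrix())
  for (alg in c("multilevel", "spinglass")) {
    a <- detect_communities(uni, alg, seed = 13)
    b <- detect_communities(uni, alg, seed = 13)
    expect_identical(a$membership, b$membership)
  }
})

test_that("mixing parameter matches hand counts", {
  uni <- project_unipartite(two_clique_matrix())
  one <- as_partition(stats::setNames(rep("all", 8),
                                      names(uni$habitat)))
  mix0 <- mixing_parameter(uni, one)
  expect_equal(mix0$mu_degree, 0)
  expect_equal(mix0$mu_strength, 0)

  # complete 4-node uniform graph split 2+2: 2 of each node's 3 edges external
  counts <- matrix(1L, 4, 3, dimnames = list(paste0("p", 1:4),
                                             paste0("s", 1:3)))
  k4 <- project_unipartite(abundance_matrix(counts, rep("h", 4)))
  half <- as_partition(stats::setNames(c(1, 1, 2, 2), paste0("p", 1:4)))
  mix <- mixing_parameter(k4, half)
  expect_equal(mix$mu_degree, 2 / 3)
  expect_equal(mix$mu_strength, 2 / 3)

  expect_error(mixing_parameter(uni, list(membership = NULL)), "empty")
})

test_that("adjusted Rand index matches conventions and the closed form", {
  a <- stats::setNames(c(1, 1, 2, 2), letters[1:4])
  expect_equal(partition_agreement(a, a), 1)
  singletons <- stats::setNames(1:4, letters[1:4])
  whole <- stats::setNames(rep(1, 4), letters[1:4])
  expect_equal(partition_agreement(whole, singletons), 0)
  expect_error(partition_agreement(a, stats::setNames(1:3, letters[1:3])),
               "same named node set")

  set.seed(55)
  for (rep in 1:20) {
    x <- stats::setNames(sample.int(3, 10, TRUE), letters[1:10])
    y <- stats::setNames(sample.int(4, 10, TRUE), letters[1:10])
    expect_equal(partition_agreement(x, y), naive_ari(x, y[names(x)]))
  }
})

test_that("adjusted Rand index agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(56)
  for (rep in 1:10) {
    x <- stats::setNames(sample.int(3, 12, TRUE), letters[1:12])
    y <- stats::setNames(sample.int(3, 12, TRUE), letters[1:12])
    expect_equal(partition_agreement(x, y),
                 mclust::adjustedRandIndex(x, y[names(x)]))
  }
})
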