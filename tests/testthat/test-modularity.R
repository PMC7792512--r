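test_that("single-module partitions score exactly zero", {
  set.seed(3)
  counts <- random_count_matrix(5, 6)
  net <- build_bipartite(toy_matrix(counts))
  part <- list(
    patches = setNames(rep(1L, 5), rownames(counts)),
    species = setNames(rep(1L, 6), colnames(counts))
  )
  expect_equal(barber_modularity(net, part), 0)
})

test_that("diagonal 2x2 blocks score Q = 0.5", {
  net <- build_bipartite(toy_matrix(rbind(c(1, 0), c(0, 1))))
  part <- list(patches = c(A = 1L, B = 2L), species = c(s1 = 1L, s2 = 2L))
  expect_equal(barber_modularity(net, part), 0.5)
})

test_that("partitions missing a node are rejected", {
  net <- build_bipartite(toy_matrix(rbind(c(1, 0), c(0, 1))))
  expect_error(
    barber_modularity(net, list(patches = c(A = 1L),
                                species = c(s1 = 1L, s2 = 2L))),
    "missing node")
})

test_that("optimizer matches exhaustive search on tiny matrices", {
  blocks <- rbind(c(3, 2, 0, 0), c(0, 0, 1, 2))
  part <- optimize_modularity(toy_matrix(blocks), seed = 1, n_restarts = 10)
  expect_equal(part$quality, exhaustive_barber(blocks))

  set.seed(8)
  for (rep in 1:5) {
    m <- random_count_matrix(2, 3)
    part <- optimize_modularity(toy_matrix(m), seed = rep, n_restarts = 10)
    expect_equal(part$quality, exhaustive_barber(m), tolerance = 1e-12)
  }
})

test_that("optimizer recovers planted disconnected modules", {
  # even abundances: with skewed weights the optimum may legitimately
  # subdivide a fully-occupied block, so exact count recovery needs
  # within-block homogeneity
  spec <- landscape_spec(n_habitats = 3, sites_per_habitat = 4,
                         specialists_per_habitat = 5, n_generalists = 0,
                         p_in = 1, p_out = 0, sigma_ln = 0)
  land <- generate_landscape(spec, seed = 2)
  part <- optimize_modularity(land$matrix, seed = 3)
  expect_identical(part$n_communities, 3L)
  expect_equal(
    partition_agreement(
      stats::setNames(part$patches, names(part$patches)),
      land$truth$habitat[names(part$patches)]),
    1)
})

test_that("optimizer Q never falls below a supplied initial partition", {
  set.seed(12)
  for (rep in 1:5) {
    counts <- random_count_matrix(6, 8)
    hab <- sample(c("x", "y", "z"), 6, replace = TRUE)
    m <- abundance_matrix(counts, hab)
    net <- build_bipartite(m)
    hm <- setNames(as.integer(factor(hab)), rownames(counts))
    sp <- setNames(sample.int(3L, 8, replace = TRUE), colnames(counts))
    init <- list(patches = hm, species = sp)
    q_init <- barber_modularity(net, init)
    part <- optimize_modularity(net, seed = rep, n_restarts = 5,
                                init = list(init))
    expect_gte(part$quality, max(q_init, 0))
    expect_equal(barber_modularity(net, part), part$quality)
  }
})

test_that("optimizer is deterministic given the seed", {
  set.seed(4)
  counts <- random_count_matrix(8, 10)
  m <- toy_matrix(counts)
  a <- optimize_modularity(m, seed = 7, n_restarts = 8)
  b <- optimize_modularity(m, seed = 7, n_restarts = 8)
  expect_identical(a$patches, b$patches)
  expect_identical(a$species, b$species)
  expect_identical(a$quality, b$quality)
})

test_that("shuffled block matrices lose their modular signal", {
  blocks <- rbind(c(5, 4, 0, 0), c(4, 5, 0, 0), c(0, 0, 5, 4), c(0, 0, 4, 5))
  rownames(blocks) <- LETTERS[1:4]; colnames(blocks) <- paste0("s", 1:4)
  q_obs <- optimize_modularity(toy_matrix(blocks), seed = 1)$quality
  set.seed(41)
  q_null <- vapply(patefield_draws(blocks, 30), function(r) {
    optimize_modularity(toy_matrix(r), seed = NULL, n_restarts = 5)$quality
  }, numeric(1))
  expect_gt(q_obs, mean(q_null))
})
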