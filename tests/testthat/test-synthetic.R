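test_that("default landscape has the study-design shape", {
  land <- generate_landscape(seed = 1)
  expect_identical(dim(land$matrix$counts), c(44L, 74L))
  expect_identical(as.integer(table(land$matrix$habitat)[paste0("habitat", 1:5)]),
                   c(10L, 10L, 10L, 7L, 7L))
  expect_identical(sum(land$truth$role == "generalist"), 34L)
  expect_true(all(rowSums(land$matrix$counts) > 0))
  expect_true(all(colSums(land$matrix$counts) > 0))
})

test_that("identical spec and seed give identical matrices", {
  a <- generate_landscape(seed = 7)
  b <- generate_landscape(seed = 7)
  expect_identical(a$matrix$counts, b$matrix$counts)
  c_ <- generate_landscape(seed = 8)
  expect_false(identical(a$matrix$counts, c_$matrix$counts))
})

test_that("spec invariants are enforced", {
  expect_error(landscape_spec(p_in = 0.2, p_out = 0.5))
  expect_error(landscape_spec(p_gen = 1.4))
  expect_error(landscape_spec(specialists_per_habitat = 0, n_generalists = 0))
})

test_that("zero cross-occupancy plants disconnected habitat blocks", {
  spec <- landscape_spec(n_habitats = 3, sites_per_habitat = 4,
                         specialists_per_habitat = 6, n_generalists = 0,
                         p_in = 1, p_out = 0, sigma_ln = 0)
  land <- generate_landscape(spec, seed = 3)
  m <- land$matrix$counts
  for (j in seq_len(ncol(m))) {
    occupied <- land$matrix$habitat[m[, j] > 0]
    expect_identical(unique(unname(occupied)), unname(land$truth$role[j]))
  }
  part <- optimize_modularity(land$matrix, seed = 1)
  expect_identical(part$n_communities, 3L)
})

test_that("indistinguishable roles leave no habitat signal", {
  # equal occupancy probabilities: detected communities should agree with
  # the planted habitats no better than chance
  spec <- landscape_spec(n_habitats = 3, sites_per_habitat = 4,
                         specialists_per_habitat = 4, n_generalists = 2,
                         p_in = 0.5, p_out = 0.5, p_gen = 0.5)
  set.seed(71)
  aris <- replicate(15, {
    land <- generate_landscape(spec, seed = sample.int(1e6, 1))
    part <- detect_communities(project_unipartite(land$matrix),
                               "multilevel", seed = 1)
    partition_agreement(part$membership, land$truth$habitat)
  })
  expect_lt(abs(mean(aris)), 0.15)
})

test_that("matrices drawn from the null model score z near zero", {
  spec <- landscape_spec(n_habitats = 3, sites_per_habitat = 4,
                         specialists_per_habitat = 4, n_generalists = 2,
                         p_in = 0.5, p_out = 0.5, p_gen = 0.5)
  base <- generate_landscape(spec, seed = 81)$matrix
  set.seed(82)
  draws <- patefield_draws(base$counts, 13)
  zs <- vapply(draws[1:12], function(obs) {
    q <- optimize_modularity(toy_matrix(obs), seed = 1,
                             n_restarts = 3)$quality
    nulls <- vapply(patefield_draws(obs, 25), function(r) {
      optimize_modularity(toy_matrix(r), seed = NULL,
                          n_restarts = 3)$quality
    }, numeric(1))
    z_score(q, nulls)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 2)
})

test_that("abundances are skewed and strictly positive where present", {
  land <- generate_landscape(seed = 5)
  counts <- land$matrix$counts[land$matrix$counts > 0]
  expect_true(all(counts >= 1))
  expect_gt(max(counts), 5 * stats::median(counts))   # log-normal-like skew
})

test_that("nested generator respects its extent schedule", {
  m <- generate_nested(10, 5, decay = 0.4)
  extents <- colSums(m$counts > 0)
  expect_equal(unname(extents),
               pmax(1, pmin(10, ceiling(10 * exp(-0.4 * (0:4))))))
  full <- generate_nested(6, 4, decay = 0)
  expect_true(all(full$counts > 0))
})
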