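test_that("birth-death simulator yields reproducible ultrametric trees", {
  tr <- simulate_tree(2, birth = 1, death = 0, seed = 1)
  ages <- species_ages(tr)
  expect_equal(unname(ages[1]), unname(ages[2]))  # cherry: ultrametry

  t1 <- simulate_tree(16, seed = 7)
  t2 <- simulate_tree(16, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  for (s in 1:20) {
    tr <- simulate_tree(64, seed = s)
    expect_equal(ape::Ntip(tr), 64)
    expect_equal(tr$Nnode, 63)  # n - 1 internals in a rooted binary tree
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  }
  expect_error(simulate_tree(1), "n_tips")
  expect_error(simulate_tree(8, birth = 1, death = 1), "exceed")
})

test_that("planted rate shifts multiply along clade coverage", {
  tr <- simulate_tree(8, seed = 3)
  expect_equal(effective_rates(tr, NULL), rep(1, nrow(tr$edge)))
  expect_equal(nrow(plant_rate_shifts(tr, 0, 0, seed = 1)), 0)

  cfg <- plant_rate_shifts(tr, n_branch = 0, n_clade = 1,
                           scalar_range = c(2, 2), seed = 5)
  er <- effective_rates(tr, cfg)
  cov <- beakrates:::descendant_edges(tr, cfg$edge[1])
  expect_equal(er[cov], rep(2, length(cov)))
  expect_equal(er[-cov], rep(1, nrow(tr$edge) - length(cov)))

  # nested clade scalars multiply: 2 * 3 = 6 on doubly covered edges
  e_out <- find_clade_edge(tr, 4, 6)
  inner <- beakrates:::descendant_edges(tr, e_out, include_self = FALSE)
  e_in <- inner[1]
  cfg2 <- rate_config(c(e_out, e_in), c("clade", "clade"), c(3, 2))
  er2 <- effective_rates(tr, cfg2)
  double <- beakrates:::descendant_edges(tr, e_in)
  expect_equal(er2[double], rep(6, length(double)))

  expect_error(plant_rate_shifts(tr, n_branch = 100), "more shifts")
})

test_that("effective rates match brute-force path enumeration", {
  for (s in 1:5) {
    tr <- simulate_tree(32, seed = 100 + s)
    cfg <- plant_rate_shifts(tr, n_branch = 2, n_clade = 3, seed = 200 + s)
    expect_equal(effective_rates(tr, cfg), brute_effective_rates(tr, cfg),
                 tolerance = 1e-12)
  }
})

test_that("trait simulator reproduces Brownian moments", {
  # zero-time limit: every tip at the root state
  tr <- simulate_tree(6, seed = 2)
  tr0 <- tr; tr0$edge.length <- tr0$edge.length * 1e-12
  X <- simulate_traits(tr0, mvbm_params(c(3, -1), diag(2)), seed = 1)
  expect_equal(unname(X), matrix(rep(c(3, -1), each = 6), 6),
               tolerance = 1e-4)

  # star tree, depth T: tip variance = sigma * T
  star <- ape::stree(4, "star"); star$edge.length <- rep(2.5, 4)
  set.seed(10)
  reps <- replicate(2000,
    simulate_traits(star, mvbm_params(0, matrix(1.3)))[1, 1])
  expect_equal(stats::var(reps), 1.3 * 2.5, tolerance = 0.1)

  # planted cross-trait correlation survives
  S <- matrix(c(1, 0.9, 0.9, 1), 2)
  set.seed(11)
  reps2 <- replicate(2000, simulate_traits(star, mvbm_params(c(0, 0), S))[1, ])
  expect_equal(stats::cor(reps2[1, ], reps2[2, ]), 0.9, tolerance = 0.05)

  expect_error(mvbm_params(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("tip covariance matches kron(Sigma, C) on small trees", {
  tr <- simulate_tree(5, seed = 33)
  S <- matrix(c(1, 0.5, 0.5, 2), 2)
  cfg <- plant_rate_shifts(tr, n_clade = 1, scalar_range = c(3, 3),
                           seed = 34)
  trs <- tr
  trs$edge.length <- tr$edge.length * effective_rates(tr, cfg)
  C <- ape::vcv(trs)[tr$tip.label, tr$tip.label]
  K <- kronecker(S, C)
  set.seed(35)
  draws <- t(replicate(5000, as.numeric(
    simulate_traits(tr, mvbm_params(c(0, 0), S), scalars = cfg))))
  emp <- stats::cov(draws)
  expect_lt(max(abs(emp - K)) / max(abs(K)), 0.1)
})

test_that("markup simulator applies corruptions exactly as declared", {
  tpl <- beak_template()
  m0 <- simulate_markups(tpl, 3, noise_sd = 0, seed = 1)
  for (u in m0$users) expect_equal(u$coords, tpl$coords, tolerance = 1e-12)

  m1 <- simulate_markups(tpl, 3, noise_sd = 0,
                         corruptions = list(list(user = 2,
                                                 type = "swap_tomial_edges")),
                         seed = 1)
  li <- which(tpl$curve == attr(tpl, "left_curve"))
  ri <- which(tpl$curve == attr(tpl, "right_curve"))
  expect_equal(m1$users[[2]]$coords[li, ], tpl$coords[ri, ])
  expect_equal(m1$users[[2]]$coords[ri, ], tpl$coords[li, ])
  expect_equal(m1$ledger$type, "swap_tomial_edges")

  m2 <- simulate_markups(tpl, 3, noise_sd = 0.005,
                         corruptions = list(list(user = 1,
                                                 type = "outlier_user",
                                                 distance = 0.3)),
                         seed = 2)
  expect_equal(procrustes_distance(tpl, m2$users[[1]]), 0.3,
               tolerance = 0.02)
  expect_error(simulate_markups(tpl, 2,
                                corruptions = list(list(user = 5,
                                                        type = "outlier_user"))),
               "missing user")
})

test_that("range grid simulator honours occupancy, islands, contiguity", {
  g1 <- simulate_range_grid(1, grid_dims = c(3, 4), cell_km = 110,
                            occupancy = 1, seed = 1)
  expect_equal(sort(g1$ranges[[1]]), 1:12)
  expect_equal(range_summaries(g1, names(g1$ranges)[1])$range_size,
               12 * 110^2)

  g2 <- simulate_range_grid(5, grid_dims = c(6, 6), occupancy = 0.3,
                            island_fraction = 0, seed = 2)
  for (sp in names(g2$ranges)) {
    expect_equal(range_summaries(g2, sp)$island_proportion, 0)
  }
  expect_error(simulate_range_grid(3, occupancy = 0), "occupancy")
})

test_that("predictor simulator plants a recoverable PGLS structure", {
  tr <- simulate_tree(40, seed = 4)
  sim0 <- simulate_predictors(tr, betas = NULL, noise_sd = 1e-12, seed = 1)
  expect_lt(stats::sd(sim0$response), 1e-10)  # all-zero betas: constant

  expect_error(simulate_predictors(tr, lambda = 1.5), "lambda")

  # lambda = 0: residuals uncorrelated across species (phylogenetic signal
  # of the response around its mean should be weak)
  sim <- simulate_predictors(tr, betas = NULL, lambda = 0, noise_sd = 1,
                             seed = 3)
  d <- sim$design; d$y <- sim$response
  f <- pgls(y ~ 1, d, tr, lambda = "ML")
  expect_lt(f$lambda, 0.5)
})
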