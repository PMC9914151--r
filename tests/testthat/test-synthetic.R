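test_that("generators are pure functions of their spec", {
  s <- frontier_spec(n_dmu = 5, n_efficient = 2, seed = 10)
  expect_identical(as.data.frame(gen_dea_panel(s)),
                   as.data.frame(gen_dea_panel(s)))
  cs <- chain_spec(diag(4), n_units = 10, n_years = 5, seed = 10)
  expect_identical(gen_markov_panel(cs)$values$rho,
                   gen_markov_panel(cs)$values$rho)
  expect_identical(gen_adjacency(12, "random_geometric", seed = 3)$W,
                   gen_adjacency(12, "random_geometric", seed = 3)$W)
})

test_that("frontier construction honours its spec", {
  expect_error(frontier_spec(inefficiency_factors = 0.9), ">= 1")
  # factors of exactly 1 make every unit a frontier copy: all efficient
  pan <- gen_dea_panel(frontier_spec(n_dmu = 4, n_efficient = 2,
                                     inefficiency_factors = 1, seed = 5))
  expect_true(all(efficiency_table(pan)$rho >= 1 - 1e-9))

  # single-input technologies use the concave frontier; labels still exact
  pan1 <- gen_dea_panel(frontier_spec(n_dmu = 5, n_inputs = 1, n_outputs = 1,
                                      n_efficient = 3, seed = 6))
  et <- efficiency_table(pan1)
  expect_equal(unname(et$rho >= 1 - 1e-9), unname(attr(pan1, "efficient")))
})

test_that("degenerate kernels simulate exactly", {
  cs <- chain_spec(diag(4), n_units = 8, n_years = 6, seed = 2)
  g <- gen_markov_panel(cs)
  S <- matrix(g$states$state[order(g$states$unit, g$states$year)], ncol = 6,
              byrow = TRUE)
  expect_true(all(S == S[, 1]))   # identity kernel: constant chains

  flip <- matrix(c(0, 1, 1, 0), 2)
  g2 <- gen_markov_panel(chain_spec(flip, n_units = 5, n_years = 8,
                                    cuts = 1, seed = 2))
  S2 <- matrix(g2$states$state[order(g2$states$unit, g2$states$year)],
               ncol = 8, byrow = TRUE)
  expect_true(all(abs(S2[, -1] - S2[, -8]) == 1))   # strict alternation
})

test_that("continuous values classify back to the generating states", {
  P <- matrix(c(.7,.2,.1,0, .2,.5,.3,0, 0,.3,.5,.2, 0,.1,.2,.7), 4, byrow = TRUE)
  cs <- chain_spec(P, n_units = 60, n_years = 15, seed = 9)
  g <- gen_markov_panel(cs)
  st <- classify_states(g$values, cs$cuts)
  expect_identical(st$state, g$states$state)
  expect_true(all(g$values$rho > 0))
})

test_that("long-run occupancy approaches the kernel's stationary law", {
  P <- matrix(c(.6,.3,.1,0, .2,.5,.3,0, .1,.2,.5,.2, 0,.1,.3,.6), 4,
              byrow = TRUE)
  g <- gen_markov_panel(chain_spec(P, n_units = 200, n_years = 500, seed = 4))
  S <- matrix(g$states$state[order(g$states$unit, g$states$year)], ncol = 500,
              byrow = TRUE)
  occ <- as.vector(table(factor(S[, 451:500], 1:4))) / (200 * 50)
  expect_equal(occ, stationary_distribution(P), tolerance = 0.03)
})

test_that("graph models have the advertised structure", {
  ring <- gen_adjacency(4, "ring")
  expect_equal(unname(rowSums(ring$W != 0)), rep(2, 4))
  grid <- gen_adjacency(9, "grid")
  expect_equal(sort(unname(rowSums(grid$W != 0))),
               c(2, 2, 2, 2, 3, 3, 3, 3, 4))
  set.seed(1)
  g <- gen_adjacency(20, "random_geometric", seed = 14)
  expect_true(isSymmetric(g$W))
  expect_equal(length(g$isolated), 0)
})
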