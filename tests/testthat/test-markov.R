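test_that("transition counts match hand tallies", {
  # two units over three years: u1 goes 1,1,2; u2 stays 2,2,2
  S <- rbind(c(1, 1, 2), c(2, 2, 2))
  tm <- transition_matrix(toy_state_panel(S, k = 4))
  expect_equal(unname(tm$probs[1, ]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(tm$probs[2, ]), c(0, 1, 0, 0))
  expect_equal(unname(tm$origin_totals), c(2, 2, 0, 0))
  expect_equal(tm$empty_rows, c(`3` = 3L, `4` = 4L))
  expect_equal(sum(tm$origin_totals), 2 * (3 - 1))

  # constant states give the identity on occupied rows
  tc <- transition_matrix(toy_state_panel(rbind(c(3, 3, 3), c(1, 1, 1)), k = 4))
  expect_equal(unname(diag(tc$probs)[c(1, 3)]), c(1, 1))
})

test_that("initial distribution is origin-window occupancy", {
  S <- rbind(c(1, 2, 4), c(2, 2, 1), c(3, 3, 3), c(4, 1, 2))
  # origin years are the first two columns
  expect_equal(initial_distribution(toy_state_panel(S, k = 4)),
               c(2, 3, 2, 1) / 8)
  all2 <- toy_state_panel(matrix(2L, 3, 4), k = 4)
  expect_equal(initial_distribution(all2), c(0, 1, 0, 0))
})

test_that("transition types compare endpoint states", {
  S <- rbind(c(1, 3), c(4, 2), c(2, 2))
  tt <- transition_type_map(toy_state_panel(S))
  expect_equal(tt$type, c("upward", "downward", "unchanged"))
  expect_equal(tt$from, c(1, 4, 2))
})

test_that("row standardisation gives uniform neighbour weights", {
  path <- adjacency_map(data.frame(unit_a = c("A", "B"), unit_b = c("B", "C")))
  w <- row_standardize(path)
  expect_equal(unname(w$W["B", c("A", "C")]), c(0.5, 0.5))
  expect_equal(unname(rowSums(w$W)), c(1, 1, 1))

  ring <- row_standardize(gen_adjacency(6, "ring"))
  expect_true(all(abs(rowSums(ring$W) - 1) < 1e-12))

  set.seed(8)
  for (rep in 1:5) {
    g <- row_standardize(gen_adjacency(sample(5:15, 1), "random_geometric",
                                       seed = rep))
    rs <- rowSums(g$W)
    expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
    expect_equal(g$units[rs == 0], g$isolated)
  }
})

test_that("spatial lag values are the neighbour averages", {
  # two mutual neighbours: each unit's lag equals the other's score
  pan <- toy_eff_panel(rbind(c(0.3, 0.4), c(1.5, 1.6)))
  adj <- adjacency_map(data.frame(unit_a = "u01", unit_b = "u02"))
  lag <- spatial_lag_states(pan, adj, k = 2, breaks = 1.0)
  lv <- attr(lag, "lag_values")
  expect_equal(unname(lv["u01", ]), c(1.5, 1.6))
  expect_equal(unname(lv["u02", ]), c(0.3, 0.4))
  expect_equal(lag$state[lag$unit == "u01"], c(2L, 2L))
  expect_equal(lag$state[lag$unit == "u02"], c(1L, 1L))

  iso <- adjacency_map(data.frame(unit_a = "u01", unit_b = "u02"),
                       units = c("u01", "u02", "u03"))
  pan3 <- toy_eff_panel(rbind(c(0.3, 0.4), c(1.5, 1.6), c(1, 1)))
  expect_error(spatial_lag_states(pan3, iso, k = 2, breaks = 1.0),
               "isolated")
  expect_warning(l3 <- spatial_lag_states(pan3, iso, k = 2, breaks = 1.0,
                                          isolated = "drop"), "dropping")
  expect_equal(sort(unique(l3$unit)), c("u01", "u02"))
})

test_that("conditional matrices conserve the traditional counts", {
  set.seed(31)
  S <- matrix(sample(1:4, 40 * 6, TRUE), 40)
  Lg <- matrix(sample(1:4, 40 * 6, TRUE), 40)
  st <- toy_state_panel(S, 4); lg <- toy_state_panel(Lg, 4)
  sts <- spatial_transition_set(st, lg)
  total <- Reduce(`+`, lapply(sts$blocks, `[[`, "counts"))
  expect_equal(total, transition_matrix(st)$counts)
  for (blk in sts$blocks) {
    rs <- rowSums(blk$probs)
    expect_true(all(abs(rs - 1) < 1e-9 | blk$origin_totals == 0))
  }
  # a single shared lag class reproduces the traditional matrix
  one <- toy_state_panel(matrix(1L, 40, 6), 4)
  sts1 <- spatial_transition_set(st, one)
  expect_equal(sts1$blocks[[1]]$probs, transition_matrix(st)$probs)
  expect_true(all(sts1$blocks[[2]]$counts == 0))
})

test_that("limiting distributions are fixed points", {
  expect_equal(as.vector(limiting_distribution(diag(4), c(0.1, 0.2, 0.3, 0.4))),
               c(0.1, 0.2, 0.3, 0.4))
  P <- matrix(0.5, 2, 2)
  expect_equal(as.vector(limiting_distribution(P, c(0.9, 0.1))), c(0.5, 0.5))
})

test_that("power iteration matches the algebraic stationary solution", {
  set.seed(12)
  for (rep in 1:8) {
    k <- sample(2:5, 1)
    P <- matrix(rgamma(k * k, 1) + 0.05, k)   # strictly positive: irreducible
    P <- P / rowSums(P)
    pi_pow <- limiting_distribution(P, rep(1 / k, k), tol = 1e-14)
    pi_alg <- stationary_distribution(P)
    expect_equal(as.vector(pi_pow), pi_alg, tolerance = 1e-10)
    expect_equal(unname(as.vector(pi_alg %*% P)), pi_alg, tolerance = 1e-12)
  }
})

test_that("reducible chains match the fundamental-matrix closed form", {
  # states 1-2 transient, 3 and 4 absorbing
  P <- rbind(c(0.5, 0.2, 0.2, 0.1),
             c(0.3, 0.4, 0.1, 0.2),
             c(0,   0,   1,   0),
             c(0,   0,   0,   1))
  pi0 <- c(0.4, 0.4, 0.1, 0.1)
  lim <- limiting_distribution(P, pi0, tol = 1e-14)
  expect_equal(as.vector(lim), absorption_limit(P, c(3, 4), pi0),
               tolerance = 1e-10)
})

test_that("periodic chains fail pointwise but converge in Cesaro mode", {
  P <- rbind(c(0, 1), c(1, 0))
  expect_error(limiting_distribution(P, c(0.8, 0.2), max_iter = 500),
               "periodic")
  ces <- limiting_distribution(P, c(0.8, 0.2), cesaro = TRUE)
  expect_equal(as.vector(ces), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("empty rows are flagged and treated as absorbing", {
  P <- rbind(c(0.5, 0.5, 0), c(0.2, 0.8, 0), c(0, 0, 0))
  expect_warning(lim <- limiting_distribution(P, c(0.3, 0.3, 0.4)),
                 "absorbing")
  expect_equal(unname(lim[3]), 0.4)
  bad <- rbind(c(0.7, 0.2), c(0.5, 0.5))
  expect_error(limiting_distribution(bad, c(0.5, 0.5)), "stochastic")
})
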