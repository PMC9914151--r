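two_dmu <- function() indicator_panel(data.frame(
  unit = c("A", "B"), year = 2020, region = "central",
  x1 = c(1, 2), y1 = c(1, 1)))

test_that("hand-solvable SBM instances score correctly", {
  p <- two_dmu()
  b <- sbm_score(p, "B", 2020)
  expect_equal(b$rho, 0.5)
  expect_equal(b$input_slacks, 1)
  expect_equal(b$output_slacks, 0)
  expect_equal(b$status, "inefficient")
  # rho equals the slack ratio evaluated at the solution
  expect_equal(b$rho, (1 - mean(b$input_slacks / 2)) /
                 (1 + mean(b$output_slacks / 1)))

  a <- sbm_score(p, "A", 2020)
  expect_equal(a$rho, 1)
  expect_equal(a$status, "efficient")

  # a unit identical to a frontier unit is efficient
  p3 <- indicator_panel(data.frame(
    unit = c("A", "A2", "B"), year = 2020, region = "central",
    x1 = c(1, 1, 2), y1 = c(1, 1, 1)))
  expect_equal(sbm_score(p3, "A2", 2020)$rho, 1)
})

test_that("super-efficiency scores and guards behave", {
  p <- two_dmu()
  expect_equal(super_sbm_score(p, "A", 2020, dea_config("crs"))$rho, 2)
  expect_error(super_sbm_score(p, "B", 2020), "inefficient")

  # duplicate of the evaluated unit keeps the super score at 1
  p3 <- indicator_panel(data.frame(
    unit = c("A", "A2", "B"), year = 2020, region = "central",
    x1 = c(1, 1, 2), y1 = c(1, 1, 1)))
  expect_equal(super_sbm_score(p3, "A", 2020, dea_config("crs"))$rho, 1)

  # collinear CRS technology: interior unit is efficient but not extreme
  pc <- indicator_panel(data.frame(
    unit = c("A", "B", "C"), year = 2020, region = "central",
    x1 = c(1, 2, 3), y1 = c(1, 2, 3)))
  expect_equal(super_sbm_score(pc, "B", 2020, dea_config("crs"))$rho, 1)

  # extreme unit under VRS: the non-oriented exclusion program stays
  # feasible (outputs may contract towards the remaining frontier);
  # hand solution: xbar = 1, ybar = 1 gives delta = (1/1)/(1/5) = 5
  pe <- indicator_panel(data.frame(
    unit = c("A", "B"), year = 2020, region = "central",
    x1 = c(1, 1), y1 = c(5, 1)))
  sol <- super_sbm_score(pe, "A", 2020, dea_config("vrs"))
  expect_equal(sol$status, "efficient")
  expect_equal(sol$rho, 5)
})

test_that("LP optimum agrees with the dense lambda-grid oracle", {
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(2:3, 1); m <- sample(1:2, 1); q <- sample(1:2, 1)
    df <- data.frame(unit = LETTERS[1:n], year = 2020, region = "central")
    for (i in 1:m) df[[paste0("x", i)]] <- round(runif(n, 1, 5), 2)
    for (r in 1:q) df[[paste0("y", r)]] <- round(runif(n, 1, 5), 2)
    p <- indicator_panel(df)
    X <- t(as.matrix(df[, paste0("x", 1:m), drop = FALSE]))
    Y <- t(as.matrix(df[, paste0("y", 1:q), drop = FALSE]))
    for (k in 1:n) {
      lp <- sbm_score(p, LETTERS[k], 2020, dea_config("vrs"))
      oracle <- sbm_grid_oracle(X, Y, k)
      expect_equal(lp$rho, min(oracle, 1), tolerance = 1e-3,
                   label = sprintf("rep %d unit %d", rep, k))
    }
  }
})

test_that("SBM is units-invariant and properly bounded", {
  set.seed(7)
  n <- 6
  df <- data.frame(unit = sprintf("u%d", 1:n), year = 2020, region = "central",
                   x1 = runif(n, 1, 5), x2 = runif(n, 1, 5),
                   y1 = runif(n, 1, 5), y2 = runif(n, 1, 5))
  p <- indicator_panel(df)
  rho <- vapply(df$unit, function(u) sbm_score(p, u, 2020)$rho, numeric(1))
  expect_true(all(rho > 0 & rho <= 1))

  scaled <- df
  scaled$x1 <- scaled$x1 * 1000
  scaled$y2 <- scaled$y2 / 50
  ps <- indicator_panel(scaled)
  rho2 <- vapply(df$unit, function(u) sbm_score(ps, u, 2020)$rho, numeric(1))
  expect_equal(rho, rho2, tolerance = 1e-8)

  # increasing one input of one unit never increases its score
  worse <- df
  worse$x1[3] <- worse$x1[3] * 1.5
  pw <- indicator_panel(worse)
  expect_lte(sbm_score(pw, "u3", 2020)$rho, rho[3] + 1e-9)
})

test_that("reference weights are consistent under VRS", {
  set.seed(11)
  n <- 5
  df <- data.frame(unit = sprintf("u%d", 1:n), year = 2020, region = "central",
                   x1 = runif(n, 1, 4), y1 = runif(n, 1, 4))
  p <- indicator_panel(df)
  for (u in df$unit) {
    sol <- sbm_score(p, u, 2020)
    expect_equal(sum(sol$lambda), 1, tolerance = 1e-9)
    expect_true(all(sol$lambda >= -1e-10))
  }
})

test_that("efficiency_table flags exactly the constructed frontier", {
  for (seed in c(2, 13, 77)) {
    pan <- gen_dea_panel(frontier_spec(n_dmu = 6, n_inputs = 2, n_outputs = 2,
                                       n_efficient = 2,
                                       inefficiency_factors = 1.5,
                                       seed = seed))
    et <- efficiency_table(pan)
    expect_equal(unname(et$rho >= 1 - 1e-9), unname(attr(pan, "efficient")),
                 label = paste("seed", seed))
  }
  # identical DMUs are all efficient with score 1
  same <- indicator_panel(data.frame(
    unit = sprintf("u%d", 1:4), year = 2020, region = "central",
    x1 = 2, y1 = 3))
  expect_equal(efficiency_table(same)$rho, rep(1, 4))
})

test_that("whole-table scores are units-invariant", {
  pan <- gen_dea_panel(frontier_spec(n_dmu = 5, n_efficient = 2, seed = 9))
  et1 <- efficiency_table(pan)
  df <- as.data.frame(pan)
  df$x1 <- df$x1 * 10
  df$x2 <- df$x2 * 10
  et2 <- efficiency_table(indicator_panel(df))
  expect_equal(et1$rho, et2$rho, tolerance = 1e-8)
})
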