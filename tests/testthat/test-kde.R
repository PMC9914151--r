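test_that("bandwidth rule has the stated closed form", {
  # constant fixed to 1: pure n^(-1/5) rate
  expect_equal(bandwidth_rule(rep(c(0, 1), 16), const = 1), 32^(-0.2))
  v <- rnorm(20, sd = 0.4)
  expect_equal(bandwidth_rule(v, const = 1.06 * sd(v)),
               1.06 * sd(v) * 20^(-0.2))
  # default robust constant matches R's rule-of-thumb
  expect_equal(bandwidth_rule(v), stats::bw.nrd0(v))
  # scale equivariance: doubling the data doubles the default bandwidth
  expect_equal(bandwidth_rule(2 * v), 2 * bandwidth_rule(v))
  expect_error(bandwidth_rule(rep(1, 10)), "zero spread")
})

test_that("density values match the closed-form kernel sum", {
  c1 <- gaussian_kde(0, h = 1, from = -1, to = 1, n_grid = 3)
  expect_equal(c1$density[2], 1 / sqrt(2 * pi))   # single kernel at centre

  c2 <- gaussian_kde(c(-1, 1), h = 1, from = -1, to = 1, n_grid = 3)
  expect_equal(c2$density[2], dnorm(1))           # two-point midpoint value

  expect_error(gaussian_kde(numeric(0)), "length")
})

test_that("curves normalise, agree with stats::density, and are symmetric", {
  set.seed(21)
  v <- rnorm(40)
  h <- bandwidth_rule(v)
  cur <- gaussian_kde(v, h, pad = 5)
  expect_true(all(cur$density >= 0))
  expect_equal(.trapz_test(cur$grid, cur$density), 1, tolerance = 1e-3)

  ref <- stats::density(v, bw = h, from = min(cur$grid), to = max(cur$grid),
                        n = 512)
  expect_equal(cur$density, ref$y, tolerance = 1e-3)

  # symmetric sample on a symmetric grid gives a symmetric estimate
  vs <- c(-2, -1, 1, 2)
  cs <- gaussian_kde(vs, h = 0.5, from = -4, to = 4, n_grid = 401)
  expect_equal(cs$density, rev(cs$density), tolerance = 1e-9)
})

test_that("mass concentrates near observations as h shrinks", {
  v <- c(0, 1, 3)
  for (h in c(0.2, 0.05, 0.01)) {
    cur <- gaussian_kde(v, h, from = -1, to = 4, n_grid = 2001)
    # the 10%-of-maximum level set collapses onto the observations with h
    top <- cur$grid[cur$density >= 0.1 * max(cur$density)]
    spread <- max(vapply(top, function(g) min(abs(g - v)), numeric(1)))
    expect_lt(spread, 3 * h + 0.01)
  }
})

test_that("peak detection finds constructed modes", {
  uni <- gaussian_kde(rnorm(200, 5, 0.5), h = 0.3, pad = 4)
  expect_equal(nrow(curve_shape(uni)$peaks), 1)

  set.seed(3)
  bim <- c(rnorm(150, 0, 0.3), rnorm(150, 4, 0.3))
  cur <- gaussian_kde(bim, h = 0.25, pad = 4)
  sh <- curve_shape(cur)
  expect_equal(nrow(sh$peaks), 2)
  expect_equal(sh$peaks$position, c(0, 4), tolerance = 0.15)
  expect_equal(unname(sh$main_peak["height"]), max(cur$density))
})

test_that("fixture distribution keeps two peaks with a falling main peak", {
  eff <- supply_efficiency()
  curves <- kde_by_year(eff)
  shapes <- lapply(curves, curve_shape)
  for (yy in names(shapes))
    expect_gte(nrow(shapes[[yy]]$peaks), 2)
  expect_lt(shapes[["2019"]]$main_peak["height"],
            shapes[["2011"]]$main_peak["height"])
})
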