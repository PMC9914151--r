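#' Synthetic ground-truth generators
#'
#' Every pipeline stage gets a generator whose output has a known answer:
#' DEA panels with a constructed efficient frontier, state panels evolving
#' under known (optionally lag-conditioned) transition kernels on a known
#' graph, and random contiguity graphs. All generators are pure functions of
#' their spec: the RNG kind is pinned (Mersenne-Twister / Inversion /
#' Rejection) and seeded from the spec, so outputs are identical across runs
#' and platforms. The generators target statistical structure, not the
#' magnitudes of any real yearbook data.
#'
#' @name synthetic
NULL

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Frontier specification for synthetic DEA panels
#'
#' @param n_dmu total units per year.
#' @param n_inputs,n_outputs indicator counts.
#' @param n_efficient number of frontier units (`<= n_dmu`).
#' @param inefficiency_factors multipliers `>= 1` applied to the inputs of
#'   the `n_dmu - n_efficient` non-frontier units (recycled); factors above 1
#'   make the unit strictly dominated.
#' @param n_years years to generate (independent cross-sections).
#' @param noise_sd sd of optional multiplicative log-normal indicator noise
#'   (0 = exact frontier, the default; only for robustness experiments —
#'   truth labels assume no noise).
#' @param seed RNG seed.
#' @return a `frontier_spec` list.
#' @export
frontier_spec <- function(n_dmu = 6, n_inputs = 2, n_outputs = 2,
                          n_efficient = 2, inefficiency_factors = 1.5,
                          n_years = 1, noise_sd = 0, seed = 1) {
  stopifnot(n_efficient >= 1, n_efficient <= n_dmu,
            n_inputs >= 1, n_outputs >= 1)
  if (any(inefficiency_factors < 1))
    stop("inefficiency factors must be >= 1", call. = FALSE)
  structure(list(n_dmu = n_dmu, n_inputs = n_inputs, n_outputs = n_outputs,
                 n_efficient = n_efficient,
                 inefficiency_factors = inefficiency_factors,
                 n_years = n_years, noise_sd = noise_sd, seed = seed),
            class = "frontier_spec")
}

#' Generate a DEA panel with a known frontier
#'
#' Frontier units are efficient by construction under variable returns to
#' scale: with two or more inputs they share a common output vector while
#' their first two inputs sit on a strictly convex curve (`x2 = c/x1`), so no
#' convex combination of peers can weakly dominate any of them; with a single
#' input they sit on a strictly concave increasing production function
#' (`y1 = sqrt(x1)`), making each a vertex of the VRS frontier. Every
#' non-frontier unit is a frontier unit with all inputs scaled up by a factor
#' `> 1`, hence strictly dominated and inefficient. The true labels travel
#' with the panel as attribute `"efficient"`.
#'
#' @param spec a [frontier_spec()].
#' @return an [indicator_panel()] with attribute `"efficient"` (logical,
#'   per unit).
#' @export
gen_dea_panel <- function(spec) {
  stopifnot(inherits(spec, "frontier_spec"))
  .with_seed(spec$seed, {
    m <- spec$n_inputs; q <- spec$n_outputs
    ne <- spec$n_efficient; n <- spec$n_dmu
    fac <- rep_len(spec$inefficiency_factors, n - ne)
    units <- sprintf("dmu%02d", seq_len(n))
    rows <- list()
    for (yy in seq_len(spec$n_years)) {
      tpar <- sort(stats::runif(ne, 1, 3))
      X <- matrix(1, m, n); Y <- matrix(1, q, n)
      if (m >= 2) {
        X[1, 1:ne] <- tpar
        X[2, 1:ne] <- 2 / tpar          # strictly convex input boundary
        Y[1, 1:ne] <- 2                  # common outputs
      } else {
        X[1, 1:ne] <- tpar
        Y[1, 1:ne] <- sqrt(tpar)         # strictly concave frontier
        if (q >= 2) Y[2:q, 1:ne] <- 1
      }
      if (n > ne) {
        src <- rep_len(seq_len(ne), n - ne)
        X[, (ne + 1):n] <- X[, src, drop = FALSE] * rep(fac, each = m)
        Y[, (ne + 1):n] <- Y[, src, drop = FALSE]
      }
      if (spec$noise_sd > 0) {
        X <- X * exp(matrix(stats::rnorm(m * n, 0, spec$noise_sd), m, n))
        Y <- Y * exp(matrix(stats::rnorm(q * n, 0, spec$noise_sd), q, n))
      }
      df <- data.frame(unit = units, year = 2000L + yy,
                       region = rep(c("central", "western"), length.out = n),
                       stringsAsFactors = FALSE)
      for (i in seq_len(m)) df[[paste0("x", i)]] <- X[i, ]
      for (r in seq_len(q)) df[[paste0("y", r)]] <- Y[r, ]
      rows[[yy]] <- df
    }
    panel <- indicator_panel(do.call(rbind, rows))
    attr(panel, "efficient") <- stats::setNames(
      seq_len(n) <= ne, units)[order(units)]
    panel
  })
}

#' Chain specification for synthetic state panels
#'
#' @param kernels one row-stochastic `k x k` matrix, or a list of `k` such
#'   matrices (one per spatial-lag state) for lag-conditioned evolution.
#' @param n_units,n_years panel dimensions.
#' @param pi0 initial state distribution (default uniform).
#' @param adjacency an [adjacency_map()] (required for lag-conditioned
#'   kernels).
#' @param cuts state cut points used when materialising continuous values;
#'   class value bands sit strictly inside the cut intervals (5% margin) so
#'   classification recovers the states exactly.
#' @param seed RNG seed.
#' @return a `chain_spec` list.
#' @export
chain_spec <- function(kernels, n_units = 100, n_years = 20, pi0 = NULL,
                       adjacency = NULL, cuts = c(0.5, 0.85, 1.25),
                       seed = 1) {
  klist <- if (is.matrix(kernels)) list(kernels) else kernels
  k <- nrow(klist[[1]])
  for (P in klist) {
    stopifnot(is.matrix(P), nrow(P) == k, ncol(P) == k, all(P >= 0))
    if (any(abs(rowSums(P) - 1) > 1e-9))
      stop("kernel rows must sum to 1", call. = FALSE)
  }
  lagged <- length(klist) > 1
  if (lagged && length(klist) != k)
    stop("need one kernel per lag state (", k, ")", call. = FALSE)
  if (lagged && is.null(adjacency))
    stop("lag-conditioned kernels need an adjacency map", call. = FALSE)
  if (is.null(pi0)) pi0 <- rep(1 / k, k)
  stopifnot(length(pi0) == k, abs(sum(pi0) - 1) < 1e-9,
            length(cuts) == k - 1)
  structure(list(kernels = klist, k = k, lagged = lagged, n_units = n_units,
                 n_years = n_years, pi0 = pi0, adjacency = adjacency,
                 cuts = cuts, seed = seed),
            class = "chain_spec")
}

# class value bands strictly inside the cut intervals (5% margin per side);
# the open end classes get a band as wide as the mean interior interval
.class_bands <- function(cuts) {
  k <- length(cuts) + 1
  w0 <- if (k > 2) mean(diff(cuts)) else 0.5
  lo_edge <- c(cuts[1] - w0, cuts)
  hi_edge <- c(cuts, cuts[k - 1] + w0)
  w <- hi_edge - lo_edge
  cbind(lo = lo_edge + 0.05 * w, hi = hi_edge - 0.05 * w)
}

#' Simulate a state panel from known kernels
#'
#' Unit chains start from `pi0` and step through the kernel — when
#' lag-conditioned, the kernel indexed by the unit's current lag class, i.e.
#' the class of the neighbour-weighted average of the current continuous
#' values under the spec's cuts. Continuous values are drawn uniformly
#' within class bands lying strictly inside the cut intervals, so
#' classification under `spec$cuts` recovers the states exactly.
#'
#' @param spec a [chain_spec()].
#' @return list with `states` (`state_panel`), `values`
#'   ([efficiency_panel()]), `lag_states` (`state_panel`, lag-conditioned
#'   specs only) and `spec`.
#' @export
gen_markov_panel <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  .with_seed(spec$seed, {
    k <- spec$k; nu <- spec$n_units; ny <- spec$n_years
    units <- sprintf("u%04d", seq_len(nu))
    bands <- .class_bands(spec$cuts)
    W <- NULL
    if (spec$lagged) {
      adj <- spec$adjacency
      if (!adj$standardized) adj <- row_standardize(adj)
      if (length(adj$units) != nu)
        stop("adjacency size must equal n_units", call. = FALSE)
      W <- adj$W
    }
    S <- matrix(0L, nu, ny)
    V <- matrix(0, nu, ny)
    LG <- matrix(0L, nu, ny)
    S[, 1] <- sample.int(k, nu, replace = TRUE, prob = spec$pi0)
    V[, 1] <- stats::runif(nu, bands[S[, 1], "lo"], bands[S[, 1], "hi"])
    for (t in seq_len(ny - 1)) {
      if (spec$lagged) {
        lagv <- as.vector(W %*% V[, t])
        LG[, t] <- findInterval(lagv, spec$cuts) + 1L
      } else LG[, t] <- 1L
      for (u in seq_len(nu)) {
        P <- if (spec$lagged) spec$kernels[[LG[u, t]]] else spec$kernels[[1]]
        S[u, t + 1] <- sample.int(k, 1, prob = P[S[u, t], ])
      }
      V[, t + 1] <- stats::runif(nu, bands[S[, t + 1], "lo"],
                                 bands[S[, t + 1], "hi"])
    }
    yrs <- seq_len(ny)
    long <- function(M) data.frame(
      unit = rep(units, ny), year = rep(yrs, each = nu),
      state = as.vector(M), stringsAsFactors = FALSE)
    states <- structure(.canonical(long(S)),
                        class = c("state_panel", "data.frame"), k = k)
    vals <- efficiency_panel(data.frame(
      unit = rep(units, ny), year = rep(yrs, each = nu),
      region = "synthetic", rho = as.vector(V), stringsAsFactors = FALSE))
    out <- list(states = states, values = vals, spec = spec)
    if (spec$lagged) {
      LG[, ny] <- {  # final-year lag classes, for completeness
        lagv <- as.vector(W %*% V[, ny])
        findInterval(lagv, spec$cuts) + 1L
      }
      out$lag_states <- structure(.canonical(long(LG)),
                                  class = c("state_panel", "data.frame"),
                                  k = k)
    }
    out
  })
}

#' Random contiguity graphs
#'
#' Connected symmetric graphs for lag-conditioned simulations: a cycle, a
#' square grid, or a random geometric graph (points in the unit square,
#' connected within radius `r`; resampled up to `retries` times if
#' disconnected).
#'
#' @param n_units number of nodes.
#' @param model `"ring"`, `"grid"` or `"random_geometric"`.
#' @param r connection radius for the geometric model.
#' @param seed RNG seed.
#' @param retries resample cap for disconnected geometric draws.
#' @return an [adjacency_map()] (not yet row-standardised).
#' @export
gen_adjacency <- function(n_units, model = c("ring", "grid",
                                             "random_geometric"),
                          r = NULL, seed = 1, retries = 50) {
  model <- match.arg(model)
  stopifnot(n_units >= 2)
  units <- sprintf("u%04d", seq_len(n_units))
  W <- matrix(0, n_units, n_units, dimnames = list(units, units))
  connected <- function(W) {
    seen <- logical(nrow(W)); seen[1] <- TRUE; front <- 1L
    while (length(front)) {
      nb <- which(colSums(W[front, , drop = FALSE] != 0) > 0 & !seen)
      seen[nb] <- TRUE; front <- nb
    }
    all(seen)
  }
  if (model == "ring") {
    for (i in seq_len(n_units)) {
      j <- i %% n_units + 1L
      W[i, j] <- W[j, i] <- 1
    }
  } else if (model == "grid") {
    side <- ceiling(sqrt(n_units))
    for (i in seq_len(n_units)) {
      row <- (i - 1) %/% side; col <- (i - 1) %% side
      if (col < side - 1 && i + 1 <= n_units) W[i, i + 1] <- W[i + 1, i] <- 1
      if (i + side <= n_units) W[i, i + side] <- W[i + side, i] <- 1
    }
  } else {
    if (is.null(r)) r <- 1.5 * sqrt(log(n_units) / (pi * n_units))
    .with_seed(seed, {
      for (try in seq_len(retries)) {
        px <- stats::runif(n_units); py <- stats::runif(n_units)
        D <- as.matrix(stats::dist(cbind(px, py)))
        W[] <- (D <= r) * 1
        diag(W) <- 0
        if (connected(W)) break
        if (try == retries) stop("could not draw a connected geometric graph",
                                 call. = FALSE)
      }
    })
  }
  adjacency_map(W)
}
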