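# Independent oracles and small fixture builders used across test files.

# Dense two-stage grid search over the lambda simplex (VRS) for the SBM
# fractional program: for fixed lambda the slacks are determined, so the
# optimum is a minimum over the simplex. Independent of the LP route.
sbm_grid_oracle <- function(X, Y, k, step = 0.0025) {
  J <- ncol(X)
  xk <- X[, k]; yk <- Y[, k]
  eval_rho <- function(Lam) {  # Lam: J x N
    sin_ <- xk - X %*% Lam     # required input slacks
    sout <- Y %*% Lam - yk     # required output slacks
    feas <- colSums(sin_ < -1e-9) == 0 & colSums(sout < -1e-9) == 0
    num <- 1 - colMeans(pmax(sin_, 0) / xk)
    den <- 1 + colMeans(pmax(sout, 0) / yk)
    rho <- num / den
    rho[!feas] <- Inf
    rho
  }
  simplex_grid <- function(step, centre = NULL, width = NULL) {
    s <- seq(0, 1, by = step)
    if (!is.null(centre)) {
      lo <- pmax(centre - width, 0); hi <- pmin(centre + width, 1)
      if (J == 1) return(matrix(1, 1, 1))
      s1 <- seq(lo[1], hi[1], by = step)
      if (J == 2) return(rbind(s1, 1 - s1))
      s2 <- seq(lo[2], hi[2], by = step)
      g <- expand.grid(s1, s2)
      g <- g[g[, 1] + g[, 2] <= 1 + 1e-12, ]
      return(rbind(g[, 1], g[, 2], pmax(1 - g[, 1] - g[, 2], 0)))
    }
    if (J == 1) return(matrix(1, 1, 1))
    if (J == 2) return(rbind(s, 1 - s))
    g <- expand.grid(s, s)
    g <- g[g[, 1] + g[, 2] <= 1 + 1e-12, ]
    rbind(g[, 1], g[, 2], pmax(1 - g[, 1] - g[, 2], 0))
  }
  Lam <- simplex_grid(step)
  rho <- eval_rho(Lam)
  best <- which.min(rho)
  Lam2 <- simplex_grid(1e-4, centre = Lam[, best], width = 2 * step)
  min(rho[best], min(eval_rho(Lam2)))
}

# exhaustive Fisher-Jenks oracle: enumerate every split of the sorted values
# into k contiguous classes
jenks_exhaustive <- function(values, k) {
  x <- sort(values); n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf; best_b <- NULL
  for (b in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    bounds <- c(0, b, n)
    tot <- sum(vapply(seq_len(k),
                      function(i) sse(x[(bounds[i] + 1):bounds[i + 1]]),
                      numeric(1)))
    if (tot < best - 1e-12) { best <- tot; best_b <- b }
  }
  list(sse = best, cuts = (x[best_b] + x[best_b + 1]) / 2)
}

# absorption distribution of a chain with transient block Q and absorption
# probabilities R into absorbing states, from the fundamental matrix
absorption_limit <- function(P, absorbing, pi0) {
  tr <- setdiff(seq_len(nrow(P)), absorbing)
  Q <- P[tr, tr, drop = FALSE]
  R <- P[tr, absorbing, drop = FALSE]
  B <- solve(diag(length(tr)) - Q, R)   # absorption probabilities
  out <- numeric(nrow(P))
  out[absorbing] <- pi0[absorbing] + as.vector(pi0[tr] %*% B)
  out
}

# trapezoid integral (independent of the package's internal helper)
.trapz_test <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# small efficiency panel builder
toy_eff_panel <- function(values, years = NULL, region = "central") {
  n <- nrow(values)
  if (is.null(years)) years <- seq_len(ncol(values)) + 2000
  efficiency_panel(data.frame(
    unit = rep(sprintf("u%02d", seq_len(n)), length(years)),
    year = rep(years, each = n),
    region = region,
    rho = as.vector(values)))
}

# state panel from a units x years integer matrix
toy_state_panel <- function(S, k = max(S)) {
  structure(
    data.frame(unit = rep(sprintf("u%02d", seq_len(nrow(S))), ncol(S)),
               year = rep(seq_len(ncol(S)) + 2000, each = nrow(S)),
               state = as.vector(S)),
    class = c("state_panel", "data.frame"), k = k)
}
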