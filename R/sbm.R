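#' DEA configuration
#'
#' @param rts returns-to-scale assumption: `"vrs"` adds the convexity row
#'   `sum(lambda) = 1`; `"crs"` leaves the cone unconstrained.
#' @param pool frontier pool: `"per_year"` evaluates each unit against its own
#'   year's cross-section (the default; within-year rankings are what the
#'   reference panel reports), `"pooled"` against all unit-years.
#' @param epsilon slack-sum tolerance for classifying a unit as efficient.
#' @return a `dea_config` list.
#' @export
dea_config <- function(rts = c("vrs", "crs"), pool = c("per_year", "pooled"),
                       epsilon = 1e-6) {
  rts <- match.arg(rts)
  pool <- match.arg(pool)
  stopifnot(epsilon > 0, epsilon <= 1e-4)
  structure(list(rts = rts, pool = pool, epsilon = epsilon),
            class = "dea_config")
}

# input/output matrices (rows = indicators, cols = units) for a frontier pool
.pool_matrices <- function(panel, year, config) {
  sub <- if (config$pool == "per_year") panel[panel$year == year, ] else panel
  if (!nrow(sub)) stop("empty frontier pool", call. = FALSE)
  xin <- attr(panel, "inputs"); yout <- attr(panel, "outputs")
  list(X = t(as.matrix(sub[, xin, drop = FALSE])),
       Y = t(as.matrix(sub[, yout, drop = FALSE])),
       ids = paste(sub$unit, sub$year))
}

# Charnes-Cooper linearized SBM / super-SBM.
# Variables z = (t, Lambda_ref, S-_1..m, S+_1..q), all >= 0.
# Plain SBM:  min t - (1/m) sum S-_i/x_ik
#   s.t. t + (1/q) sum S+_r/y_rk = 1
#        X Lambda + S- - t x_k = 0,  Y Lambda - S+ - t y_k = 0
#        [vrs] sum Lambda - t = 0
# Super-SBM (reference set excludes k; the evaluated point (xbar, ybar)
# = (x_k + s-, y_k - s+) must be reachable from the remaining frontier):
#   min t + (1/m) sum S-_i/x_ik
#   s.t. t - (1/q) sum S+_r/y_rk = 1
#        X Lambda - S- - t x_k <= 0,  Y Lambda + S+ - t y_k >= 0
#        S+_r - t y_rk <= 0 (ybar >= 0), [vrs] sum Lambda - t = 0
.sbm_lp <- function(X, Y, xk, yk, exclude = NULL, rts = "vrs", super = FALSE) {
  if (!is.null(exclude)) {
    X <- X[, -exclude, drop = FALSE]
    Y <- Y[, -exclude, drop = FALSE]
  }
  m <- nrow(X); q <- nrow(Y); J <- ncol(X)
  if (J == 0) stop("empty reference set", call. = FALSE)
  nv <- 1L + J + m + q
  iT <- 1L; iL <- 1L + seq_len(J); iS <- 1L + J + seq_len(m)
  iP <- 1L + J + m + seq_len(q)
  vrs <- rts == "vrs"
  sgn <- if (super) -1 else 1
  cvec <- numeric(nv)
  cvec[iT] <- 1
  cvec[iS] <- -sgn / (m * xk)
  norm_row <- numeric(nv); norm_row[iT] <- 1; norm_row[iP] <- sgn / (q * yk)
  in_rows <- matrix(0, m, nv)
  for (i in seq_len(m)) {
    in_rows[i, iL] <- X[i, ]
    in_rows[i, iS[i]] <- sgn
    in_rows[i, iT] <- -xk[i]
  }
  out_rows <- matrix(0, q, nv)
  for (r in seq_len(q)) {
    out_rows[r, iL] <- Y[r, ]
    out_rows[r, iP[r]] <- -sgn
    out_rows[r, iT] <- -yk[r]
  }
  A <- rbind(norm_row, in_rows, out_rows)
  dir <- c("=", rep(if (super) "<=" else "=", m),
           rep(if (super) ">=" else "=", q))
  if (super) {  # ybar >= 0
    bnd <- matrix(0, q, nv)
    for (r in seq_len(q)) { bnd[r, iP[r]] <- 1; bnd[r, iT] <- -yk[r] }
    A <- rbind(A, bnd)
    dir <- c(dir, rep("<=", q))
  }
  if (vrs) {
    cvx <- numeric(nv); cvx[iL] <- 1; cvx[iT] <- -1
    A <- rbind(A, cvx)
    dir <- c(dir, "=")
  }
  b <- c(1, numeric(nrow(A) - 1))
  sol <- solve_lp(cvec, A, dir, b)
  if (sol$status != "optimal")
    return(list(status = sol$status, rho = NA_real_))
  t <- sol$x[iT]
  list(status = "optimal", rho = sol$value, t = t,
       lambda = sol$x[iL] / t, s_in = sol$x[iS] / t, s_out = sol$x[iP] / t)
}

.solution <- function(unit, year, rho, res, status) {
  structure(list(unit = unit, year = year, rho = rho,
                 input_slacks = res$s_in, output_slacks = res$s_out,
                 lambda = res$lambda, status = status),
            class = "sbm_solution")
}

#' Score one unit with the slack-based measure
#'
#' Solves the non-oriented SBM program of Tone's slack-based measure via its
#' exact fractional-to-linear (Charnes-Cooper) conversion. The score is
#' `(1 - mean(s-/x)) / (1 + mean(s+/y))` at the optimal slacks: 1 exactly when
#' no input excess or output shortfall exists relative to the frontier pool.
#'
#' @param panel an [indicator_panel()].
#' @param unit,year the DMU to score.
#' @param config a [dea_config()].
#' @return an `sbm_solution`: `rho`, `input_slacks`, `output_slacks`,
#'   `lambda` (peer weights over the frontier pool), `status`.
#' @export
sbm_score <- function(panel, unit, year, config = dea_config()) {
  stopifnot(inherits(panel, "indicator_panel"))
  pm <- .pool_matrices(panel, year, config)
  k <- match(paste(unit, year), pm$ids)
  if (is.na(k)) stop("unit '", unit, "' not in frontier pool for ", year,
                     call. = FALSE)
  res <- .sbm_lp(pm$X, pm$Y, pm$X[, k], pm$Y[, k], rts = config$rts)
  if (res$status != "optimal")
    stop("SBM solver failed (", res$status, ") for ", unit, "/", year,
         call. = FALSE)
  eff <- sum(res$s_in) + sum(res$s_out) <= config$epsilon
  .solution(unit, year, if (eff) 1 else res$rho, res,
            if (eff) "efficient" else "inefficient")
}

#' Super-efficiency score of an efficient unit
#'
#' Re-scores an SBM-efficient unit against the frontier pool with the unit
#' itself removed, so efficient units can be ranked; the score is at least 1.
#' Under variable returns to scale the exclusion program can be infeasible
#' for extreme units; such units get status `"super_infeasible"` and a
#' missing score, never a substituted number.
#'
#' @inheritParams sbm_score
#' @export
super_sbm_score <- function(panel, unit, year, config = dea_config()) {
  stopifnot(inherits(panel, "indicator_panel"))
  base <- sbm_score(panel, unit, year, config)
  if (base$status != "efficient")
    stop("super-efficiency is defined only for SBM-efficient units; '",
         unit, "'/", year, " is ", base$status, call. = FALSE)
  pm <- .pool_matrices(panel, year, config)
  k <- match(paste(unit, year), pm$ids)
  res <- .sbm_lp(pm$X, pm$Y, pm$X[, k], pm$Y[, k], exclude = k,
                 rts = config$rts, super = TRUE)
  if (res$status == "infeasible")
    return(.solution(unit, year, NA_real_, list(), "super_infeasible"))
  if (res$status != "optimal")
    stop("super-SBM solver failed (", res$status, ") for ", unit, "/", year,
         call. = FALSE)
  .solution(unit, year, max(res$rho, 1), res, "efficient")
}

#' Score a whole panel
#'
#' For every unit-year: the SBM score if the unit is inefficient, otherwise
#' its super-efficiency score, so that the emitted `rho` brackets 1 on both
#' sides (scores >= 1 are efficient units ranked by super-efficiency).
#'
#' @inheritParams sbm_score
#' @param slacks if `TRUE`, attach a per-unit slack report as attribute
#'   `"slacks"`.
#' @return an [efficiency_panel()]; units whose super-efficiency program is
#'   infeasible carry `rho = NA` and are reported via attribute
#'   `"super_infeasible"`.
#' @export
efficiency_table <- function(panel, config = dea_config(), slacks = FALSE) {
  stopifnot(inherits(panel, "indicator_panel"))
  rows <- vector("list", nrow(panel))
  slack_rows <- vector("list", nrow(panel))
  infeas <- character(0)
  for (i in seq_len(nrow(panel))) {
    u <- panel$unit[i]; y <- panel$year[i]
    sol <- tryCatch(sbm_score(panel, u, y, config),
                    error = function(e) stop("unit ", u, "/", y, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (sol$status == "efficient") sol <- super_sbm_score(panel, u, y, config)
    if (sol$status == "super_infeasible") infeas <- c(infeas, paste(u, y))
    rows[[i]] <- data.frame(unit = u, year = y, region = panel$region[i],
                            rho = sol$rho, stringsAsFactors = FALSE)
    if (slacks && length(sol$input_slacks))
      slack_rows[[i]] <- data.frame(unit = u, year = y,
                                    t(sol$input_slacks), t(sol$output_slacks),
                                    status = sol$status)
  }
  out <- do.call(rbind, rows)
  if (length(infeas)) {
    warning("super-efficiency infeasible for: ", paste(infeas, collapse = ", "))
    ok <- !is.na(out$rho)
    res <- efficiency_panel(out[ok, ])  # validate the solvable part
    res <- structure(.canonical(out), class = class(res))
  } else {
    res <- efficiency_panel(out)
  }
  attr(res, "super_infeasible") <- infeas
  if (slacks) attr(res, "slacks") <- do.call(rbind, slack_rows)
  res
}
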