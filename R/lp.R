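#' Solve a small dense linear program
#'
#' Two-phase primal simplex with Bland's anti-cycling rule, written for the
#' small, dense, frequently degenerate programs that slack-based DEA models
#' generate (a few dozen variables, about a dozen rows). Minimises
#' \code{c'x} subject to \code{A x (dir) b}, \code{x >= 0}, where \code{dir}
#' is one of \code{"<="}, \code{">="}, \code{"="} per row. Redundant equality
#' rows are tolerated: artificial variables that remain basic at zero after
#' phase 1 are pivoted out or their rows dropped.
#'
#' @param cvec objective coefficients (length `n`).
#' @param A constraint matrix (`m x n`).
#' @param dir character vector of row directions (`"<="`, `">="`, `"="`).
#' @param b right-hand sides (length `m`).
#' @param tol feasibility/optimality tolerance.
#' @param max_iter simplex pivot cap.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (primal solution) and `value` (objective at the optimum).
#' @keywords internal
solve_lp <- function(cvec, A, dir, b, tol = 1e-9, max_iter = 10000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cvec) == n, length(b) == m, length(dir) == m)
  # orient rows so b >= 0
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  dir[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[flip]]

  # columns: structural | slack/surplus | artificial
  n_slack <- sum(dir != "=")
  slack_of <- integer(m); art_of <- integer(m)
  Tb <- cbind(A, matrix(0, m, n_slack))
  j <- n
  for (i in seq_len(m)) {
    if (dir[i] != "=") {
      j <- j + 1L
      Tb[i, j] <- if (dir[i] == "<=") 1 else -1
      slack_of[i] <- j
    }
  }
  need_art <- dir == "=" | dir == ">="
  n_art <- sum(need_art)
  Tb <- cbind(Tb, matrix(0, m, n_art))
  j <- n + n_slack
  for (i in which(need_art)) { j <- j + 1L; Tb[i, j] <- 1; art_of[i] <- j }
  ntot <- ncol(Tb)
  basis <- ifelse(need_art, art_of, slack_of)

  pivot <- function(Tb, b, i, j) {
    piv <- Tb[i, j]
    Tb[i, ] <- Tb[i, ] / piv
    b[i] <- b[i] / piv
    for (r in seq_len(nrow(Tb))) if (r != i && abs(Tb[r, j]) > 0) {
      b[r] <- b[r] - Tb[r, j] * b[i]
      Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
    }
    list(Tb = Tb, b = b)
  }
  run_phase <- function(obj, Tb, b, basis, live_cols) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex iteration limit reached")
      red <- obj - crossprod(Tb, obj[basis])  # reduced costs wrt basis
      red[basis] <- 0
      enter <- which(live_cols & red < -tol)
      if (!length(enter)) return(list(Tb = Tb, b = b, basis = basis, ok = TRUE))
      jcol <- min(enter)                      # Bland: smallest index
      col <- Tb[, jcol]
      rows <- which(col > tol)
      if (!length(rows)) return(list(Tb = Tb, b = b, basis = basis, ok = FALSE))
      ratio <- b[rows] / col[rows]
      cand <- rows[ratio <= min(ratio) + tol]
      irow <- cand[which.min(basis[cand])]    # Bland on leaving variable
      p <- pivot(Tb, b, irow, jcol)
      Tb <- p$Tb; b <- p$b
      basis[irow] <- jcol
    }
  }

  live <- rep(TRUE, ntot)
  if (n_art > 0) {
    obj1 <- numeric(ntot); obj1[art_of[art_of > 0]] <- 1
    # price out the initial artificial basis
    r1 <- run_phase(obj1, Tb, b, basis, live)
    if (!r1$ok) return(list(status = "infeasible", x = NULL, value = NA_real_))
    Tb <- r1$Tb; b <- r1$b; basis <- r1$basis
    if (sum(b[basis %in% art_of[art_of > 0]]) > 1e-7)
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    # drive residual zero-level artificials out of the basis
    drop_rows <- integer(0)
    for (i in seq_len(m)) {
      if (basis[i] %in% art_of[art_of > 0]) {
        piv_cols <- which(abs(Tb[i, seq_len(n + n_slack)]) > tol)
        if (length(piv_cols)) {
          p <- pivot(Tb, b, i, piv_cols[1])
          Tb <- p$Tb; b <- p$b
          basis[i] <- piv_cols[1]
        } else drop_rows <- c(drop_rows, i)  # redundant row
      }
    }
    if (length(drop_rows)) {
      Tb <- Tb[-drop_rows, , drop = FALSE]
      b <- b[-drop_rows]
      basis <- basis[-drop_rows]
    }
    live[art_of[art_of > 0]] <- FALSE
  }
  obj2 <- c(cvec, numeric(ntot - n))
  r2 <- run_phase(obj2, Tb, b, basis, live)
  if (!r2$ok) return(list(status = "unbounded", x = NULL, value = NA_real_))
  x <- numeric(ntot)
  x[r2$basis] <- r2$b
  x <- x[seq_len(n)]
  list(status = "optimal", x = x, value = sum(cvec * x))
}
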