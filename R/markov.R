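#' Contiguity map
#'
#' Undirected adjacency among units, stored as a symmetric weight matrix.
#' Construct from an edge list (two-column data frame `unit_a`, `unit_b`), a
#' symmetric 0/1 matrix, and optionally restrict to a unit subset.
#'
#' @param edges data frame with columns `unit_a`, `unit_b`, or a symmetric
#'   numeric matrix with dimnames.
#' @param units optional unit set (adds isolated units / drops others).
#' @return an `adjacency_map`: list with `W` (weight matrix), `units`,
#'   `standardized` flag and `isolated` (units with no neighbour).
#' @export
adjacency_map <- function(edges, units = NULL) {
  if (is.matrix(edges)) {
    stopifnot(!is.null(rownames(edges)), isTRUE(all.equal(edges, t(edges))))
    W <- edges
  } else {
    stopifnot(all(c("unit_a", "unit_b") %in% names(edges)))
    us <- sort(unique(c(edges$unit_a, edges$unit_b, units)))
    W <- matrix(0, length(us), length(us), dimnames = list(us, us))
    for (i in seq_len(nrow(edges))) {
      a <- edges$unit_a[i]; b <- edges$unit_b[i]
      if (a == b) stop("self-loop on '", a, "'", call. = FALSE)
      W[a, b] <- 1; W[b, a] <- 1
    }
  }
  if (!is.null(units)) {
    us <- sort(unique(units))
    W2 <- matrix(0, length(us), length(us), dimnames = list(us, us))
    common <- intersect(us, rownames(W))
    W2[common, common] <- W[common, common]
    W <- W2
  }
  diag(W) <- 0
  structure(list(W = W, units = rownames(W), standardized = FALSE,
                 isolated = rownames(W)[rowSums(W) == 0]),
            class = "adjacency_map")
}

#' Row-standardise a contiguity map
#'
#' Each unit's weights become uniform over its neighbours and sum to 1.
#' Isolated units keep an all-zero row and are flagged.
#'
#' @param adjacency an [adjacency_map()].
#' @return the map with `standardized = TRUE`.
#' @export
row_standardize <- function(adjacency) {
  stopifnot(inherits(adjacency, "adjacency_map"))
  W <- adjacency$W
  deg <- rowSums(W != 0)
  keep <- deg > 0
  W[keep, ] <- W[keep, , drop = FALSE] / rowSums(W[keep, , drop = FALSE])
  adjacency$W <- W
  adjacency$standardized <- TRUE
  adjacency$isolated <- adjacency$units[!keep]
  adjacency
}

# states as a units x years integer matrix
.state_matrix <- function(states) {
  stopifnot(inherits(states, "state_panel"))
  us <- sort(unique(states$unit)); ys <- sort(unique(states$year))
  S <- matrix(NA_integer_, length(us), length(ys), dimnames = list(us, ys))
  S[cbind(match(states$unit, us), match(states$year, ys))] <- states$state
  if (anyNA(S)) stop("unbalanced state panel", call. = FALSE)
  S
}

#' One-step transition matrix
#'
#' Tabulates all transitions between consecutive years and row-normalises the
#' counts by origin-state totals (the maximum-likelihood estimate of a
#' time-homogeneous first-order chain). Rows with no observed origins keep
#' zero probabilities and are flagged, never renormalised.
#'
#' @param states a `state_panel`.
#' @param k number of states (defaults to the panel's).
#' @return a `transition_matrix`: list with `counts`, `probs`,
#'   `origin_totals`, `empty_rows`.
#' @export
transition_matrix <- function(states, k = NULL) {
  S <- .state_matrix(states)
  if (ncol(S) < 2) stop("need at least two years", call. = FALSE)
  if (is.null(k)) k <- attr(states, "k") %||% max(S)
  counts <- matrix(0L, k, k, dimnames = list(1:k, 1:k))
  for (t in seq_len(ncol(S) - 1)) {
    tab <- table(factor(S[, t], 1:k), factor(S[, t + 1], 1:k))
    counts <- counts + unclass(tab)
  }
  totals <- rowSums(counts)
  probs <- counts / pmax(totals, 1)
  probs[totals == 0, ] <- 0
  structure(list(counts = counts, probs = probs, origin_totals = totals,
                 empty_rows = which(totals == 0)),
            class = "transition_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initial state-occupancy distribution
#'
#' Share of each state over all unit-years in the origin-year window (every
#' year except the last, i.e. the origins of the tabulated transitions).
#'
#' @param states a `state_panel`.
#' @param k number of states.
#' @return numeric probability vector of length `k`.
#' @export
initial_distribution <- function(states, k = NULL) {
  S <- .state_matrix(states)
  if (is.null(k)) k <- attr(states, "k") %||% max(S)
  origin <- S[, -ncol(S), drop = FALSE]
  as.vector(table(factor(origin, 1:k))) / length(origin)
}

#' Transition type between two years
#'
#' Compares each unit's state at `end_year` against `start_year`.
#'
#' @param states a `state_panel`.
#' @param start_year,end_year endpoint years (default: first and last).
#' @return data frame `unit`, `from`, `to`, `type` in
#'   `{"upward", "downward", "unchanged"}`.
#' @export
transition_type_map <- function(states, start_year = NULL, end_year = NULL) {
  S <- .state_matrix(states)
  ys <- as.integer(colnames(S))
  start_year <- start_year %||% ys[1]
  end_year <- end_year %||% ys[length(ys)]
  stopifnot(start_year %in% ys, end_year %in% ys)
  a <- S[, as.character(start_year)]; b <- S[, as.character(end_year)]
  data.frame(unit = rownames(S), from = a, to = b,
             type = ifelse(b > a, "upward", ifelse(b < a, "downward",
                                                   "unchanged")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spatial-lag values and lag states
#'
#' The spatial lag of a unit is the row-standardised weighted average of its
#' neighbours' efficiency scores in the same year. Lag values are classified
#' into the same number of states as the own values; by default the lag
#' cross-sections get their own per-year Fisher-Jenks breaks (the
#' classification that reproduces the reference conditional matrices), but
#' fixed breaks can be supplied.
#'
#' @param panel an [efficiency_panel()].
#' @param adjacency a row-standardised [adjacency_map()] covering the panel's
#'   units.
#' @param k number of lag states.
#' @param breaks optional `state_breaks` (or cut vector) applied to every
#'   year instead of per-year fitting.
#' @param isolated `"error"` (default) or `"drop"`: what to do with units
#'   that have no in-sample neighbour.
#' @return a `state_panel` of lag classes with attribute `"lag_values"`.
#' @export
spatial_lag_states <- function(panel, adjacency, k = 4, breaks = NULL,
                               isolated = c("error", "drop")) {
  stopifnot(inherits(panel, "efficiency_panel"),
            inherits(adjacency, "adjacency_map"))
  isolated <- match.arg(isolated)
  if (!adjacency$standardized) adjacency <- row_standardize(adjacency)
  us <- sort(unique(panel$unit)); ys <- sort(unique(panel$year))
  if (!all(us %in% adjacency$units))
    stop("adjacency map missing unit(s): ",
         paste(setdiff(us, adjacency$units), collapse = ", "), call. = FALSE)
  iso <- intersect(adjacency$isolated, us)
  if (length(iso)) {
    if (isolated == "error")
      stop("isolated unit(s): ", paste(iso, collapse = ", "), call. = FALSE)
    warning("dropping isolated unit(s): ", paste(iso, collapse = ", "))
    us <- setdiff(us, iso)
  }
  W <- adjacency$W[us, sort(unique(panel$unit)), drop = FALSE]
  R <- matrix(panel$rho[order(panel$unit, panel$year)],
              nrow = length(unique(panel$unit)), byrow = TRUE,
              dimnames = list(sort(unique(panel$unit)), ys))
  L <- W %*% R
  parts <- lapply(seq_along(ys), function(j) {
    cuts <- if (is.null(breaks)) jenks_breaks(L[, j], k)$cuts
            else if (inherits(breaks, "state_breaks")) breaks$cuts else breaks
    data.frame(unit = rownames(L), year = ys[j],
               state = findInterval(L[, j], cuts) + 1L,
               stringsAsFactors = FALSE)
  })
  out <- structure(.canonical(do.call(rbind, parts)),
                   class = c("state_panel", "data.frame"), k = k)
  attr(out, "lag_values") <- L
  out
}

#' Spatial (lag-conditioned) transition matrices
#'
#' Splits the one-step transitions by the origin-year lag class of the moving
#' unit and row-normalises each bin, yielding one conditional matrix per lag
#' state. The element-wise sum of the conditional count matrices equals the
#' unconditional count matrix by construction.
#'
#' @param states own-state `state_panel`.
#' @param lag_states lag-class `state_panel` aligned with `states`.
#' @param k number of states.
#' @return a `spatial_transition_set`: list of [transition_matrix()]-like
#'   blocks, one per lag state.
#' @export
spatial_transition_set <- function(states, lag_states, k = NULL) {
  S <- .state_matrix(states)
  Lg <- .state_matrix(lag_states)
  common <- intersect(rownames(S), rownames(Lg))
  S <- S[common, , drop = FALSE]; Lg <- Lg[common, , drop = FALSE]
  stopifnot(identical(colnames(S), colnames(Lg)))
  if (is.null(k)) k <- attr(states, "k") %||% max(S, Lg)
  blocks <- lapply(1:k, function(N) {
    counts <- matrix(0L, k, k, dimnames = list(1:k, 1:k))
    for (t in seq_len(ncol(S) - 1)) {
      sel <- Lg[, t] == N
      if (!any(sel)) next
      tab <- table(factor(S[sel, t], 1:k), factor(S[sel, t + 1], 1:k))
      counts <- counts + unclass(tab)
    }
    totals <- rowSums(counts)
    probs <- counts / pmax(totals, 1)
    probs[totals == 0, ] <- 0
    structure(list(counts = counts, probs = probs, origin_totals = totals,
                   empty_rows = which(totals == 0)),
              class = "transition_matrix")
  })
  names(blocks) <- paste0("lag", 1:k)
  structure(list(blocks = blocks, k = k), class = "spatial_transition_set")
}

#' Stationary distribution by linear solve
#'
#' Solves `pi P = pi`, `sum(pi) = 1` directly (null-space of `t(P) - I` with
#' the normalisation row appended). Intended for irreducible chains, where
#' the solution is unique; used as the algebraic cross-check of
#' [limiting_distribution()].
#'
#' @param P row-stochastic matrix.
#' @return probability vector.
#' @export
stationary_distribution <- function(P) {
  k <- nrow(P)
  A <- rbind(t(P) - diag(k), rep(1, k))
  b <- c(numeric(k), 1)
  pi <- unname(qr.solve(A, b))
  pi[pi < 0 & pi > -1e-12] <- 0
  pi / sum(pi)
}

#' Limiting distribution by power iteration
#'
#' Iterates `pi <- pi P` from a start vector until the L1 change falls below
#' `tol`. For irreducible aperiodic chains the limit is the unique stationary
#' distribution; for reducible chains it depends on the start vector and is
#' returned as such (transient mass drains into the closed classes). Periodic
#' chains do not converge pointwise; `cesaro = TRUE` computes the Cesaro
#' (time-average) limit instead, by power-iterating the lazy chain
#' `(P + I)/2` — aperiodic, with the same closed classes, absorption
#' probabilities and stationary distributions, hence the same time-average
#' limit — which converges geometrically.
#'
#' @param P row-stochastic matrix (a `transition_matrix` is accepted; its
#'   `probs` are used). Rows with no observations (all-zero) are treated as
#'   absorbing, with a warning, if they carry mass en route.
#' @param pi0 start distribution (default uniform).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @param cesaro use Cesaro (running-average) convergence.
#' @return probability vector with attribute `"iterations"`.
#' @export
limiting_distribution <- function(P, pi0 = NULL, tol = 1e-12,
                                  max_iter = 1e6, cesaro = FALSE) {
  if (inherits(P, "transition_matrix")) P <- P$probs
  P <- as.matrix(P)
  k <- nrow(P)
  rs <- rowSums(P)
  zero <- rs < .Machine$double.eps
  if (any(zero)) {
    warning("empty row(s) ", paste(which(zero), collapse = ", "),
            " treated as absorbing")
    P[zero, ] <- 0
    P[cbind(which(zero), which(zero))] <- 1
    rs[zero] <- 1
  }
  if (any(abs(rs - 1) > 1e-6))
    stop("matrix is not row-stochastic (row sums off by > 1e-6)",
         call. = FALSE)
  P <- P / rs  # absorb printing-level rounding in the last digit
  if (is.null(pi0)) pi0 <- rep(1 / k, k)
  stopifnot(length(pi0) == k, all(pi0 >= 0),
            abs(sum(pi0) - 1) < 1e-6)
  pi <- pi0 / sum(pi0)
  if (cesaro) P <- (P + diag(k)) / 2
  for (it in seq_len(max_iter)) {
    nxt <- as.vector(pi %*% P)
    if (sum(abs(nxt - pi)) < tol) return(structure(nxt, iterations = it))
    pi <- nxt
  }
  stop("power iteration did not converge in ", max_iter,
       " steps; the chain may be periodic (try cesaro = TRUE)", call. = FALSE)
}
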