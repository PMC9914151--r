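#' Fisher-Jenks natural breaks
#'
#' Exact optimal univariate classification: partitions the sorted values into
#' `k` contiguous classes minimising the total within-class sum of squared
#' deviations, by the O(k n^2) dynamic programme over class start indices
#' (not the iterative reallocation heuristic). Ties in the optimum are broken
#' towards the lexicographically smallest boundary indices, so the result is
#' deterministic. Cut points are placed midway between the largest value of
#' one class and the smallest value of the next.
#'
#' @param values numeric vector (at least `k` distinct values).
#' @param k number of classes.
#' @return object of class `state_breaks`: list with `cuts` (k-1 ascending
#'   cut points), `k`, and `classes` (class index of each input value).
#' @export
jenks_breaks <- function(values, k = 4) {
  stopifnot(is.numeric(values), k >= 2)
  if (length(unique(values)) < k)
    stop("need at least k = ", k, " distinct values", call. = FALSE)
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssq <- function(i, j) {  # within-class SSE of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    max(s2 - s^2 / (j - i + 1), 0)
  }
  D <- matrix(Inf, k, n)   # D[c, j]: optimal SSE of x[1..j] in c classes
  B <- matrix(0L, k, n)    # start index of the last class at the optimum
  for (j in 1:n) D[1, j] <- ssq(1, j)
  B[1, ] <- 1L
  for (cc in 2:k) {
    for (j in cc:n) {
      best <- Inf; arg <- 0L
      for (i in cc:j) {
        v <- D[cc - 1, i - 1] + ssq(i, j)
        if (v < best - 1e-12) { best <- v; arg <- i }
      }
      D[cc, j] <- best; B[cc, j] <- arg
    }
  }
  starts <- integer(k)
  jj <- n
  for (cc in k:2) { starts[cc] <- B[cc, jj]; jj <- starts[cc] - 1L }
  starts[1] <- 1L
  cuts <- vapply(2:k, function(cc) (x[starts[cc] - 1] + x[starts[cc]]) / 2,
                 numeric(1))
  cls <- integer(n)
  cls[ord] <- findInterval(x, cuts) + 1L
  structure(list(cuts = cuts, k = k, classes = cls, sse = D[k, n]),
            class = "state_breaks")
}

#' Classify efficiency values into states
#'
#' Maps each observation to its state under a set of breaks. Classes are
#' left-closed and right-open except the top class, which is unbounded above:
#' a value exactly at a cut belongs to the upper class.
#'
#' @param panel an [efficiency_panel()].
#' @param breaks a `state_breaks` object or a numeric vector of cut points.
#' @return a `state_panel`: data frame `unit`, `year`, `state`.
#' @export
classify_states <- function(panel, breaks) {
  stopifnot(inherits(panel, "efficiency_panel"))
  cuts <- if (inherits(breaks, "state_breaks")) breaks$cuts else breaks
  stopifnot(!is.unsorted(cuts, strictly = TRUE))
  out <- data.frame(unit = panel$unit, year = panel$year,
                    state = findInterval(panel$rho, cuts) + 1L,
                    stringsAsFactors = FALSE)
  structure(.canonical(out), class = c("state_panel", "data.frame"),
            k = length(cuts) + 1L)
}

#' Fit breaks and classify a panel in one step
#'
#' The replication default fits Fisher-Jenks breaks to each year's
#' cross-section separately (`pool = "per_year"`), keeping each year's state
#' space maximally discriminating for that year; `pool = "pooled"` fits one
#' set of breaks on all unit-year values and applies it throughout.
#'
#' @param panel an [efficiency_panel()].
#' @param k number of states.
#' @param pool `"per_year"` or `"pooled"`.
#' @return a `state_panel` with attribute `"breaks"` (a list per year, or a
#'   single `state_breaks`).
#' @export
state_panel <- function(panel, k = 4, pool = c("per_year", "pooled")) {
  stopifnot(inherits(panel, "efficiency_panel"))
  pool <- match.arg(pool)
  if (pool == "pooled") {
    br <- jenks_breaks(panel$rho, k)
    out <- classify_states(panel, br)
    attr(out, "breaks") <- br
    attr(out, "pool") <- pool
    return(out)
  }
  yrs <- sort(unique(panel$year))
  brs <- list()
  parts <- lapply(yrs, function(yy) {
    sub <- panel[panel$year == yy, ]
    br <- jenks_breaks(sub$rho, k)
    brs[[as.character(yy)]] <<- br
    data.frame(unit = sub$unit, year = sub$year,
               state = findInterval(sub$rho, br$cuts) + 1L,
               stringsAsFactors = FALSE)
  })
  out <- structure(.canonical(do.call(rbind, parts)),
                   class = c("state_panel", "data.frame"), k = k)
  attr(out, "breaks") <- brs
  attr(out, "pool") <- pool
  out
}
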