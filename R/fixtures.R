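#' Packaged supply-efficiency panel, 2010-2019
#'
#' Super-efficiency SBM scores of primary medical and health service supply
#' for 20 central and western Chinese provinces over 2010-2019 (non-radial,
#' variable returns to scale; inputs: institutions, beds, personnel; outputs:
#' visits, admissions, family-service frequency). Scores at or above 1 mark
#' units on or beyond the frontier; scores below 1 mark inefficient units.
#' This is the reference panel all downstream distribution-dynamics and
#' Markov analyses in the package operate on; the raw yearbook indicator
#' data behind it are not distributed.
#'
#' The region split follows the official statistical-yearbook convention:
#' 8 central provinces (Anhui, Heilongjiang, Henan, Hubei, Hunan, Jiangxi,
#' Jilin, Shanxi) and 12 western ones.
#'
#' @return an [efficiency_panel()] with 200 rows (20 units x 10 years).
#' @export
supply_efficiency <- function() {
  path <- system.file("extdata", "supply_efficiency_2010_2019.csv",
                      package = "phceff", mustWork = TRUE)
  wide <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  yrs <- grep("^[0-9]{4}$", names(wide), value = TRUE)
  long <- do.call(rbind, lapply(yrs, function(y) {
    data.frame(unit = wide$province, year = as.integer(y),
               region = wide$region, rho = wide[[y]],
               stringsAsFactors = FALSE)
  }))
  efficiency_panel(long)
}

#' Packaged province contiguity map
#'
#' First-order land-border contiguity among the 20 in-sample provinces,
#' encoded as an undirected edge list; borders with out-of-sample (eastern)
#' provinces are dropped. Row-standardised by default so each province's
#' weights are uniform over its in-sample neighbours.
#'
#' @param standardize row-standardise the weight matrix (default `TRUE`).
#' @return an [adjacency_map()].
#' @export
province_adjacency <- function(standardize = TRUE) {
  path <- system.file("extdata", "province_adjacency.csv",
                      package = "phceff", mustWork = TRUE)
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  adj <- adjacency_map(edges)
  if (standardize) row_standardize(adj) else adj
}
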