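#' Indicator and efficiency panels
#'
#' A panel of decision-making units (DMUs, here province-years) carries three
#' input indicators (institutions, beds, personnel) and three output
#' indicators (visits, admissions, family-service frequency) for DEA scoring;
#' an efficiency panel carries the resulting score `rho` per unit-year.
#' Both are plain data frames with a light S3 class so that validators and
#' print methods can hang off them. Units are ordered lexicographically and
#' years ascending throughout; all downstream matrices index in this order.
#'
#' @name panels
NULL

.canonical <- function(df) {
  df <- df[order(df$unit, df$year), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.check_balanced <- function(df, what) {
  key <- paste(df$unit, df$year)
  dup <- key[duplicated(key)]
  if (length(dup))
    stop(sprintf("%s: duplicate (unit, year): %s", what, dup[1]), call. = FALSE)
  tab <- table(df$unit, df$year)
  if (any(tab != 1))
    stop(sprintf("%s: unbalanced panel (not every unit observed in every year)",
                 what), call. = FALSE)
  invisible(df)
}

#' Validate and construct an indicator panel
#'
#' @param df data frame with columns `unit`, `year`, `region` and at least one
#'   input column `x1, x2, ...` and one output column `y1, y2, ...`.
#' @param repair_zeros if `TRUE`, nonpositive indicator values are replaced by
#'   `zero_eps` instead of rejected. Off by default: the SBM objective divides
#'   by the evaluated unit's indicators, so zeros are undefined.
#' @param zero_eps replacement value used when `repair_zeros = TRUE`.
#' @return the validated panel, class `indicator_panel`, canonically ordered.
#' @export
indicator_panel <- function(df, repair_zeros = FALSE, zero_eps = 1e-6) {
  need <- c("unit", "year", "region")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  xin <- grep("^x[0-9]+$", names(df), value = TRUE)
  yout <- grep("^y[0-9]+$", names(df), value = TRUE)
  if (!length(xin) || !length(yout))
    stop("need at least one input column x<i> and one output column y<r>",
         call. = FALSE)
  df$unit <- as.character(df$unit)
  df$year <- as.integer(df$year)
  for (cl in c(xin, yout)) {
    bad <- which(!is.finite(df[[cl]]) | df[[cl]] <= 0)
    if (length(bad)) {
      if (repair_zeros) {
        df[[cl]][bad] <- zero_eps
      } else {
        stop(sprintf("nonpositive indicator %s for unit '%s', year %d",
                     cl, df$unit[bad[1]], df$year[bad[1]]), call. = FALSE)
      }
    }
  }
  df <- .canonical(df)
  .check_balanced(df, "indicator panel")
  structure(df, class = c("indicator_panel", "data.frame"),
            inputs = xin, outputs = yout)
}

#' Read an indicator panel from CSV
#'
#' Long format, UTF-8, comma-separated, header required:
#' `unit,year,region,x1,...,y1,...`.
#'
#' @inheritParams indicator_panel
#' @param path CSV file path.
#' @return an `indicator_panel`.
#' @export
load_indicator_panel <- function(path, repair_zeros = FALSE, zero_eps = 1e-6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  indicator_panel(df, repair_zeros = repair_zeros, zero_eps = zero_eps)
}

#' @rdname load_indicator_panel
#' @param panel panel to write.
#' @export
write_indicator_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate and construct an efficiency panel
#'
#' @param df data frame with columns `unit`, `year`, `region`, `rho`.
#' @return the validated panel, class `efficiency_panel`.
#' @export
efficiency_panel <- function(df) {
  need <- c("unit", "year", "region", "rho")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df$unit <- as.character(df$unit)
  df$year <- as.integer(df$year)
  if (any(!is.finite(df$rho) | df$rho <= 0))
    stop("rho must be positive and finite", call. = FALSE)
  df <- .canonical(df[, need])
  .check_balanced(df, "efficiency panel")
  structure(df, class = c("efficiency_panel", "data.frame"))
}

#' @rdname efficiency_panel
#' @param path CSV file path (`unit,year,region,rho`).
#' @export
load_efficiency_panel <- function(path) {
  efficiency_panel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname efficiency_panel
#' @param panel panel to write.
#' @export
write_efficiency_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annual mean efficiency
#'
#' Arithmetic mean of `rho` per year over all units or a region subset.
#'
#' @param panel an `efficiency_panel`.
#' @param region `"all"` or one of the region labels in the panel.
#' @return data frame `year`, `mean_rho`, ordered by year.
#' @export
annual_mean <- function(panel, region = "all") {
  stopifnot(inherits(panel, "efficiency_panel"))
  sub <- if (identical(region, "all")) panel else panel[panel$region == region, ]
  if (!nrow(sub)) stop("empty subset for region '", region, "'", call. = FALSE)
  agg <- stats::aggregate(rho ~ year, data = sub, FUN = mean)
  names(agg) <- c("year", "mean_rho")
  agg[order(agg$year), ]
}

#' Efficiency range gap
#'
#' Difference between the largest and smallest score over all unit-years.
#'
#' @param panel an `efficiency_panel`.
#' @return a single number, `max(rho) - min(rho)`.
#' @export
range_gap <- function(panel) {
  stopifnot(inherits(panel, "efficiency_panel"), nrow(panel) > 0)
  max(panel$rho) - min(panel$rho)
}
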