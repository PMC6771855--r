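#' Activity-weighted unit cost across Healthcare Resource Groups
#'
#' NHS reference costs list one unit cost and an activity volume per HRG;
#' the cost applied per attendance or bed day is the activity-weighted mean
#' `sum(cost_i * activity_i) / sum(activity_i)`.
#'
#' @param cost numeric vector of HRG unit costs (GBP).
#' @param activity nonnegative activity counts, same length.
#' @return the weighted unit cost in GBP.
#' @examples
#' weighted_unit_cost(c(100, 200), c(1, 3)) # 175
#' @export
weighted_unit_cost <- function(cost, activity) {
  stopifnot(length(cost) == length(activity))
  if (any(activity < 0)) stop("activity must be nonnegative")
  if (any(cost < 0)) stop("unit costs must be nonnegative")
  total <- sum(activity)
  if (total <= 0) stop("total activity must be positive to form a weighted unit cost")
  sum(cost * activity) / total
}

new_unit_cost_table <- function(category_costs, delivery_costs, plgf_test_cost,
                                currency_year) {
  cats <- resource_categories()$category
  missing <- setdiff(cats, names(category_costs))
  if (length(missing)) {
    stop("unit-cost table lacks resource categories: ",
         paste(missing, collapse = ", "))
  }
  missing_d <- setdiff(delivery_modes(), names(delivery_costs))
  if (length(missing_d)) {
    stop("unit-cost table lacks delivery modes: ",
         paste(missing_d, collapse = ", "))
  }
  if (any(c(category_costs, delivery_costs, plgf_test_cost) < 0)) {
    stop("all unit costs must be nonnegative")
  }
  structure(
    list(category_costs = category_costs[cats],
         delivery_costs = delivery_costs[delivery_modes()],
         plgf_test_cost = plgf_test_cost,
         currency_year = currency_year),
    class = "unit_cost_table")
}

#' Synthetic default unit-cost table
#'
#' A clearly synthetic stand-in for an NHS-reference-style (2016/17) unit
#' cost schedule, with realistic magnitudes: the true trial schedule is not
#' reproduced here.  Both neonatal categories (ICU/HDU and SCBU) share one
#' weighted cost per bed day, and delivery is costed per mode and kept out
#' of the Monte Carlo totals.  The PlGF test defaults to GBP 70.
#'
#' @param plgf_test_cost price per PlGF test in GBP (default 70).
#' @return a `unit_cost_table`.
#' @export
default_unit_costs <- function(plgf_test_cost = 70) {
  neonatal_day <- 1000
  new_unit_cost_table(
    category_costs = c(outpatient = 120,
                       antenatal_ward = 450,
                       labour_ward = 700,
                       maternal_postnatal = 400,
                       maternal_icu_hdu = 1200,
                       infant_icu_hdu = neonatal_day,
                       infant_scbu = neonatal_day),
    delivery_costs = c(spontaneous = 2100,
                       assisted = 2700,
                       planned_CS = 3800,
                       emergency_CS = 5000),
    plgf_test_cost = plgf_test_cost,
    currency_year = "2016/17 GBP (synthetic)")
}

#' Read a unit-cost table from delimited text
#'
#' Expected columns: `item`, `unit`, `cost_gbp` and optionally `activity`.
#' Items are resource-category names, delivery modes, or `plgf_test`.  When
#' several rows share an item and carry activity, they are collapsed to one
#' activity-weighted unit cost ([weighted_unit_cost()]), so an HRG-level
#' schedule can be supplied directly.
#'
#' @param path CSV path.
#' @param currency_year label propagated to every costed output.
#' @param plgf_test_cost optional override of the test price.
#' @return a `unit_cost_table`.
#' @export
read_unit_costs <- function(path, currency_year = "2016/17 GBP",
                            plgf_test_cost = NULL) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("item", "cost_gbp")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("unit-cost CSV lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!"activity" %in% names(x)) x$activity <- 1
  x$activity[is.na(x$activity)] <- 1
  collapsed <- vapply(split(x, x$item), function(g)
    weighted_unit_cost(g$cost_gbp, g$activity), numeric(1))
  test_cost <- plgf_test_cost %||%
    (if ("plgf_test" %in% names(collapsed)) collapsed[["plgf_test"]] else 70)
  new_unit_cost_table(
    category_costs = collapsed[intersect(names(collapsed),
                                         resource_categories()$category)],
    delivery_costs = collapsed[intersect(names(collapsed), delivery_modes())],
    plgf_test_cost = test_cost,
    currency_year = currency_year)
}

#' Write a unit-cost table as CSV
#'
#' @param table a `unit_cost_table`.
#' @param path CSV path.
#' @export
write_unit_costs <- function(table, path) {
  stopifnot(inherits(table, "unit_cost_table"))
  units <- resource_categories()$unit[
    match(names(table$category_costs), resource_categories()$category)]
  df <- rbind(
    data.frame(item = names(table$category_costs), unit = units,
               cost_gbp = unname(table$category_costs)),
    data.frame(item = names(table$delivery_costs), unit = "delivery",
               cost_gbp = unname(table$delivery_costs)),
    data.frame(item = "plgf_test", unit = "test",
               cost_gbp = table$plgf_test_cost))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat("Unit costs (", x$currency_year, ")\n", sep = "")
  print(round(x$category_costs, 2))
  cat("Delivery modes:\n")
  print(round(x$delivery_costs, 2))
  cat("PlGF test: ", x$plgf_test_cost, "\n")
  invisible(x)
}

delivery_cost_of_mode <- function(mode, unit_costs) {
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  out <- unit_costs$delivery_costs[mode]
  if (anyNA(out)) {
    stop("no delivery unit cost for mode(s): ",
         paste(unique(mode[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Cost a set of resource-use profiles
#'
#' Per-category cost = quantity x unit cost.  The delivery cost is computed
#' from the delivery mode but returned in its own column, excluded from the
#' maternal/infant totals: bed-day reference costs already include delivery,
#' so adding it to the simulation totals would double-count.
#'
#' @param records data.frame with the resource-category columns and
#'   `delivery_mode`.
#' @param unit_costs a `unit_cost_table`.
#' @return data.frame of per-woman costs: one column per category,
#'   `maternal_total`, `infant_total`, `total` (excluding delivery) and
#'   `delivery_cost` (separate).  Carries attribute `currency_year`.
#' @export
cost_profile <- function(records, unit_costs) {
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  rc <- resource_categories()
  missing <- setdiff(rc$category, names(records))
  if (length(missing)) {
    stop("records lack resource categories: ", paste(missing, collapse = ", "))
  }
  out <- as.data.frame(lapply(setNames(rc$category, rc$category), function(cat) {
    uc <- unit_costs$category_costs[[cat]]
    if (is.null(uc) || is.na(uc)) stop("no unit cost for category ", cat)
    records[[cat]] * uc
  }))
  out$maternal_total <- rowSums(out[, rc$category[rc$group == "maternal"],
                                    drop = FALSE])
  out$infant_total <- rowSums(out[, rc$category[rc$group == "infant"],
                                  drop = FALSE])
  out$total <- out$maternal_total + out$infant_total
  out$delivery_cost <- if ("delivery_mode" %in% names(records)) {
    delivery_cost_of_mode(records$delivery_mode, unit_costs)
  } else {
    NA_real_
  }
  attr(out, "currency_year") <- unit_costs$currency_year
  out
}
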