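# Unit constant: Table-style chemical prices are quoted per short ton.
KG_PER_SHORT_TON <- 907.185

#' Cost index for USD year conversion
#'
#' Year-to-index mapping used to move nominal costs between dollar years
#' (defaults: CPI-U annual averages for 2007 and 2016).
#'
#' @param index Named numeric vector, names are years.
#' @return Class `cost_index`.
#' @export
cost_index <- function(index = c("2007" = 207.34, "2016" = 240.01)) {
  if (any(index <= 0)) stop("cost indices must be positive")
  structure(as.list(index), class = "cost_index")
}

#' Convert an amount between dollar years
#'
#' @param amount USD amount.
#' @param from_year,to_year Years present in the index.
#' @param index A `cost_index`.
#' @return Amount expressed in `to_year` USD.
#' @export
convert_usd <- function(amount, from_year, to_year,
                        index = cost_index()) {
  from <- index[[as.character(from_year)]]
  to <- index[[as.character(to_year)]]
  if (is.null(from) || is.null(to)) {
    stop("cost index missing for year ", if (is.null(from)) from_year else to_year)
  }
  amount * to / from
}

#' Define a capital equipment item
#'
#' @param description Item name.
#' @param base_cost Purchased cost of one unit at `base_size`, USD in
#'   `cost_year` dollars.
#' @param base_size,actual_size Characteristic size (same units).
#' @param exponent Cost scaling exponent, in (0, 1].
#' @param installation_factor Installed/purchased cost ratio (>= 1).
#' @param count Number of identical units.
#' @param cost_year Dollar year of `base_cost`.
#' @param size_units Free-text units of the size column.
#' @return A one-row data.frame.
#' @export
capex_item <- function(description, base_cost, base_size, actual_size = base_size,
                       exponent = 0.6, installation_factor = 1, count = 1,
                       cost_year = 2007, size_units = "") {
  if (base_cost < 0) stop("base cost must be >= 0")
  if (exponent <= 0 || exponent > 1) stop("scaling exponent must be in (0, 1]")
  if (installation_factor < 1) stop("installation factor must be >= 1")
  data.frame(description = description, base_cost = base_cost,
             base_size = base_size, actual_size = actual_size,
             exponent = exponent, installation_factor = installation_factor,
             count = count, cost_year = cost_year, size_units = size_units,
             stringsAsFactors = FALSE)
}

#' Installed cost of a capital item
#'
#' Power-law scaling with an installation factor:
#' installed = count x base_cost x (actual/base)^exponent x factor,
#' converted to the target dollar year.
#'
#' @param item A `capex_item()` row (or data.frame of them; returns a vector).
#' @param to_year Target dollar year.
#' @param index A `cost_index`.
#' @return Installed cost(s) in `to_year` USD.
#' @export
scale_equipment_cost <- function(item, to_year = 2007, index = cost_index()) {
  vapply(seq_len(nrow(item)), function(i) {
    x <- item[i, ]
    installed <- x$count * x$base_cost *
      (x$actual_size / x$base_size)^x$exponent * x$installation_factor
    convert_usd(installed, x$cost_year, to_year, index)
  }, numeric(1))
}

#' Total capital investment with indirect costs
#'
#' Adds the installed cost of scenario additions, grossed up by an indirect
#' cost multiplier, to a baseline plant TCI.
#'
#' @param baseline_tci Baseline total capital investment, USD.
#' @param installed_additions Vector of installed addition costs, USD.
#' @param indirect_multiplier Indirect-cost multiplier on additions (>= 1).
#' @return TCI in USD.
#' @export
total_capital_investment <- function(baseline_tci, installed_additions = numeric(),
                                     indirect_multiplier = 1.631) {
  if (indirect_multiplier < 1) stop("indirect multiplier must be >= 1")
  baseline_tci + indirect_multiplier * sum(installed_additions)
}

#' Annual operating costs and co-product revenues
#'
#' Mass-rate items are billed per short ton (907.185 kg); electricity items
#' per kWh at the configured price.
#'
#' @param opex data.frame with columns `description`, `usage_rate` (kg/h, or
#'   kW for electricity), `unit` (`"kg_h"` or `"kW"`), `unit_price` (USD per
#'   short ton, or per kWh for electricity).
#' @param revenue data.frame with columns `description`, `rate`, `unit`
#'   (`"kg_h"` or `"kW"`), `unit_price` (USD per kg, or per kWh).
#' @param operating_hours Operating hours per year, in (0, 8760].
#' @param electricity_price_usd_per_kwh Price applied to `unit == "kW"` rows
#'   whose `unit_price` is NA.
#' @return List with `annual_opex`, `annual_revenue` and itemized
#'   data.frames carrying an `annual_usd` column.
#' @export
annual_opex_and_revenue <- function(opex, revenue, operating_hours = 8410,
                                    electricity_price_usd_per_kwh = 0.0572) {
  if (operating_hours <= 0 || operating_hours > 8760) {
    stop("operating hours must lie in (0, 8760]")
  }
  annualize <- function(df, per_mass_unit_kg) {
    if (is.null(df) || !nrow(df)) {
      df$annual_usd <- numeric(0); return(df)
    }
    bad <- setdiff(df$unit, c("kg_h", "kW"))
    if (length(bad)) stop("unknown rate unit(s): ", paste(bad, collapse = ", "))
    price <- df$unit_price
    price[df$unit == "kW" & is.na(price)] <- electricity_price_usd_per_kwh
    rate <- if ("usage_rate" %in% names(df)) df$usage_rate else df$rate
    df$annual_usd <- ifelse(
      df$unit == "kW",
      rate * operating_hours * price,
      rate * operating_hours / per_mass_unit_kg * price
    )
    df
  }
  # opex chemical prices are per short ton; product revenues are per kg
  opex <- annualize(opex, KG_PER_SHORT_TON)
  revenue <- annualize(revenue, 1)
  list(annual_opex = sum(opex$annual_usd),
       annual_revenue = sum(revenue$annual_usd),
       opex = opex, revenue = revenue)
}
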