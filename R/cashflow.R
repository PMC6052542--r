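#' Financial configuration for the discounted cash flow
#'
#' Packages the financing conventions of the reference lignocellulosic
#' biorefinery cost model as explicit, overridable parameters: a 30-year
#' project at a 10% target internal rate of return, 61 million gallons of
#' ethanol per year, a three-year construction spend profile, 40% equity
#' with a 10-year loan on the remainder, 35% income tax with loss
#' carry-forward, 200% declining-balance depreciation (straight-line switch),
#' working capital as a fraction of fixed capital, and a reduced-revenue
#' startup year. Because the row-level constants of the reference model are
#' not public, the engine is anchored by calibration: the unknown baseline
#' annual operating cost is solved once so that the ethanol-electricity
#' baseline returns its known selling price (see [calibrate_baseline_opex()]).
#'
#' @param horizon Operating years.
#' @param irr_target Target internal rate of return (discount rate).
#' @param ethanol_output Ethanol production, gallons/yr.
#' @param construction_profile Fractions of fixed capital spent in each
#'   construction year (must sum to 1).
#' @param equity_fraction Equity share of capital spending.
#' @param loan_rate,loan_term Interest rate and term (years) of the loan on
#'   the non-equity share.
#' @param tax_rate Income tax rate.
#' @param dep_years Depreciation recovery period, years.
#' @param working_capital_fraction Working capital as fraction of TCI.
#' @param startup_revenue_fraction Revenue factor applied to the first
#'   operating year.
#' @param gasoline_lhv_ratio Ethanol/gasoline lower-heating-value ratio used
#'   for gasoline-gallon-equivalent prices.
#' @return Class `financial_config`.
#' @export
financial_config <- function(horizon = 30, irr_target = 0.10,
                             ethanol_output = 61e6,
                             construction_profile = c(0.08, 0.60, 0.32),
                             equity_fraction = 0.40,
                             loan_rate = 0.08, loan_term = 10,
                             tax_rate = 0.35, dep_years = 7,
                             working_capital_fraction = 0.05,
                             startup_revenue_fraction = 0.75,
                             gasoline_lhv_ratio = 0.6575) {
  stopifnot(horizon >= 1, irr_target > 0, ethanol_output > 0,
            abs(sum(construction_profile) - 1) < 1e-9,
            equity_fraction >= 0, equity_fraction <= 1,
            tax_rate >= 0, tax_rate < 1,
            gasoline_lhv_ratio > 0, gasoline_lhv_ratio < 1)
  structure(list(horizon = horizon, irr_target = irr_target,
                 ethanol_output = ethanol_output,
                 construction_profile = construction_profile,
                 equity_fraction = equity_fraction,
                 loan_rate = loan_rate, loan_term = loan_term,
                 tax_rate = tax_rate, dep_years = dep_years,
                 working_capital_fraction = working_capital_fraction,
                 startup_revenue_fraction = startup_revenue_fraction,
                 gasoline_lhv_ratio = gasoline_lhv_ratio),
            class = "financial_config")
}

#' Capital recovery factor
#'
#' The annuity factor r(1+r)^n / ((1+r)^n - 1) converting a present sum to
#' an equivalent uniform annual amount over n years at rate r.
#'
#' @param rate Interest rate per period.
#' @param n Number of periods.
#' @return The capital recovery factor.
#' @export
capital_recovery_factor <- function(rate, n) {
  if (rate == 0) return(1 / n)
  rate * (1 + rate)^n / ((1 + rate)^n - 1)
}

# 200% declining-balance depreciation with switch to straight line.
.depreciation_schedule <- function(basis, years) {
  dep <- numeric(years)
  remaining <- basis
  for (i in seq_len(years)) {
    ddb <- 2 / years * remaining
    sl <- remaining / (years - i + 1)
    dep[i] <- max(ddb, sl)
    remaining <- remaining - dep[i]
  }
  dep
}

#' Build the year-by-year project cash flow table
#'
#' Years run from 0 (start of construction) through construction plus the
#' operating horizon. Capital is spent per the construction profile (equity
#' share as cash out; the remainder loan-financed, serviced as a level
#' annuity with deductible interest); working capital is placed at startup
#' and recovered at the end; depreciation shields taxes, with losses carried
#' forward; the first operating year earns reduced revenue.
#'
#' @param ethanol_price USD per gallon of ethanol.
#' @param tci Total capital investment, USD.
#' @param coproduct_revenue Annual co-product revenue, USD/yr.
#' @param annual_opex Annual operating cost, USD/yr.
#' @param config A `financial_config`.
#' @return A `cash_flow_table` data.frame with per-year capital, loan,
#'   revenue, operating cost, depreciation, tax and net (equity) cash flow.
#' @export
build_cash_flow <- function(ethanol_price, tci, coproduct_revenue,
                            annual_opex, config = financial_config()) {
  stopifnot(inherits(config, "financial_config"))
  n_con <- length(config$construction_profile)
  n <- n_con + config$horizon
  year <- 0:(n - 1)
  capital <- c(config$construction_profile * tci, rep(0, config$horizon))
  equity_capital <- config$equity_fraction * capital

  # loan on the non-equity share, level annuity starting with operations
  principal <- (1 - config$equity_fraction) * tci
  payment <- principal * capital_recovery_factor(config$loan_rate, config$loan_term)
  interest <- debt_service <- numeric(n)
  balance <- principal
  for (k in seq_len(config$loan_term)) {
    i <- n_con + k
    if (i > n) break
    interest[i] <- config$loan_rate * balance
    debt_service[i] <- payment
    balance <- balance - (payment - interest[i])
  }

  wc <- config$working_capital_fraction * tci
  working_capital <- numeric(n)
  working_capital[n_con] <- wc      # placed in first operating year
  working_capital[n] <- -wc         # recovered at end

  op_year <- pmax(year - (n_con - 1), 0)
  startup <- ifelse(op_year == 1, config$startup_revenue_fraction, 1)
  revenue <- ifelse(op_year >= 1,
                    (ethanol_price * config$ethanol_output + coproduct_revenue) * startup,
                    0)
  opex <- ifelse(op_year >= 1, annual_opex, 0)

  dep <- numeric(n)
  dep_sched <- .depreciation_schedule(tci, config$dep_years)
  dep[n_con + seq_along(dep_sched)] <- dep_sched

  taxable <- tax <- numeric(n)
  carry <- 0
  for (i in seq_len(n)) {
    if (op_year[i] >= 1) {
      ti <- revenue[i] - opex[i] - dep[i] - interest[i] - carry
      if (ti < 0) { carry <- -ti; ti <- 0 } else carry <- 0
      taxable[i] <- ti
      tax[i] <- config$tax_rate * ti
    }
  }

  net <- revenue - opex - tax - debt_service - equity_capital - working_capital
  disc <- net / (1 + config$irr_target)^year
  structure(data.frame(year = year, capital = capital,
                       equity_capital = equity_capital,
                       working_capital = working_capital,
                       debt_service = debt_service, interest = interest,
                       revenue = revenue, opex = opex, depreciation = dep,
                       taxable_income = taxable, tax = tax,
                       net_cash_flow = net, discounted_cash_flow = disc),
            class = c("cash_flow_table", "data.frame"))
}

#' Net present value of a cash flow table
#'
#' Sum of net cash flows discounted at the given rate, with t = 0 at the
#' start of construction.
#'
#' @param table A `cash_flow_table` (or any data.frame with `year` and
#'   `net_cash_flow` columns).
#' @param rate Discount rate.
#' @return NPV in USD.
#' @export
npv <- function(table, rate) {
  sum(table$net_cash_flow / (1 + rate)^table$year)
}

#' Solve the minimum ethanol selling price
#'
#' Root-finds the ethanol price at which the project NPV is zero at the
#' target IRR, by bracketed bisection (Brent) on [0, 10] USD/gal. Fully
#' deterministic.
#'
#' @param tci Total capital investment, USD.
#' @param coproduct_revenue Annual co-product revenue, USD/yr.
#' @param annual_opex Annual operating cost, USD/yr.
#' @param config A `financial_config`.
#' @param bracket Price search interval, USD/gal.
#' @return An object of class `mesp_result`: list with `mesp` (USD/gal),
#'   `mesp_gge` (USD per gasoline-gallon equivalent), `npv_at_solution`,
#'   `mode = "full_dcf"`.
#' @export
solve_mesp <- function(tci, coproduct_revenue, annual_opex,
                       config = financial_config(), bracket = c(0, 10)) {
  f <- function(p) npv(build_cash_flow(p, tci, coproduct_revenue,
                                       annual_opex, config),
                       config$irr_target)
  lo <- f(bracket[1]); hi <- f(bracket[2])
  if (sign(lo) == sign(hi)) {
    stop(sprintf(
      "no sign change in bracket [%g, %g] $/gal: NPV(%g) = %.3e, NPV(%g) = %.3e",
      bracket[1], bracket[2], bracket[1], lo, bracket[2], hi
    ))
  }
  root <- stats::uniroot(f, bracket, tol = 1e-10)
  mesp <- root$root
  structure(list(mesp = mesp,
                 mesp_gge = gasoline_gallon_equivalent(mesp, config),
                 npv_at_solution = f(mesp), mode = "full_dcf"),
            class = "mesp_result")
}

#' Calibrate the baseline annual operating cost
#'
#' Solves for the baseline plant's (unpublished) annual operating cost such
#' that the full DCF reproduces the known baseline minimum ethanol selling
#' price with the baseline TCI and co-product revenue. This anchors the
#' financing engine to a published number instead of to unverifiable
#' financing constants; it must be run before scenario MESPs are computed.
#'
#' @param config A `financial_config`.
#' @param baseline_tci Baseline TCI, USD.
#' @param baseline_coproduct_revenue Baseline co-product revenue, USD/yr.
#' @param baseline_mesp Known baseline MESP, USD/gal.
#' @return Baseline annual operating cost, USD/yr.
#' @export
calibrate_baseline_opex <- function(config = financial_config(),
                                    baseline_tci = 422.9e6,
                                    baseline_coproduct_revenue = 6.6e6,
                                    baseline_mesp = 2.15) {
  g <- function(opex) {
    solve_mesp(baseline_tci, baseline_coproduct_revenue, opex,
               config, bracket = c(0, 50))$mesp - baseline_mesp
  }
  stats::uniroot(g, c(1e6, 1e9), tol = 1)$root
}

#' Fast incremental MESP approximation
#'
#' Annualized first-order update around a known baseline: capital deltas are
#' annualized with the capital recovery factor at the target IRR and horizon,
#' and revenue/opex deltas pass through per gallon of ethanol.
#'
#' @param baseline_mesp Baseline MESP, USD/gal.
#' @param d_revenue,d_opex,d_tci Deltas in annual co-product revenue, annual
#'   operating cost (USD/yr) and total capital investment (USD).
#' @param config A `financial_config`.
#' @return An `mesp_result` with `mode = "incremental"`.
#' @export
incremental_mesp <- function(baseline_mesp, d_revenue = 0, d_opex = 0,
                             d_tci = 0, config = financial_config()) {
  if (baseline_mesp <= 0) stop("baseline MESP must be positive")
  crf <- capital_recovery_factor(config$irr_target, config$horizon)
  mesp <- baseline_mesp -
    (d_revenue - d_opex - crf * d_tci) / config$ethanol_output
  structure(list(mesp = mesp,
                 mesp_gge = gasoline_gallon_equivalent(mesp, config),
                 npv_at_solution = NA_real_, mode = "incremental"),
            class = "mesp_result")
}

#' Gasoline-gallon-equivalent price
#'
#' Divides an ethanol price by the ethanol/gasoline lower-heating-value
#' ratio.
#'
#' @param mesp Ethanol price, USD/gal.
#' @param config A `financial_config` (supplies `gasoline_lhv_ratio`).
#' @return Price in USD per gasoline-gallon equivalent.
#' @export
gasoline_gallon_equivalent <- function(mesp, config = financial_config()) {
  mesp / config$gasoline_lhv_ratio
}
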