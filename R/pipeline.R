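#' Steady-state conversion fractions measured from a reactor series
#'
#' Per-product mean conversion of feed COD over the window, plus the
#' off-gas fraction inferred from mean COD removal. Used to replace the
#' scenario's configured conversion fractions with measured ones.
#'
#' @param series A `reactor_series`.
#' @param window Steady-state window, days.
#' @param products Product compounds to extract fractions for.
#' @return List with `fractions` (named vector) and `offgas_fraction`.
#' @export
measured_conversions <- function(series, window = c(30, 252),
                                 products = c("acetic", "butyric",
                                              "hexanoic", "octanoic")) {
  s <- series$samples
  inside <- s$time_day >= window[1] & s$time_day <= window[2]
  s <- s[inside, , drop = FALSE]
  if (!nrow(s)) stop("no samples inside the window")
  fracs <- vapply(products, function(p) {
    rows <- s[s$compound == p, , drop = FALSE]
    if (!nrow(rows)) return(0)
    mean(vapply(seq_len(nrow(rows)), function(i) {
      feed <- .active_feed(series, rows$time_day[i])
      rows$value[i] / feed$total_soluble_cod
    }, numeric(1)))
  }, numeric(1))
  metrics <- performance_metrics(series)
  ss <- steady_state_summary(metrics, window)
  list(fractions = fracs,
       offgas_fraction = unname(ss$mean["cod_removed"]) / 100)
}

#' Run the full stillage-to-MESP analysis pipeline
#'
#' Composes the analysis stages in order: feed characterization, reactor
#' performance metrics on the supplied (or synthetic) series, the
#' biorefinery COD mass and energy balance, capital and operating economics,
#' and the discounted-cash-flow MESP solution. In `"baseline"` mode the MCFA
#' stage is omitted and the ethanol-electricity baseline is solved (the
#' calibration gate). With `use_measured = TRUE` the scenario's conversion
#' fractions are replaced by the steady-state values measured from the
#' series before the balance and economics run.
#'
#' @param scenario A `tea_scenario` (default: the packaged co-production
#'   scenario).
#' @param series Optional `reactor_series` for the performance block.
#' @param mode `"coproduction"` or `"baseline"`.
#' @param use_measured Replace configured conversions with measured ones
#'   (requires `series`).
#' @param window Steady-state window, days.
#' @return An `analysis_report` list with blocks `feed_characterization`,
#'   `performance`, `balance`, `economics`, `mesp` and `provenance`.
#' @export
run_pipeline <- function(scenario = generate_tea_scenario(), series = NULL,
                         mode = c("coproduction", "baseline"),
                         use_measured = FALSE, window = c(30, 252)) {
  mode <- match.arg(mode)
  scenario <- validate_scenario(scenario)

  feed_char <- feed_characterization()

  performance <- NULL
  if (!is.null(series)) {
    if (!nrow(series$samples)) stop("performance stage: series contains no samples")
    metrics <- performance_metrics(series)
    summary <- steady_state_summary(metrics, window)
    titers <- lapply(c(hexanoic = "hexanoic", octanoic = "octanoic"),
                     function(p) {
                       if (any(series$samples$compound == p)) {
                         productivity_and_titer(series, p, window)
                       }
                     })
    performance <- list(metrics = metrics, steady_state = summary,
                        products = titers)
    if (use_measured) {
      mc <- measured_conversions(series, window)
      scenario$conversions$fractions <- mc$fractions
      scenario$conversions$offgas_fraction <- mc$offgas_fraction
      scenario <- validate_scenario(scenario)
    }
  } else if (use_measured) {
    stop("use_measured = TRUE requires a reactor series")
  }

  balance <- biorefinery_balance(scenario)

  fin <- scenario$financial
  fincfg <- do.call(financial_config, fin$financing)
  baseline_opex <- calibrate_baseline_opex(
    fincfg, fin$baseline_tci, fin$baseline_coproduct_revenue, fin$baseline_mesp
  )

  if (mode == "baseline") {
    economics <- list(tci = fin$baseline_tci,
                      coproduct_revenue = fin$baseline_coproduct_revenue,
                      added_opex = 0, installed_capex = numeric(),
                      itemized = NULL)
    mesp <- solve_mesp(fin$baseline_tci, fin$baseline_coproduct_revenue,
                       baseline_opex, fincfg)
  } else {
    idx <- cost_index(fin$cost_index)
    installed <- scale_equipment_cost(scenario$capex, to_year = 2007, index = idx)
    tci <- total_capital_investment(fin$baseline_tci, installed,
                                    fin$indirect_multiplier)
    opexrev <- annual_opex_and_revenue(scenario$opex, scenario$revenue,
                                       fin$operating_hours,
                                       fin$electricity_price_usd_per_kwh)
    economics <- list(tci = tci, coproduct_revenue = opexrev$annual_revenue,
                      added_opex = opexrev$annual_opex,
                      installed_capex = setNames(installed,
                                                 scenario$capex$description),
                      itemized = opexrev)
    mesp <- solve_mesp(tci, opexrev$annual_revenue,
                       baseline_opex + opexrev$annual_opex, fincfg)
  }

  structure(list(
    feed_characterization = feed_char,
    performance = performance,
    balance = balance,
    economics = economics,
    mesp = c(unclass(mesp),
             list(baseline_mesp = fin$baseline_mesp,
                  baseline_mesp_gge = gasoline_gallon_equivalent(fin$baseline_mesp,
                                                                 fincfg),
                  baseline_annual_opex = baseline_opex)),
    provenance = list(package_version = as.character(utils::packageVersion("mcfatea")),
                      mode = mode, use_measured = use_measured,
                      window = window,
                      config_hash = scenario_hash(scenario))
  ), class = "analysis_report")
}

#' Stable hash of a scenario configuration
#'
#' MD5 of the canonical JSON serialization; identical configurations hash
#' identically, so re-running the deterministic TEA path with the same hash
#' reproduces the same report.
#'
#' @param scenario A scenario list.
#' @return Hex digest string.
#' @export
scenario_hash <- function(scenario) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass(scenario), digits = NA,
                                           auto_unbox = TRUE, force = TRUE)),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Write an analysis report to JSON
#'
#' @param report An `analysis_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Stillage-to-MCFA analysis report\n")
  fc <- x$feed_characterization
  cat(sprintf("  Feed: %.0f%% glucose / %.1f%% xylose consumed; stillage holds %.1f%% of fermented COD; residual ethanol %.1f%%\n",
              fc$glucose_consumed_pct, fc$xylose_consumed_pct,
              fc$stillage_cod_fraction_pct, fc$residual_ethanol_pct))
  if (!is.null(x$performance)) {
    m <- x$performance$steady_state$mean
    cat(sprintf("  Steady state [%g, %g] d: MCFA %.1f%%, SCFA %.1f%%, carbs %.1f%%, COD removed %.1f%%\n",
                x$performance$steady_state$window[1],
                x$performance$steady_state$window[2],
                m["mcfa_conversion"], m["scfa_conversion"],
                m["carbohydrate_conversion"], m["cod_removed"]))
  }
  b <- x$balance
  cat(sprintf("  Balance: %d x %g MG reactors (%.1f MG); HA %.0f kg/h, OA %.0f kg/h recovered; biogas %.0f kg/h; generation %.1f MW; net export %.2f MW (revenue anchor %s kW)\n",
              b$reactors$count, b$reactors$total_volume_mg / b$reactors$count,
              b$reactors$total_volume_mg,
              b$recovered$mass_kg_h[b$recovered$compound == "hexanoic"],
              b$recovered$mass_kg_h[b$recovered$compound == "octanoic"],
              b$biogas_kg_h, b$generation_mw, b$net_export_mw,
              format(b$revenue_export_kw)))
  e <- x$economics
  cat(sprintf("  Economics: TCI $%.1fM, co-product revenue $%.2fM/yr, added opex $%.2fM/yr\n",
              e$tci / 1e6, e$coproduct_revenue / 1e6, e$added_opex / 1e6))
  cat(sprintf("  MESP: $%.2f/gal ($%.2f/gal gasoline-equivalent); baseline $%.2f ($%.2f)\n",
              x$mesp$mesp, x$mesp$mesp_gge, x$mesp$baseline_mesp,
              x$mesp$baseline_mesp_gge))
  invisible(x)
}
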