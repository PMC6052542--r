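#' Default technoeconomic scenario
#'
#' Builds the complete scenario configuration for the
#' ethanol-electricity-MCFA co-production case: stillage flow, fermentation
#' conversion fractions, separation parameters, AD/CHP energy parameters,
#' the capital cost items with installation factors, chemical operating
#' costs, co-product revenues, and financial constants. Optional overrides
#' are merged recursively and the result re-validated.
#'
#' Several defaults are back-solved config inputs where only derived totals
#' are published: the KOH dose from its annual cost and unit price, MCFA
#' unit prices from annual revenue over production, the electricity price
#' and operating hours from the electricity revenue line, and the
#' indirect-cost multiplier from the TCI pair.
#'
#' @param overrides Named list of fields to override (recursively merged).
#' @return A validated scenario list of class `tea_scenario`.
#' @export
generate_tea_scenario <- function(overrides = list()) {
  hours <- 8410
  capex <- rbind(
    capex_item("Mixed culture fermentation reactors",
               7540000 / 4, 4, count = 4, installation_factor = 1,
               size_units = "MG"),
    capex_item("Mixed culture fermentation agitators",
               317000 / (4 * 1.5), 30, count = 4, installation_factor = 1.5,
               size_units = "hp"),
    capex_item("Mixed culture fermentation feed pumps",
               227000 / 4, 2500, count = 4, installation_factor = 1,
               size_units = "gpm"),
    capex_item("Caustic feed system",
               29800 / 4, 300, count = 4, installation_factor = 1,
               size_units = "gph"),
    capex_item("Liquid-liquid extraction",
               860000 / (2 * 2.4), 4700, count = 2, installation_factor = 2.4,
               size_units = "ft3"),
    capex_item("Solvent feed system",
               29200 / 2.4, 50, count = 1, installation_factor = 2.4,
               size_units = "gpm"),
    capex_item("Distillation column 1 (solvent recovery)",
               1420000 / 2.4, 630, count = 1, installation_factor = 2.4,
               size_units = "ft3"),
    capex_item("Distillation column 2 (MCFA separation)",
               797000 / 2.4, 240, count = 1, installation_factor = 2.4,
               size_units = "ft3")
  )
  scenario <- list(
    stillage = list(cod_flow_kg_h = 26000, volumetric_flow_mgd = 16 / 6),
    conversions = list(
      fractions = c(acetic = 0.054, butyric = 0.15,
                    hexanoic = 0.16, octanoic = 0.017),
      offgas_fraction = 0.091
    ),
    separation = list(
      recovery = c(hexanoic = 0.964, octanoic = 0.999),
      solvent = "2-octanol",
      solvent_feed_kg_h = 9000, solvent_loss_kg_h = 745,
      duty_column1_mw = 6.3, duty_column2_mw = 0.75
    ),
    energy = list(
      chp_efficiency = 0.21,
      biogas_yield_kg_per_kg_cod = 16600 / 21000,
      ad_feed_cod_kg_h = 21000,
      baseline_generation_mw = 41.0, baseline_net_export_mw = 13.7,
      scenario_generation_anchor_mw = 38.0,
      revenue_export_kw = 3759,
      cod_energy_mj_per_kg = 13.9
    ),
    reactor = list(srt_days = 6, unit_volume_mg = 4),
    capex = capex,
    opex = data.frame(
      description = c("KOH", "2-Octanol"),
      usage_rate = c(14.0e6 * KG_PER_SHORT_TON / 866 / hours, 745),
      unit = c("kg_h", "kg_h"),
      unit_price = c(866, 1402),
      stringsAsFactors = FALSE
    ),
    revenue = data.frame(
      description = c("Electricity", "HA", "OA"),
      rate = c(3759, 1877, 169),
      unit = c("kW", "kg_h", "kg_h"),
      unit_price = c(NA, 47.45e6 / (1877 * hours), 7.49e6 / (169 * hours)),
      stringsAsFactors = FALSE
    ),
    financial = list(
      operating_hours = hours,
      electricity_price_usd_per_kwh = 0.0572,
      indirect_multiplier = 1.631,
      baseline_tci = 422.9e6,
      baseline_coproduct_revenue = 6.6e6,
      baseline_mesp = 2.15,
      cost_index = c("2007" = 207.34, "2016" = 240.01),
      financing = list()    # overrides for financial_config()
    )
  )
  if (length(overrides)) scenario <- utils::modifyList(scenario, overrides)
  validate_scenario(scenario)
}

#' Validate a scenario configuration
#'
#' Runs every section through its typed constructor so that field-level
#' invariant breaches (conversion fractions summing past 1, recoveries
#' outside [0, 1], non-positive flows, ...) raise informative errors.
#'
#' @param scenario A scenario list.
#' @return The scenario, classed `tea_scenario`, invisibly usable downstream.
#' @export
validate_scenario <- function(scenario) {
  req <- c("stillage", "conversions", "separation", "energy", "reactor",
           "capex", "opex", "revenue", "financial")
  missing <- setdiff(req, names(scenario))
  if (length(missing)) {
    stop("scenario missing section(s): ", paste(missing, collapse = ", "))
  }
  if (scenario$stillage$cod_flow_kg_h <= 0) stop("stillage COD flow must be positive")
  do.call(conversion_spec, scenario$conversions)
  do.call(separation_spec, scenario$separation)
  do.call(energy_model_spec, scenario$energy[
    intersect(names(scenario$energy), names(formals(energy_model_spec)))])
  do.call(financial_config, scenario$financial$financing)
  structure(scenario, class = "tea_scenario")
}

#' Read and write scenario configurations as YAML
#'
#' @param scenario A `tea_scenario`.
#' @param path File path.
#' @return `read_scenario` returns a validated `tea_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  plain <- rapply(unclass(scenario), function(x) {
    # yaml keeps names of lists but not of atomic vectors
    if (is.data.frame(x) || !is.null(names(x))) as.list(x) else x
  }, classes = "ANY", how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  for (tab in c("capex", "opex", "revenue")) {
    if (!is.null(raw[[tab]])) {
      raw[[tab]] <- as.data.frame(raw[[tab]], stringsAsFactors = FALSE)
    }
  }
  for (vec in c("conversions", "separation", "energy", "financial")) {
    nm <- switch(vec, conversions = "fractions", separation = "recovery",
                 financial = "cost_index", NA)
    if (!is.na(nm) && !is.null(raw[[vec]][[nm]])) {
      raw[[vec]][[nm]] <- unlist(raw[[vec]][[nm]])
    }
  }
  validate_scenario(raw)
}
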