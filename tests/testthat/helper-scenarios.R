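# Randomized but valid scenario overrides for conservation/monotonicity
# property tests. Conversions are drawn so fractions + offgas stay below 1.
random_scenario <- function() {
  raw <- stats::runif(5)
  frac <- raw / sum(raw) * stats::runif(1, 0.2, 0.95)
  generate_tea_scenario(list(
    stillage = list(cod_flow_kg_h = stats::runif(1, 5000, 60000)),
    conversions = list(
      fractions = c(acetic = frac[1], butyric = frac[2],
                    hexanoic = frac[3], octanoic = frac[4]),
      offgas_fraction = frac[5]
    ),
    separation = list(recovery = c(hexanoic = stats::runif(1),
                                   octanoic = stats::runif(1)),
                      solvent_loss_kg_h = stats::runif(1, 0, 2000)),
    energy = list(ad_feed_cod_kg_h = NULL)
  ))
}

# COD closure of one balance: recovered + aqueous (net of added solvent COD)
# + offgas must equal the stillage input.
balance_closure_error <- function(scenario) {
  biorefinery_balance(scenario)$cod_closure_rel_error
}
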