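# mcfatea

COD accounting, reactor performance metrics and technoeconomics of
medium-chain fatty acid (MCFA) co-production from lignocellulosic ethanol
stillage.

## What this package is for

After ethanol is distilled from fermented lignocellulosic hydrolysate, the
remaining stillage still holds roughly 60% of the broth's chemical oxygen
demand (COD): xylose, complex carbohydrates, glycerol, acetamide, protein
and a large unidentified pool. Instead of sending all of it to anaerobic
digestion for biogas and electricity, a mixed anaerobic culture can
chain-elongate part of that COD into hexanoic and octanoic acids — products
worth far more than the electricity they displace. This package is for
bioprocess engineers and technoeconomic analysts who want to quantify that
trade-off:

* **COD bookkeeping** (`theoretical_oxygen_demand()`, `mass_to_cod()`,
  `classify_compound()`): theoretical oxygen demand from elemental
  stoichiometry, ThOD = M(O2)·(C + H/4 − O/2 − 3N/4)/MW, a packaged compound
  registry, and SCFA (C2–C5) / MCFA (C6–C8) chain-length classification.
* **Reactor metrics** (`performance_metrics()`, `steady_state_summary()`,
  `productivity_and_titer()`, `feed_characterization()`): per-time-point COD
  removal, carbohydrate conversion and conversion of feed COD to SCFAs and
  MCFAs for a flow-through CSTR, window means ± SD, and volumetric
  productivity / titer-vs-solubility for the product acids.
* **Biorefinery balance** (`biorefinery_balance()` and the stage functions
  it composes): fermentation conversion fractions, reactor sizing,
  liquid–liquid extraction and distillation, anaerobic digestion with a
  calibrated biogas yield, CHP generation and net exportable electricity,
  with COD conservation checked to 0.1%.
* **Economics and MESP** (`scale_equipment_cost()`,
  `annual_opex_and_revenue()`, `solve_mesp()`): power-law equipment cost
  scaling with installation factors, itemized operating costs and
  co-product revenues, and a 30-year discounted cash flow that solves the
  minimum ethanol selling price (the ethanol price at which NPV = 0 at a
  10% IRR). The financing engine is anchored by a calibration gate: it must
  reproduce the ethanol-electricity baseline ($2.15/gal) before scenario
  runs.
* **Synthetic data** (`generate_reactor_series()`,
  `generate_tea_scenario()`): a deterministic-under-seed generator of
  252-day reactor series with configurable conversion targets, acclimation
  dynamics and lognormal measurement noise, so the whole pipeline is
  testable end to end.

See the vignette (`vignettes/stillage-mcfa-tea.Rmd`) for the model, its
assumptions and the reasoning behind every default.

## Worked example

```r
library(mcfatea)
print(run_pipeline())
```

```
Stillage-to-MCFA analysis report
  Feed: 100% glucose / 47.2% xylose consumed; stillage holds 59.8% of fermented COD; residual ethanol 2.8%
  Balance: 4 x 4 MG reactors (16.0 MG); HA 1820 kg/h, OA 181 kg/h recovered; biogas 16600 kg/h; generation 38.0 MW; net export 3.65 MW (revenue anchor 3759 kW)
  Economics: TCI $441.2M, co-product revenue $56.75M/yr, added opex $23.68M/yr
  MESP: $1.77/gal ($2.68/gal gasoline-equivalent); baseline $2.15 ($3.27)
```

Reading the report: the upstream yeast fermentation consumed essentially
all glucose but only 47% of the xylose, which is why stillage still holds
~60% of the fermented-broth COD. Sizing the MCFA fermenter at a 6-day
retention time requires four 4-million-gallon reactors. Extraction and
distillation recover ~1.8 t/h of hexanoic and ~0.18 t/h of octanoic acid;
the remaining organics still produce 16,600 kg/h of biogas, but the added
column duties cut sellable electricity from 13.7 to ~3.7 MW. The extra
capital ($18.3M installed-plus-indirects on a $422.9M plant) and chemical
costs ($23.7M/yr) are outweighed by $56.8M/yr of co-product revenue, so the
30-year discounted cash flow at 10% IRR clears at $1.77/gal ethanol versus
$2.15/gal for the electricity-only baseline — an ~18% reduction
($2.68 vs $3.27 per gasoline-gallon equivalent).

A measured (or synthetic) reactor series can drive the same analysis:

```r
series <- generate_reactor_series(synthetic_reactor_config(noise_cv = 0.02, seed = 42))
report <- run_pipeline(series = series, use_measured = TRUE)
report$performance$steady_state$mean[c("mcfa_conversion", "scfa_conversion")]
#> mcfa_conversion scfa_conversion
#>        17.71205        20.37391
```

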