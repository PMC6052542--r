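Package: mcfatea
Title: COD Accounting and Technoeconomics of Medium-Chain Fatty Acid
    Co-production from Lignocellulosic Stillage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the valorization of lignocellulosic ethanol
    stillage to medium-chain fatty acids (MCFAs) by mixed-culture chain
    elongation. Provides chemical-oxygen-demand (COD) bookkeeping with a
    packaged compound registry, reactor performance metrics for stillage-fed
    flow-through fermenters (COD removal, carbohydrate conversion, conversion
    to short- and medium-chain fatty acids, productivity and titer relative to
    aqueous solubility), a steady-state COD mass and energy balance of a
    modified biorefinery (fermentation, liquid-liquid extraction and
    distillation, anaerobic digestion, combined heat and power), equipment
    cost scaling with installation factors, and a 30-year discounted cash flow
    that solves the minimum ethanol selling price at a target internal rate of
    return. A synthetic reactor time-series generator with configurable
    conversion targets and lognormal measurement noise supports end-to-end
    testing without experimental data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
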