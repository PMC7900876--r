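Package: fishclim
Title: Climate-Driven Landings Projections and Consumer Welfare for US Fisheries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing the economic consequences of climate-driven
    shifts in thermally available habitat for US commercial fisheries. The
    package projects annual landings in proportion to ensemble-mean changes in
    thermal habitat under RCP 4.5 and RCP 8.5, screens fisheries by the present
    value of ex-vessel revenues at a 3 percent real discount rate with Monte
    Carlo confidence intervals, estimates a two-stage inverse almost ideal
    demand system (IAIDS) by iterated seemingly-unrelated-regression GLS under
    adding-up, homogeneity and symmetry restrictions, forecasts seafood
    expenditures from a GDP path and an income elasticity of demand, simulates
    the two-stage budget allocation to obtain implied ex-vessel prices, and
    measures annual consumer-welfare impacts with a translog distance function.
    A seeded synthetic-data generator emulates the monthly landings panel and
    the habitat projection ensemble so the full pipeline is testable without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
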