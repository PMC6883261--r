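Package: agavepi
Title: Environmental Productivity Index Modelling for Agave americana
Version: 0.1.0
Authors@R:
    person("Maricopa", "Modelling Group", email = "agavepi@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the monthly productivity of the obligate
    crassulacean acid metabolism (CAM) crop Agave americana in semi-arid
    regions. Implements the conversion of daily solar radiation records
    (Langley) to monthly mean photosynthetically active radiation, Simpson
    integration of 24 h leaf gas-exchange traces, quadratic light-response
    fitting, light/water/night-temperature indices on [0, 1], their monthly
    product (the environmental productivity index, EPI), cumulative EPI over
    a crop lifetime, linear biomass and combustible-energy yield predictors,
    moisture correction of bomb-calorimetry gross heat, and a seeded
    synthetic-data generator emulating Sonoran-desert weather, irrigation
    schedules, four-phase CAM flux traces and yield observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
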