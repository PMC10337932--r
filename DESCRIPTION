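Package: voyageEB
Title: Thermoregulatory Energy Balance on Simulated Polynesian Voyages
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Couples a drift-plus-sail ocean voyage simulator with a resting
    human energy-balance model to quantify the thermoregulatory cost of
    long-distance canoe passages across the Pacific. Generates synthetic
    gridded environmental fields (surface air temperature, 10-m wind,
    downward shortwave radiation, surface currents) with realistic
    latitudinal, seasonal, diurnal and ENSO-like structure; advances vessels
    from Tahiti toward Hawaii or New Zealand under current drift and a
    sailing polar on a fixed departure schedule; evaluates along-track
    resting energy balance (basal metabolic rate minus dry/wet convective-
    radiative heat loss plus solar gain) for configurable body types and
    exposure assumptions; and aggregates results into departure-day series,
    voyage-integrated energy deficits, destination contrasts, and
    fat/muscle/food/activity equivalents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
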