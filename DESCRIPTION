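Package: lccbalance
Title: Livestock Carrying Capacity from Metabolizable-Energy Supply and Demand Balance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models livestock carrying capacity of Sahelian and Sudanian
    agro-ecosystems as the balance between metabolizable-energy supply from
    feed resources (natural pasture, crop residues, browse) and the seasonal
    energy requirements of cattle, sheep and goat herds. Includes a seeded
    synthetic-data generator for a gridded domain (monthly climate with
    trends, land use, livestock populations), a rain-use-efficiency biomass
    surrogate, supply accounting with proper-use factors, post-harvest decay
    and grazing uplift, CSIRO-style herd energy-requirement equations,
    tropical livestock unit aggregation, supply/demand ratios and deficit-area
    statistics, bioclimatic indices, and Mann-Kendall/Sen trend analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
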