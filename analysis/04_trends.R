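#!/usr/bin/env Rscript
# Stage 4: Mann-Kendall/Sen trend statistics of the regional series,
# bioclimatic indices and their association with carrying capacity.

suppressPackageStartupMessages(library(lccbalance))
suppressPackageStartupMessages(library(dplyr))

cells <- read.csv("results/cells.csv")
climate <- read.csv("results/climate.csv")
balance <- read.csv("results/balance.csv")

regional <- regional_sd(balance)
zone_series <- balance |>
  group_by(zone, year) |>
  summarise(s_mj = sum(s_mj), .groups = "drop")

series <- list(
  supply_region = regional$s_mj,
  supply_sahelian = zone_series$s_mj[zone_series$zone == "sahelian"],
  supply_sudanian = zone_series$s_mj[zone_series$zone == "sudanian"],
  demand_region = regional$d_mj,
  sd_region = regional$ratio_of_totals)
trends <- bind_rows(lapply(names(series), function(nm) {
  mutate(mann_kendall(series[[nm]]), series_id = nm, .before = 1)
}))
write.csv(trends, "results/trends.csv", row.names = FALSE)
cat("Regional trends (Mann-Kendall, Sen slope normalized to %/decade):\n")
print(as.data.frame(trends[, c("series_id", "mk_s", "z", "p_value",
                               "significant", "pct_per_decade")]),
      row.names = FALSE, digits = 3)

bioclim <- bioclim_indices(climate)
write.csv(bioclim, "results/bioclim.csv", row.names = FALSE)

bc_cell <- bioclim |>
  group_by(cell_id) |>
  summarise(across(c(temp_seasonality, precip_seasonality, aridity), mean))
lcc_cell <- balance |>
  group_by(cell_id) |>
  summarise(lcc = mean(lcc_tlu_ha))
stopifnot(identical(bc_cell$cell_id, lcc_cell$cell_id))
assoc <- lcc_bioclim_association(
  lcc_cell$lcc,
  as.data.frame(bc_cell[, c("precip_seasonality", "temp_seasonality",
                            "aridity")]))
write.csv(assoc, "results/lcc_bioclim.csv", row.names = FALSE)
cat("Association of long-term carrying capacity with bioclimatic indices:\n")
print(as.data.frame(assoc), row.names = FALSE, digits = 3)
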