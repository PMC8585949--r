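#!/usr/bin/env Rscript
# Stage 2: convert biomass to metabolizable-energy supply and headcounts to
# herd energy demand, per cell-year and season.

suppressPackageStartupMessages(library(lccbalance))
suppressPackageStartupMessages(library(dplyr))

cells <- read.csv("results/cells.csv")
climate <- read.csv("results/climate.csv")
livestock <- read.csv("results/livestock.csv")
biomass <- read.csv("results/biomass.csv")

seasons <- classify_seasons(climate)
supply <- cell_supply(biomass, cells, seasons)
dem <- cell_demand(livestock, cells, seasons)

write.csv(supply, "results/supply.csv", row.names = FALSE)
write.csv(annual_supply(supply), "results/supply_annual.csv", row.names = FALSE)
write.csv(dem$demand, "results/demand.csv", row.names = FALSE)

ann <- filter(supply, season == "annual")
shares <- ann |>
  mutate(group = ifelse(feed_class == "forage", "natural pasture",
                        ifelse(feed_class == "browse", "browse",
                               "crop residues"))) |>
  group_by(group) |>
  summarise(share_pct = 100 * sum(me_supply_mj) / sum(ann$me_supply_mj))
cat("Feed-class shares of total energy supply (%):\n")
print(as.data.frame(shares), row.names = FALSE)

cat(sprintf("Mean demand per TLU: %.0f MJ ME/TLU/yr (reference band 8000-12000, reported regional mean ~9400)\n",
            mean(dem$demand$mer_per_tlu, na.rm = TRUE)))
cat(sprintf("Total demand %d: %.2f PJ; total supply: %.2f PJ\n",
            min(dem$demand$year),
            sum(dem$demand$d_mj[dem$demand$year == min(dem$demand$year)]) / 1e9,
            sum(ann$me_supply_mj[ann$year == min(ann$year)]) / 1e9))
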