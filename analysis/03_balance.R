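#!/usr/bin/env Rscript
# Stage 3: supply/demand balance, carrying capacity, regional series and
# decadal deficit-area fractions.

suppressPackageStartupMessages(library(lccbalance))

cells <- read.csv("results/cells.csv")
supply_annual <- read.csv("results/supply_annual.csv")
demand <- read.csv("results/demand.csv")

balance <- cell_balance(supply_annual, demand, cells)
regional <- regional_sd(balance)
decadal <- decadal_summary(balance)

write.csv(balance, "results/balance.csv", row.names = FALSE)
write.csv(regional, "results/regional_sd.csv", row.names = FALSE)
write.csv(decadal, "results/decadal_summary.csv", row.names = FALSE)

first <- regional$year == min(regional$year)
cat(sprintf("Regional S/D: %.2f in %d -> %.2f in 2019\n",
            regional$ratio_of_totals[first], min(regional$year),
            regional$ratio_of_totals[regional$year == 2019]))
cross <- min(regional$year[regional$ratio_of_totals < 1])
cat(sprintf("S/D crosses 1.0 in %d (the region exceeds its carrying capacity from then on)\n",
            cross))
cat(sprintf("Mean carrying capacity: %.2f TLU/ha\n",
            mean(tapply(balance$lcc_tlu_ha, balance$cell_id, mean))))
cat("Decadal summary:\n")
print(as.data.frame(decadal[, c("decade", "ratio_of_totals",
                                "mean_of_ratios", "deficit_area_pct")]),
      row.names = FALSE, digits = 3)
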