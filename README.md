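# lccbalance

Livestock carrying capacity of Sahelian and Sudanian agro-ecosystems from the
balance between metabolizable-energy supply and demand.

## The problem

Across the West African Sahelian and Sudanian belts, livestock keepers depend
on three feed resources: natural pasture, crop residues (maize, millet,
sorghum, groundnut) and browse (edible shrub/tree foliage). Whether a
landscape can sustain its herds is an energy-accounting question: the feed
energy an area supplies, *S* (MJ metabolizable energy, ME), versus the energy
its livestock population demands, *D*. The ratio *S/D* quantifies surplus
(*S/D* > 1) or deficit (*S/D* < 1), and the **livestock carrying capacity**

&nbsp;&nbsp;&nbsp;&nbsp;LCC = S / (MER per TLU) / area&nbsp;&nbsp;&nbsp;[TLU ha⁻¹]

is the maximum stocking rate the area can support from its own resources,
expressed in Tropical Livestock Units (TLU, a 250-kg reference animal,
TLUᵢ = Σⱼ (MLWⱼ/250)·HSⱼ·population).

`lccbalance` implements this accounting as a tested pipeline over a seeded
synthetic gridded domain that emulates the statistical structure of the real
region (zone climatologies, land use, herd growth), so that every arithmetic
step — energy conversion, herd requirements, balance, trend statistics — can
be verified under controlled conditions.

## The model

* **Supply.** Per-cell dry-matter production by feed class comes from a
  rain-use-efficiency surrogate (linear in annual precipitation and the
  matching land-use fraction; browse scales with woody cover). Dry matter is
  converted to ME with per-feed proper-use factors and ME contents
  (e.g. forage 55% at 6.1/6.5 MJ kg⁻¹ DM; browse 0.70 × 0.55 ≈ 0.38 at
  6.0/8.1; cereal stems 10%, leaves 76%), an 8%-per-month compound
  post-harvest decay on stored residues, and a 7.6% productivity uplift for
  sustainably grazed pasture.
* **Demand.** Species headcounts are split into herd categories (cattle:
  bull/steer/calf/heifer/cow; sheep and goats: young/mature). Per category
  and season, requirements follow CSIRO-style equations: maintenance
  MER_M = K·Sₓ·M·(0.26·W^0.75·e^(−0.03A))/k_m with k_m = 0.02·ME + 0.5,
  growth MER_G = ADG·17/k_g with k_g = 0.042·ME + 0.006, lactation
  MER_L = milk·3.1/0.6, locomotion MER_T = 0.0026·W·km/k_m. Dry-season
  weight loss (cattle 12%, adult small ruminants 22%) releases a tissue
  mobilization credit (28 MJ kg⁻¹ at 0.84 efficiency); immature small
  ruminants instead gain 30% slower.
* **Balance and trends.** Per cell-year the pipeline reports *S/D*, LCC and
  deficit status; regionally it aggregates ΣS/ΣD (and the area-weighted mean
  of cell ratios), decadal deficit-area fractions, bioclimatic indices
  (temperature seasonality SD×100, damped precipitation CV, De Martonne
  aridity) and Mann–Kendall/Sen trend statistics with the relative trend
  reported as 10·Sen/mean·100 % per decade.

## Worked example

The workflow lives in `analysis/01_simulate.R` … `04_trends.R`; each stage
writes its tables under `results/` and prints what it found. A condensed
in-session version:

```r
library(lccbalance)

cfg <- paper_default_config(seed = 1)   # calibrated study conditions
res <- run_analysis(cfg)

reg <- res$regional
reg$ratio_of_totals[reg$year == 1981]   # 2.607
min(reg$year[reg$ratio_of_totals < 1])  # 2002
res$decadal[, c("decade", "ratio_of_totals", "deficit_area_pct")]
```

```
    decade ratio_of_totals deficit_area_pct
 1981-1990           2.091             13.4
 1991-2000           1.287             19.8
 2001-2010           0.795             35.6
 2011-2020           0.482             58.8
```

Under the calibrated conditions (regional *S/D* = 2.6 in 1981, supply
trending −9% per decade domain-wide and +3.4% in the Sahelian zone, demand
+37% per decade) the regional balance crosses the critical *S/D* = 1 level
in 2002 and the area in feed deficit expands monotonically from 13% to 59%
of the domain. Mean demand per animal unit is ~11,500 MJ ME TLU⁻¹ yr⁻¹
(within the 8,000–12,000 consistency band implied by FAO intake
recommendations) and the long-term mean carrying capacity is
~0.16 TLU ha⁻¹, strongly associated with the aridity gradient (r ≈ 0.97 on
the synthetic domain).

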