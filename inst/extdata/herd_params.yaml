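# Herd structure and energy-requirement parameters.
#
# Herd category shares and mean live weights (mlw_kg) describe a typical
# West African agro-pastoral herd. Remaining category parameters (ages,
# average daily gain, milk offtake, daily travel) are package defaults chosen
# to be plausible for extensive Sahelian/Sudanian systems and calibrated once
# so that the herd-average demand per tropical livestock unit falls around
# the ~9400 MJ ME/TLU/yr reported for the region (and inside the FAO
# 1.5-2.0%-of-bodyweight intake band).
#
# maintenance_k: species factor K of the CSIRO-style maintenance equation
# sex_multiplier: S_x (entire males > 1)
# adg_*: average daily gain, kg/day; cattle do not gain in the dry season
# milk_kg_day: herd-average milk offtake of the category (females only)
# distance_km_day_*: grazing-orbit walking distance per season
energy:
  energy_per_kg_gain: 17.0   # MJ ME per kg live-weight gain
  milk_energy_mj_kg: 3.1     # MJ per kg milk
  k_l: 0.6                   # efficiency of ME use for lactation
  walk_cost_kj_kg_km: 2.6    # locomotion cost, kJ per kg per km
  tissue_energy_mj_kg: 28.0  # energy released per kg mobilized body tissue
  mobilization_efficiency: 0.84
  weight_loss_cattle: 0.12   # dry-season body-weight loss, all cattle
  weight_loss_small_adult: 0.22  # dry-season loss, adult sheep/goats
  immature_dry_adg_factor: 0.7   # immature small-ruminant ADG, dry vs wet
diet_me_mj_kg:               # zone forage ME density, feeds k_m and k_g
  sahelian: 6.1
  sudanian: 6.5
categories:
  - {species: cattle, category: bull,   share: 0.05, mlw_kg: 350, age_yr: 6.0, maintenance_k: 1.2, sex_multiplier: 1.10, mature: true,
     adg_wet: 0.00, adg_dry: 0.00, milk_kg_day: 0.0, distance_km_day_wet: 1.0, distance_km_day_dry: 1.5}
  - {species: cattle, category: steer,  share: 0.10, mlw_kg: 270, age_yr: 2.0, maintenance_k: 1.2, sex_multiplier: 1.00, mature: false,
     adg_wet: 0.06, adg_dry: 0.00, milk_kg_day: 0.0, distance_km_day_wet: 1.0, distance_km_day_dry: 1.5}
  - {species: cattle, category: calf,   share: 0.20, mlw_kg: 100, age_yr: 0.5, maintenance_k: 1.2, sex_multiplier: 1.00, mature: false,
     adg_wet: 0.08, adg_dry: 0.00, milk_kg_day: 0.0, distance_km_day_wet: 1.0, distance_km_day_dry: 1.5}
  - {species: cattle, category: heifer, share: 0.20, mlw_kg: 200, age_yr: 2.0, maintenance_k: 1.2, sex_multiplier: 1.00, mature: false,
     adg_wet: 0.05, adg_dry: 0.00, milk_kg_day: 0.0, distance_km_day_wet: 1.0, distance_km_day_dry: 1.5}
  - {species: cattle, category: cow,    share: 0.45, mlw_kg: 250, age_yr: 6.0, maintenance_k: 1.2, sex_multiplier: 1.00, mature: true,
     adg_wet: 0.00, adg_dry: 0.00, milk_kg_day: 0.4, distance_km_day_wet: 1.0, distance_km_day_dry: 1.5}
  - {species: sheep,  category: young,  share: 0.30, mlw_kg: 20,  age_yr: 0.5, maintenance_k: 1.0, sex_multiplier: 1.00, mature: false,
     adg_wet: 0.025, adg_dry: 0.0175, milk_kg_day: 0.0, distance_km_day_wet: 1.0, distance_km_day_dry: 1.5}
  - {species: sheep,  category: mature, share: 0.70, mlw_kg: 35,  age_yr: 3.0, maintenance_k: 1.0, sex_multiplier: 1.00, mature: true,
     adg_wet: 0.00, adg_dry: 0.00, milk_kg_day: 0.05, distance_km_day_wet: 1.0, distance_km_day_dry: 1.5}
  - {species: goat,   category: young,  share: 0.30, mlw_kg: 18,  age_yr: 0.5, maintenance_k: 1.0, sex_multiplier: 1.00, mature: false,
     adg_wet: 0.02, adg_dry: 0.014, milk_kg_day: 0.0, distance_km_day_wet: 1.0, distance_km_day_dry: 1.5}
  - {species: goat,   category: mature, share: 0.70, mlw_kg: 30,  age_yr: 3.0, maintenance_k: 1.0, sex_multiplier: 1.00, mature: true,
     adg_wet: 0.00, adg_dry: 0.00, milk_kg_day: 0.10, distance_km_day_wet: 1.0, distance_km_day_dry: 1.5}
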