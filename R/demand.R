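# Livestock metabolizable-energy demand: herd structure, CSIRO-style
# requirement equations (maintenance, growth, lactation, locomotion),
# seasonal weight dynamics with tissue mobilization, and tropical livestock
# units.

#' Load herd-structure and energy-requirement parameters
#'
#' @param path YAML parameter file; defaults to the parameters shipped with
#'   the package.
#' @return list with `categories` (tibble, one row per species/category),
#'   `energy` (scalar coefficients) and `diet_me_mj_kg` (per-zone diet ME
#'   density feeding the efficiency terms k_m and k_g).
#' @export
load_herd_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "herd_params.yaml", package = "lccbalance")
  }
  if (!file.exists(path)) {
    stop("herd parameter file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  cat_tab <- dplyr::bind_rows(lapply(raw$categories, tibble::as_tibble))
  shares <- tapply(cat_tab$share, cat_tab$species, sum)
  if (any(abs(shares - 1) > 1e-9)) {
    stop("herd shares must sum to 1 per species", call. = FALSE)
  }
  if (any(cat_tab$mlw_kg <= 0)) stop("mlw_kg must be > 0", call. = FALSE)
  list(categories = cat_tab, energy = raw$energy,
       diet_me_mj_kg = unlist(raw$diet_me_mj_kg))
}

#' Split species headcounts into herd categories
#'
#' @param livestock tibble with `cell_id`, `year`, `species`, `headcount`.
#' @param herd output of [load_herd_params()].
#' @return input expanded to one row per category, with `share`, fractional
#'   `headcount` conserved within species.
#' @export
split_herd <- function(livestock, herd = load_herd_params()) {
  unknown <- setdiff(unique(livestock$species), herd$categories$species)
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  livestock |>
    dplyr::rename(species_headcount = "headcount") |>
    dplyr::inner_join(
      dplyr::select(herd$categories, "species", "category", "share"),
      by = "species", relationship = "many-to-many") |>
    dplyr::mutate(headcount = .data$species_headcount * .data$share) |>
    dplyr::select(-"species_headcount")
}

# efficiency of ME use for maintenance / growth (CSIRO forms)
k_maintenance <- function(diet_me) 0.02 * diet_me + 0.5
k_growth <- function(diet_me) 0.042 * diet_me + 0.006

#' Daily maintenance energy requirement
#'
#' `K * S_x * M * (0.26 * W^0.75 * exp(-0.03 * A)) / k_m` with
#' `k_m = 0.02 * diet_me + 0.5`: the fasting-metabolism form of the CSIRO
#' feeding standard, scaled by species factor `K`, sex multiplier `S_x` and
#' a milk-diet multiplier `M` (1 for grazing animals).
#'
#' @param weight_kg live weight (> 0).
#' @param age_yr age in years.
#' @param sex_multiplier S_x (e.g. 1.1-1.15 for entire males).
#' @param species_factor K (default 1.2, cattle; ~1.0 for sheep/goats).
#' @param diet_me_mj_kg ME density of the diet (> 0), MJ/kg DM.
#' @param milk_multiplier M, 1 for weaned animals.
#' @return MJ per day.
#' @export
mer_maintenance <- function(weight_kg, age_yr, sex_multiplier = 1,
                            species_factor = 1.2, diet_me_mj_kg = 6.5,
                            milk_multiplier = 1) {
  if (any(weight_kg <= 0)) stop("weight_kg must be > 0", call. = FALSE)
  if (any(diet_me_mj_kg <= 0)) stop("diet_me_mj_kg must be > 0", call. = FALSE)
  species_factor * sex_multiplier * milk_multiplier *
    (0.26 * weight_kg^0.75 * exp(-0.03 * age_yr)) /
    k_maintenance(diet_me_mj_kg)
}

#' Daily growth energy requirement
#'
#' `adg * energy_per_kg_gain / k_g` with `k_g = 0.042 * diet_me + 0.006`.
#'
#' @param adg_kg_day average daily gain (>= 0).
#' @param energy_per_kg_gain MJ deposited per kg gain (default 17).
#' @param diet_me_mj_kg diet ME density.
#' @return MJ per day.
#' @export
mer_growth <- function(adg_kg_day, energy_per_kg_gain = 17,
                       diet_me_mj_kg = 6.5) {
  if (any(adg_kg_day < 0)) stop("adg_kg_day must be >= 0", call. = FALSE)
  adg_kg_day * energy_per_kg_gain / k_growth(diet_me_mj_kg)
}

#' Daily lactation energy requirement
#'
#' `milk * milk_energy / k_l`; applies to mature-female categories only
#' (other categories carry zero milk).
#'
#' @param milk_kg_day milk yield (>= 0).
#' @param milk_energy_mj_kg energy content of milk (default 3.1).
#' @param k_l efficiency of ME use for lactation (default 0.6).
#' @return MJ per day.
#' @export
mer_lactation <- function(milk_kg_day, milk_energy_mj_kg = 3.1, k_l = 0.6) {
  if (k_l <= 0) stop("k_l must be > 0", call. = FALSE)
  if (any(milk_kg_day < 0)) stop("milk_kg_day must be >= 0", call. = FALSE)
  milk_kg_day * milk_energy_mj_kg / k_l
}

#' Daily locomotion energy requirement
#'
#' `(walk_cost / 1000) * weight * distance / k_m`.
#'
#' @param weight_kg live weight.
#' @param distance_km_day distance walked (>= 0).
#' @param walk_cost_kj_kg_km cost per kg per km (default 2.6 kJ).
#' @param diet_me_mj_kg diet ME density.
#' @return MJ per day.
#' @export
mer_travel <- function(weight_kg, distance_km_day, walk_cost_kj_kg_km = 2.6,
                       diet_me_mj_kg = 6.5) {
  if (any(distance_km_day < 0)) stop("distance_km_day must be >= 0",
                                     call. = FALSE)
  (walk_cost_kj_kg_km / 1000) * weight_kg * distance_km_day /
    k_maintenance(diet_me_mj_kg)
}

#' Seasonal energy requirement of one herd category
#'
#' Daily components are scaled by the season length. In the dry season
#' cattle (all categories) lose 12% of body weight: maintenance and travel
#' use the season-mean effective weight `MLW * (1 - loss/2)` and the
#' mobilized tissue is credited against the seasonal total
#' (`MLW * loss * tissue_energy * efficiency`). Adult small ruminants lose
#' 22% analogously; immature small ruminants keep their weight but their dry
#' season daily gain is 30% lower than in the wet season. The seasonal total
#' is floored at zero.
#'
#' @param cat one-row category data frame (as in
#'   `load_herd_params()$categories`).
#' @param season `"wet"` or `"dry"`.
#' @param season_days length of the season in days (0-365).
#' @param zone agro-ecological zone (selects the diet ME density).
#' @param herd output of [load_herd_params()].
#' @return one-row tibble with `mer_m`, `mer_g`, `mer_l`, `mer_t`,
#'   `mobilization_credit`, `mer_total` (MJ per animal per season).
#' @export
seasonal_category_demand <- function(cat, season, season_days, zone,
                                     herd = load_herd_params()) {
  if (!season %in% c("wet", "dry")) {
    stop("unknown season: ", season, call. = FALSE)
  }
  stopifnot(season_days >= 0, season_days <= 365)
  en <- herd$energy
  diet_me <- herd$diet_me_mj_kg[[zone]]
  small <- cat$species %in% c("sheep", "goat")

  loss <- 0
  credit <- 0
  adg <- cat$adg_wet
  dist <- cat$distance_km_day_wet
  if (season == "dry") {
    dist <- cat$distance_km_day_dry
    if (cat$species == "cattle") {
      loss <- en$weight_loss_cattle
    } else if (small && cat$mature) {
      loss <- en$weight_loss_small_adult
    }
    credit <- cat$mlw_kg * loss * en$tissue_energy_mj_kg *
      en$mobilization_efficiency
    adg <- if (small && !cat$mature) {
      en$immature_dry_adg_factor * cat$adg_wet
    } else {
      cat$adg_dry
    }
  }
  w_eff <- cat$mlw_kg * (1 - loss / 2)

  m <- mer_maintenance(w_eff, cat$age_yr, cat$sex_multiplier,
                       cat$maintenance_k, diet_me) * season_days
  g <- mer_growth(adg, en$energy_per_kg_gain, diet_me) * season_days
  l <- mer_lactation(cat$milk_kg_day, en$milk_energy_mj_kg, en$k_l) *
    season_days
  tr <- mer_travel(w_eff, dist, en$walk_cost_kj_kg_km, diet_me) * season_days
  tibble::tibble(mer_m = m, mer_g = g, mer_l = l, mer_t = tr,
                 mobilization_credit = credit,
                 mer_total = pmax(0, m + g + l + tr - credit))
}

#' Tropical livestock units of a set of category headcounts
#'
#' `sum((MLW_j / 250) * count_j)`: the standard 250-kg reference animal.
#'
#' @param category_counts tibble with `species`, `category`, `headcount`.
#' @param herd output of [load_herd_params()].
#' @return TLU (scalar).
#' @export
compute_tlu <- function(category_counts, herd = load_herd_params()) {
  key <- match(paste(category_counts$species, category_counts$category),
               paste(herd$categories$species, herd$categories$category))
  if (anyNA(key)) stop("unknown species/category in headcounts", call. = FALSE)
  sum(herd$categories$mlw_kg[key] / 250 * category_counts$headcount)
}

# per-animal seasonal MER for every (category x season x zone x season-day
# profile) combination present; vectorized over rows of `key`
category_season_mer <- function(key, herd) {
  en <- herd$energy
  cats <- herd$categories
  i <- match(paste(key$species, key$category),
             paste(cats$species, cats$category))
  c_ <- cats[i, ]
  diet_me <- herd$diet_me_mj_kg[key$zone]
  dry <- key$season == "dry"
  small <- c_$species %in% c("sheep", "goat")

  loss <- ifelse(dry & c_$species == "cattle", en$weight_loss_cattle,
                 ifelse(dry & small & c_$mature, en$weight_loss_small_adult, 0))
  credit <- c_$mlw_kg * loss * en$tissue_energy_mj_kg *
    en$mobilization_efficiency
  adg <- ifelse(!dry, c_$adg_wet,
                ifelse(small & !c_$mature,
                       en$immature_dry_adg_factor * c_$adg_wet, c_$adg_dry))
  dist <- ifelse(dry, c_$distance_km_day_dry, c_$distance_km_day_wet)
  w_eff <- c_$mlw_kg * (1 - loss / 2)
  days <- key$season_days

  m <- mer_maintenance(w_eff, c_$age_yr, c_$sex_multiplier, c_$maintenance_k,
                       diet_me) * days
  g <- mer_growth(adg, en$energy_per_kg_gain, diet_me) * days
  l <- mer_lactation(c_$milk_kg_day, en$milk_energy_mj_kg, en$k_l) * days
  tr <- mer_travel(w_eff, dist, en$walk_cost_kj_kg_km, diet_me) * days
  dplyr::mutate(key, mer_m = m, mer_g = g, mer_l = l, mer_t = tr,
                mobilization_credit = credit,
                mer_total = pmax(0, m + g + l + tr - credit))
}

#' Per-cell energy demand, TLU and per-TLU requirement
#'
#' Splits headcounts into herd categories, evaluates seasonal per-animal
#' requirements with the cell-year wet/dry season lengths, and aggregates:
#' `D = sum over categories and seasons of headcount * mer_total`,
#' `mer_per_tlu = D / TLU` (NA where TLU = 0).
#'
#' @param livestock tibble `cell_id`, `year`, `species`, `headcount`.
#' @param cells output of [build_domain()] (provides the zone per cell).
#' @param seasons output of [classify_seasons()]; must cover every cell-year.
#' @param herd output of [load_herd_params()].
#' @return list with `demand` (tibble `cell_id`, `year`, `d_mj`, `tlu`,
#'   `mer_per_tlu`) and `breakdown` (per cell-year-category-season MER
#'   components, per animal).
#' @export
cell_demand <- function(livestock, cells, seasons,
                        herd = load_herd_params()) {
  split <- split_herd(livestock, herd) |>
    dplyr::left_join(dplyr::select(cells, "cell_id", "zone"), by = "cell_id") |>
    dplyr::left_join(dplyr::select(seasons, "cell_id", "year", "wet_days",
                                   "dry_days"),
                     by = c("cell_id", "year"))
  if (anyNA(split$wet_days)) {
    stop("missing season mask for some cell-years", call. = FALSE)
  }
  long <- dplyr::bind_rows(
    dplyr::mutate(split, season = "wet", season_days = .data$wet_days),
    dplyr::mutate(split, season = "dry", season_days = .data$dry_days))
  breakdown <- category_season_mer(
    dplyr::select(long, "cell_id", "year", "species", "category", "zone",
                  "season", "season_days", "headcount"), herd)

  mlw <- herd$categories$mlw_kg[
    match(paste(split$species, split$category),
          paste(herd$categories$species, herd$categories$category))]
  tlu_tab <- split |>
    dplyr::mutate(tlu = mlw / 250 * .data$headcount) |>
    dplyr::group_by(.data$cell_id, .data$year) |>
    dplyr::summarise(tlu = sum(.data$tlu), .groups = "drop")

  demand <- breakdown |>
    dplyr::group_by(.data$cell_id, .data$year) |>
    dplyr::summarise(d_mj = sum(.data$headcount * .data$mer_total),
                     .groups = "drop") |>
    dplyr::left_join(tlu_tab, by = c("cell_id", "year")) |>
    dplyr::mutate(mer_per_tlu = ifelse(.data$tlu > 0,
                                       .data$d_mj / .data$tlu, NA_real_))
  list(demand = demand, breakdown = breakdown)
}
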