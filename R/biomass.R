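# Rain-use-efficiency biomass surrogate and wet/dry season classification.
#
# Stands in for a process-based biogeochemical simulation: per-cell dry-matter
# production of each feed class is linear in annual precipitation and the
# matching land-use fraction, which preserves the climate -> biomass causal
# pathway that the downstream trend analysis probes.

#' Default parameters of the biomass surrogate
#'
#' Rain-use efficiencies (kg DM per ha per mm annual precipitation) are
#' back-solved so that, with noise off and the default land-use means, the
#' zone-mean total feed production is 0.1 t/ha (Sahelian) and 0.6 t/ha
#' (Sudanian). Browse foliage production is expressed directly as digestible
#' dry matter: 65 (Sahelian) and 135 (Sudanian) kg/ha at the reference woody
#' cover; no further digestibility factor is applied downstream beyond the
#' 0.38 availability rule.
#'
#' @param stem_fraction fraction of cereal residue mass that is stem (the
#'   remainder is leaf); the 60:40 default is a plumbing choice, not a
#'   reported value.
#' @return list of surrogate parameters.
#' @export
default_biomass_params <- function(stem_fraction = 0.60) {
  list(
    rue_forage = c(sahelian = 100 / 245, sudanian = 600 / 670),
    rue_crop = c(sahelian = 0.731429, sudanian = 1.531343),
    browse_rate = c(sahelian = 65, sudanian = 135),  # kg digestible DM/ha at reference cover
    reference_cover = 0.25,
    stem_fraction = stem_fraction,
    wet_month_threshold_mm = 50
  )
}

#' Classify wet and dry seasons from monthly precipitation
#'
#' A month is wet iff its precipitation is at least `threshold_mm` (default
#' 50 mm). Wet days are `round(30.42 * n_wet)` and dry days the complement of
#' a 365-day year.
#'
#' @param climate tibble as produced by [generate_climate()] (needs
#'   `cell_id`, `year`, `month`, `precip_mm`).
#' @param threshold_mm wet-month precipitation threshold in mm.
#' @return tibble `cell_id`, `year`, `n_wet`, `first_wet`, `last_wet`,
#'   `wet_months` (comma-joined indices), `wet_days`, `dry_days`,
#'   `harvest_month` (month after the last wet month, wrapping past
#'   December).
#' @export
classify_seasons <- function(climate, threshold_mm = 50) {
  counts <- dplyr::count(climate, .data$cell_id, .data$year)
  if (any(counts$n != 12)) {
    stop("classify_seasons: every cell-year needs exactly 12 monthly values",
         call. = FALSE)
  }
  climate |>
    dplyr::group_by(.data$cell_id, .data$year) |>
    dplyr::arrange(.data$month, .by_group = TRUE) |>
    dplyr::summarise(
      n_wet = sum(.data$precip_mm >= threshold_mm),
      first_wet = if (any(.data$precip_mm >= threshold_mm))
        min(.data$month[.data$precip_mm >= threshold_mm]) else NA_integer_,
      last_wet = if (any(.data$precip_mm >= threshold_mm))
        max(.data$month[.data$precip_mm >= threshold_mm]) else NA_integer_,
      wet_months = paste(.data$month[.data$precip_mm >= threshold_mm],
                         collapse = ","),
      .groups = "drop") |>
    dplyr::mutate(
      wet_days = as.integer(round(30.42 * .data$n_wet)),
      dry_days = 365L - .data$wet_days,
      harvest_month = ifelse(is.na(.data$last_wet), NA_integer_,
                             .data$last_wet %% 12L + 1L))
}

#' Simulate per-cell dry-matter production by feed class
#'
#' Noise-free production rules per hectare of cell:
#' * forage: `rue_forage[zone] * annual_precip * frac_grass`
#' * cereal residue (maize, millet, sorghum):
#'   `rue_crop[zone] * annual_precip * frac_crop * crop_share`, split into
#'   stem and leaf by `stem_fraction`
#' * groundnut residue: same rule, whole plant (no split)
#' * browse: `browse_rate[zone] * woody_cover / reference_cover`,
#'   precipitation-independent
#'
#' Multiplicative mean-one lognormal noise (sigma `config$biomass_sigma`) is
#' applied per cell-year-feed-class record.
#'
#' @param cells output of [build_domain()].
#' @param climate output of [generate_climate()].
#' @param config a [domain_config()] (supplies noise level and seed).
#' @param params list from [default_biomass_params()].
#' @return tibble `cell_id`, `year`, `feed_class`, `part`, `dm_kg_ha`,
#'   `harvest_month` (NA except for residues).
#' @export
simulate_biomass <- function(cells, climate, config,
                             params = default_biomass_params()) {
  stopifnot(inherits(config, "domain_config"))
  seasons <- classify_seasons(climate, params$wet_month_threshold_mm)
  annual <- climate |>
    dplyr::group_by(.data$cell_id, .data$year) |>
    dplyr::summarise(annual_precip = sum(.data$precip_mm), .groups = "drop") |>
    dplyr::left_join(cells, by = "cell_id") |>
    dplyr::left_join(dplyr::select(seasons, "cell_id", "year", "harvest_month"),
                     by = c("cell_id", "year"))

  rue_f <- params$rue_forage[annual$zone]
  rue_c <- params$rue_crop[annual$zone]
  forage <- tibble::tibble(
    cell_id = annual$cell_id, year = annual$year,
    feed_class = "forage", part = "whole",
    dm_kg_ha = rue_f * annual$annual_precip * annual$frac_grass,
    harvest_month = NA_integer_)
  browse <- tibble::tibble(
    cell_id = annual$cell_id, year = annual$year,
    feed_class = "browse", part = "whole",
    dm_kg_ha = params$browse_rate[annual$zone] * annual$woody_cover /
      params$reference_cover,
    harvest_month = NA_integer_)

  crops <- c("maize", "millet", "sorghum", "groundnut")
  res <- lapply(crops, function(cr) {
    dm <- rue_c * annual$annual_precip * annual$frac_crop *
      annual[[paste0("share_", cr)]]
    base <- tibble::tibble(cell_id = annual$cell_id, year = annual$year,
                           feed_class = paste0("residue_", cr),
                           dm_total = dm,
                           harvest_month = annual$harvest_month)
    if (cr == "groundnut") {
      dplyr::mutate(base, part = "whole", dm_kg_ha = .data$dm_total)
    } else {
      dplyr::bind_rows(
        dplyr::mutate(base, part = "stem",
                      dm_kg_ha = .data$dm_total * params$stem_fraction),
        dplyr::mutate(base, part = "leaf",
                      dm_kg_ha = .data$dm_total * (1 - params$stem_fraction)))
    } |> dplyr::select(-"dm_total")
  })

  out <- dplyr::bind_rows(c(list(forage, browse), res)) |>
    dplyr::select("cell_id", "year", "feed_class", "part", "dm_kg_ha",
                  "harvest_month")
  if (config$biomass_sigma > 0) {
    set.seed(substream_seed(config$seed, "biomass"))
    s <- config$biomass_sigma
    out$dm_kg_ha <- out$dm_kg_ha *
      stats::rlnorm(nrow(out), meanlog = -s^2 / 2, sdlog = s)
  }
  dplyr::arrange(out, .data$year, .data$cell_id, .data$feed_class, .data$part)
}
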