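# Metabolizable-energy supply accounting: dry matter -> usable MJ ME per
# cell-year and season, with proper-use factors, grazing uplift, post-harvest
# residue decay and the browse availability rule.

#' Browse availability factor
#'
#' Combines the take-70%-leave-30% browsing rule with the general 55%
#' availability factor: `round(take_fraction * availability, 2)`, giving the
#' 0.38 used as the browse proper-use value.
#'
#' @param take_fraction fraction of browse foliage that may be taken.
#' @param availability general feed availability factor.
#' @return rounded availability factor.
#' @export
#' @examples
#' browse_availability()  # 0.38
browse_availability <- function(take_fraction = 0.70, availability = 0.55) {
  round(take_fraction * availability, 2)
}

#' Load feed-energy parameters
#'
#' Reads the shipped feed parameter file (proper-use fractions and ME
#' contents per feed class, part and zone; residue decay; grazing uplift) or
#' a user-supplied file with the same layout. Rows with `zone: both` are
#' expanded to the two agro-ecological zones.
#'
#' @param path YAML parameter file; defaults to the parameters shipped with
#'   the package.
#' @return list with `table` (tibble keyed by feed_class, part, zone),
#'   `decay_per_month`, `grazing_uplift`, `wet_season_forage_share`.
#' @export
load_feed_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "feed_params.yaml", package = "lccbalance")
  }
  if (!file.exists(path)) {
    stop("feed parameter file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  tab <- dplyr::bind_rows(lapply(raw$feeds, tibble::as_tibble))
  both <- tab[tab$zone == "both", ]
  tab <- dplyr::bind_rows(
    tab[tab$zone != "both", ],
    dplyr::mutate(both, zone = "sahelian"),
    dplyr::mutate(both, zone = "sudanian"))
  bad <- tab$proper_use < 0 | tab$proper_use > 1 |
    tab$me_min > tab$me_avg | tab$me_avg > tab$me_max
  if (any(bad)) stop("invalid feed parameters for: ",
                     paste(tab$feed_class[bad], tab$part[bad], collapse = "; "),
                     call. = FALSE)
  list(table = tab,
       decay_per_month = raw$decay_per_month,
       grazing_uplift = raw$grazing_uplift,
       wet_season_forage_share = raw$wet_season_forage_share)
}

#' Post-harvest residue decay factor
#'
#' Nutritive value compounds down by `decay_per_month` for every month of
#' storage: `(1 - decay_per_month)^months_stored`.
#'
#' @param months_stored months since harvest (>= 0, fractional allowed).
#' @param decay_per_month monthly loss fraction in `[0, 1)`.
#' @return factor in (0, 1].
#' @export
residue_decay_factor <- function(months_stored, decay_per_month = 0.08) {
  if (any(months_stored < 0)) stop("months_stored must be >= 0", call. = FALSE)
  if (decay_per_month < 0 || decay_per_month >= 1) {
    stop("decay_per_month must lie in [0, 1)", call. = FALSE)
  }
  (1 - decay_per_month)^months_stored
}

#' Usable metabolizable energy of a feed quantity
#'
#' `dm * proper_use * me_avg`, times the residue decay factor for stored
#' residues, and times `1 + grazing_uplift` for forage (grass growth is
#' simulated ungrazed and corrected to sustainably grazed productivity).
#'
#' @param dm_kg_ha dry matter, kg per ha (>= 0).
#' @param feed_class,part,zone parameter key.
#' @param months_stored storage months (used for residues only).
#' @param params output of [load_feed_params()].
#' @param me_column which ME column to use: `"me_avg"` (central run) or
#'   `"me_min"`/`"me_max"` (uncertainty band).
#' @return MJ ME per ha.
#' @export
usable_energy <- function(dm_kg_ha, feed_class, part, zone, months_stored = 0,
                          params = load_feed_params(), me_column = "me_avg") {
  if (any(dm_kg_ha < 0)) stop("dm_kg_ha must be >= 0", call. = FALSE)
  tab <- params$table
  key <- match(paste(feed_class, part, zone),
               paste(tab$feed_class, tab$part, tab$zone))
  if (anyNA(key)) {
    miss <- unique(paste(feed_class, part, zone)[is.na(key)])
    stop("no feed parameters for: ", paste(miss, collapse = "; "),
         call. = FALSE)
  }
  e <- dm_kg_ha * tab$proper_use[key] * tab[[me_column]][key]
  is_res <- startsWith(tab$feed_class[key], "residue")
  if (any(is_res)) {
    m <- rep_len(months_stored, length(e))
    e[is_res] <- e[is_res] *
      residue_decay_factor(m[is_res], params$decay_per_month)
  }
  is_forage <- tab$feed_class[key] == "forage"
  e[is_forage] <- e[is_forage] * (1 + params$grazing_uplift)
  e
}

#' Per-cell seasonal and annual energy supply
#'
#' Converts the biomass table into MJ ME per cell-year, feed class and
#' season. Forage is split between seasons by the configurable wet-season
#' share (default 0.8); browse follows the wet/dry day proportions; residues
#' are allocated entirely to the dry season, with decay evaluated at
#' mid-storage (half the dry-season length after harvest). Annual records are
#' the sum of the two seasons.
#'
#' @param biomass output of [simulate_biomass()].
#' @param cells output of [build_domain()].
#' @param seasons output of [classify_seasons()].
#' @param params output of [load_feed_params()].
#' @param me_column ME column to use (see [usable_energy()]).
#' @return tibble `cell_id`, `year`, `season` (wet/dry/annual), `feed_class`,
#'   `me_supply_mj` (MJ ME for the whole cell).
#' @export
cell_supply <- function(biomass, cells, seasons,
                        params = load_feed_params(), me_column = "me_avg") {
  orphans <- setdiff(unique(biomass$cell_id), cells$cell_id)
  if (length(orphans)) {
    stop("biomass rows reference unknown cells: ",
         paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
  }
  b <- biomass |>
    dplyr::left_join(dplyr::select(cells, "cell_id", "zone", "area_ha"),
                     by = "cell_id") |>
    dplyr::left_join(dplyr::select(seasons, "cell_id", "year", "n_wet",
                                   "wet_days", "dry_days"),
                     by = c("cell_id", "year"))
  if (anyNA(b$wet_days)) {
    stop("missing season mask for some cell-years", call. = FALSE)
  }
  # storage time to the dry-season midpoint since harvest, in months
  b$months_stored <- (12 - b$n_wet) / 2
  b$energy_ha <- usable_energy(b$dm_kg_ha, b$feed_class, b$part, b$zone,
                               b$months_stored, params, me_column)
  b$energy <- b$energy_ha * b$area_ha

  wet_share <- ifelse(
    b$feed_class == "forage", params$wet_season_forage_share,
    ifelse(b$feed_class == "browse", b$wet_days / 365, 0))
  seasonal <- dplyr::bind_rows(
    dplyr::mutate(b, season = "wet", me_supply_mj = .data$energy * wet_share),
    dplyr::mutate(b, season = "dry",
                  me_supply_mj = .data$energy * (1 - wet_share))) |>
    dplyr::group_by(.data$cell_id, .data$year, .data$season,
                    .data$feed_class) |>
    dplyr::summarise(me_supply_mj = sum(.data$me_supply_mj), .groups = "drop")
  annual <- seasonal |>
    dplyr::group_by(.data$cell_id, .data$year, .data$feed_class) |>
    dplyr::summarise(season = "annual",
                     me_supply_mj = sum(.data$me_supply_mj), .groups = "drop")
  dplyr::bind_rows(seasonal, annual) |>
    dplyr::arrange(.data$year, .data$cell_id, .data$feed_class, .data$season)
}

#' Total annual supply per cell-year
#'
#' Convenience aggregation of [cell_supply()] output: the annual supply `S`
#' summed over feed classes.
#'
#' @param supply output of [cell_supply()].
#' @return tibble `cell_id`, `year`, `s_mj`.
#' @export
annual_supply <- function(supply) {
  supply |>
    dplyr::filter(.data$season == "annual") |>
    dplyr::group_by(.data$cell_id, .data$year) |>
    dplyr::summarise(s_mj = sum(.data$me_supply_mj), .groups = "drop")
}
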