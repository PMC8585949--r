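# Supply/demand balance: S/D ratios, livestock carrying capacity, regional
# series, deficit-area fractions and decadal summaries.

#' Combine per-cell supply and demand into an energy balance table
#'
#' `sd_ratio = s_mj / d_mj` where demand is positive. Cells with demand zero
#' but positive supply carry `sd_ratio = Inf` and are never in deficit;
#' cells with both zero carry `NA` and are excluded from aggregates.
#'
#' @param supply_annual tibble `cell_id`, `year`, `s_mj` (see
#'   [annual_supply()]).
#' @param demand tibble `cell_id`, `year`, `d_mj`, `tlu`, `mer_per_tlu`
#'   (see [cell_demand()]).
#' @param cells output of [build_domain()] (area and zone).
#' @param fallback_mer_per_tlu per-TLU requirement used for the carrying
#'   capacity of cells with no stock, when no zone mean is available
#'   (default 9400 MJ/TLU/yr, the regional herd average).
#' @return tibble `cell_id`, `year`, `zone`, `area_ha`, `s_mj`, `d_mj`,
#'   `tlu`, `sd_ratio`, `deficit`, `lcc_tlu_ha`.
#' @export
cell_balance <- function(supply_annual, demand, cells,
                         fallback_mer_per_tlu = 9400) {
  only_s <- dplyr::anti_join(supply_annual, demand, by = c("cell_id", "year"))
  only_d <- dplyr::anti_join(demand, supply_annual, by = c("cell_id", "year"))
  if (nrow(only_s) || nrow(only_d)) {
    bad <- unique(c(only_s$cell_id, only_d$cell_id))
    stop("supply/demand cell-year keys do not match; offending cells: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  b <- dplyr::inner_join(supply_annual, demand, by = c("cell_id", "year")) |>
    dplyr::left_join(dplyr::select(cells, "cell_id", "zone", "area_ha"),
                     by = "cell_id") |>
    dplyr::mutate(
      sd_ratio = dplyr::case_when(
        .data$d_mj > 0 ~ .data$s_mj / .data$d_mj,
        .data$s_mj > 0 ~ Inf,
        TRUE ~ NA_real_),
      deficit = !is.na(.data$sd_ratio) & .data$sd_ratio < 1)

  zone_mer <- b |>
    dplyr::filter(!is.na(.data$mer_per_tlu)) |>
    dplyr::group_by(.data$zone, .data$year) |>
    dplyr::summarise(zone_mer = mean(.data$mer_per_tlu), .groups = "drop")
  b <- b |>
    dplyr::left_join(zone_mer, by = c("zone", "year")) |>
    dplyr::mutate(
      mer_for_lcc = dplyr::coalesce(.data$mer_per_tlu, .data$zone_mer,
                                    fallback_mer_per_tlu),
      lcc_tlu_ha = lcc(.data$s_mj, .data$mer_for_lcc, .data$area_ha)) |>
    dplyr::select("cell_id", "year", "zone", "area_ha", "s_mj", "d_mj",
                  "tlu", "mer_per_tlu", "sd_ratio", "deficit", "lcc_tlu_ha")
  b
}

#' Livestock carrying capacity of a cell
#'
#' The stocking rate whose annual energy demand would exactly exhaust the
#' supply: `supply_mj / mer_per_tlu / area_ha`, in TLU per hectare.
#'
#' @param supply_mj annual energy supply of the cell, MJ ME.
#' @param mer_per_tlu annual requirement per TLU, MJ (> 0).
#' @param area_ha cell area (> 0).
#' @return TLU per hectare.
#' @export
lcc <- function(supply_mj, mer_per_tlu, area_ha) {
  if (any(mer_per_tlu <= 0, na.rm = TRUE) || any(area_ha <= 0)) {
    stop("mer_per_tlu and area_ha must be > 0", call. = FALSE)
  }
  supply_mj / mer_per_tlu / area_ha
}

#' Regional supply/demand ratio per year
#'
#' Two aggregations are reported: `ratio_of_totals` (`sum(S) / sum(D)`, the
#' default regional series) and `mean_of_ratios` (area-weighted mean of the
#' finite cell ratios).
#'
#' @param balance output of [cell_balance()] (optionally pre-filtered, e.g.
#'   to one zone).
#' @return tibble `year`, `s_mj`, `d_mj`, `ratio_of_totals`,
#'   `mean_of_ratios`.
#' @export
regional_sd <- function(balance) {
  valid <- dplyr::filter(balance, !is.na(.data$sd_ratio))
  if (!nrow(valid)) stop("no valid cells", call. = FALSE)
  valid |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      s_mj = sum(.data$s_mj),
      d_mj = sum(.data$d_mj),
      ratio_of_totals = sum(.data$s_mj) / sum(.data$d_mj),
      mean_of_ratios = {
        fin <- is.finite(.data$sd_ratio)
        stats::weighted.mean(.data$sd_ratio[fin], .data$area_ha[fin])
      },
      .groups = "drop")
}

#' Area fraction in feed deficit over a period
#'
#' Area-weighted percentage of cells whose period-mean S/D ratio is below 1.
#'
#' @param balance output of [cell_balance()].
#' @param period_years years included (default: all present).
#' @return percent of area in `[0, 100]`.
#' @export
deficit_area_fraction <- function(balance, period_years = unique(balance$year)) {
  if (!length(period_years)) stop("period_years must be non-empty", call. = FALSE)
  per_cell <- balance |>
    dplyr::filter(.data$year %in% period_years, !is.na(.data$sd_ratio)) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(mean_sd = mean(.data$sd_ratio),
                     area_ha = .data$area_ha[1], .groups = "drop")
  100 * stats::weighted.mean(per_cell$mean_sd < 1, per_cell$area_ha)
}

#' Decadal balance summary
#'
#' One row per decade (1981-1990, 1991-2000, 2001-2010, 2011-2020, restricted
#' to decades overlapping the data): mean annual total supply and demand,
#' regional S/D by both aggregations, and the deficit-area fraction.
#'
#' @param balance output of [cell_balance()].
#' @return tibble `decade`, `years_used`, `mean_s_mj`, `mean_d_mj`,
#'   `ratio_of_totals`, `mean_of_ratios`, `deficit_area_pct`.
#' @export
decadal_summary <- function(balance) {
  decades <- tibble::tibble(start = c(1981, 1991, 2001, 2011),
                            end = c(1990, 2000, 2010, 2020))
  yrs <- unique(balance$year)
  out <- lapply(seq_len(nrow(decades)), function(i) {
    dy <- intersect(yrs, decades$start[i]:decades$end[i])
    if (!length(dy)) return(NULL)
    if (length(dy) < 10) {
      warning("partial decade ", decades$start[i], "-", decades$end[i],
              ": computed on ", length(dy), " year(s)", call. = FALSE)
    }
    sub <- dplyr::filter(balance, .data$year %in% dy)
    reg <- regional_sd(sub)
    tibble::tibble(
      decade = paste0(decades$start[i], "-", decades$end[i]),
      years_used = length(dy),
      mean_s_mj = mean(reg$s_mj),
      mean_d_mj = mean(reg$d_mj),
      ratio_of_totals = sum(reg$s_mj) / sum(reg$d_mj),
      mean_of_ratios = mean(reg$mean_of_ratios),
      deficit_area_pct = deficit_area_fraction(sub, dy))
  })
  dplyr::bind_rows(out)
}
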