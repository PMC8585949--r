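# Synthetic gridded domain: cells, monthly climate, livestock populations.
#
# The generator emulates the statistical structure the downstream energy
# accounting assumes: a 0.1-degree-style grid split into a Sahelian and a
# Sudanian agro-ecological zone, unimodal monthly rainfall scaled to an
# annual total with a linear trend, and livestock headcounts with a fixed
# spatial distribution growing geometrically over time.

#' Default per-zone settings of the synthetic domain
#'
#' Zone climatologies follow the study region: Sahelian mean annual
#' precipitation (MAP) ~245 mm with a 3-month wet season inside Jun-Sep and
#' mean annual temperature (MAT) ~29 degC; Sudanian MAP ~670 mm with a
#' 6-month May-Oct wet season and MAT ~28 degC. Monthly precipitation is a
#' fixed zone weight vector scaled to the annual total, which reproduces the
#' observed wet-season lengths without a stochastic weather generator.
#'
#' @return named list with one entry per zone (`sahelian`, `sudanian`).
#' @keywords internal
zone_defaults <- function() {
  list(
    sahelian = list(
      map_mm = 245, mat_c = 29,
      precip_trend_mm_yr = 0, warming_c_per_40yr = 1.0,
      # nonzero only Jun-Sep; Sep weight kept low so the zone stays at
      # 3 wet months (>= 50 mm) across the simulated MAP range
      precip_weights = c(0, 0, 0, 0, 0, 0.24, 0.30, 0.32, 0.14, 0, 0, 0),
      # monthly temperature anomaly (degC, mean zero): hottest Apr-May,
      # coolest Dec-Jan, as in the central Sahel
      temp_anomaly = c(-3.5, -1.5, 1.5, 4, 4.5, 2.5, 0, -0.5, 0, 0, -2.5, -4.5),
      landuse_mean = c(frac_grass = 0.70, frac_crop = 0.15, frac_tree = 0.05,
                       frac_settlement = 0.02, frac_other = 0.08),
      crop_share_mean = c(maize = 0.03, millet = 0.60, sorghum = 0.25,
                          groundnut = 0.12),
      woody_cover_mean = 0.012,
      # base stocking densities, head per hectare: the Sahelian zone holds a
      # disproportionate share of the herd relative to its area, as the
      # regional demand split (~34 vs ~41 TJ/yr over 12% vs 78% of area)
      # implies
      density_head_ha = c(cattle = 0.20, sheep = 0.08, goat = 0.08)
    ),
    sudanian = list(
      map_mm = 670, mat_c = 28,
      precip_trend_mm_yr = 0, warming_c_per_40yr = 1.0,
      # May-Oct, all months stay >= 50 mm for annual totals 540-800 mm
      precip_weights = c(0, 0, 0, 0, 0.11, 0.15, 0.21, 0.23, 0.18, 0.12, 0, 0),
      temp_anomaly = c(-2.5, -1, 1.5, 3, 3, 1.5, -0.5, -1, -0.5, 0, -1, -2.5),
      landuse_mean = c(frac_grass = 0.55, frac_crop = 0.25, frac_tree = 0.12,
                       frac_settlement = 0.03, frac_other = 0.05),
      crop_share_mean = c(maize = 0.20, millet = 0.30, sorghum = 0.30,
                          groundnut = 0.20),
      woody_cover_mean = 0.025,
      density_head_ha = c(cattle = 0.045, sheep = 0.02, goat = 0.02)
    )
  )
}

#' Configuration of the synthetic domain
#'
#' @param n_cells number of grid cells (default 500, a down-scaled stand-in
#'   for a full 0.1-degree domain).
#' @param sahel_fraction fraction of cells in the Sahelian zone; the default
#'   0.12/(0.12+0.78) reproduces the 12%/78% area split of the study region.
#' @param area_ha area of one cell in hectares (default 12100, i.e. ~11x11 km,
#'   a 0.1-degree cell in the tropics).
#' @param years calendar years covered (default 1981:2020).
#' @param seed integer master seed; every stochastic component draws from a
#'   named substream derived from it.
#' @param precip_sigma lognormal sigma of multiplicative interannual
#'   precipitation noise (0 switches noise off; default 0.15).
#' @param temp_sigma sd (degC) of the additive annual temperature anomaly.
#' @param biomass_sigma lognormal sigma of multiplicative biomass noise.
#' @param landuse_concentration Dirichlet concentration of per-cell land-use
#'   fractions around the zone means (larger = less spatial heterogeneity).
#' @param crop_share_concentration Dirichlet concentration of per-cell crop
#'   shares around the zone means.
#' @param livestock_alpha Gamma/Dirichlet shape of the fixed per-cell
#'   livestock weights; smaller values give a heavier-tailed stocking
#'   distribution.
#' @param growth_per_decade geometric headcount growth per decade (0.37 means
#'   a factor 1.37 after ten years), applied to all species.
#' @param density_scale multiplier on all base stocking densities.
#' @param zones per-zone settings; see [zone_defaults()].
#' @return object of class `domain_config`.
#' @export
domain_config <- function(n_cells = 500,
                          sahel_fraction = 0.12 / (0.12 + 0.78),
                          area_ha = 12100,
                          years = 1981:2020,
                          seed = 1L,
                          precip_sigma = 0.15,
                          temp_sigma = 0.3,
                          biomass_sigma = 0.10,
                          landuse_concentration = 150,
                          crop_share_concentration = 60,
                          livestock_alpha = 1.5,
                          growth_per_decade = 0.37,
                          density_scale = 1,
                          zones = zone_defaults()) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1) {
    stop("invalid config: n_cells must be a single integer >= 1", call. = FALSE)
  }
  if (sahel_fraction < 0 || sahel_fraction > 1) {
    stop("invalid config: sahel_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (area_ha <= 0) stop("invalid config: area_ha must be > 0", call. = FALSE)
  if (length(years) < 1) stop("invalid config: empty year range", call. = FALSE)
  for (z in names(zones)) {
    w <- zones[[z]]$precip_weights
    stopifnot(length(w) == 12, abs(sum(w) - 1) < 1e-9,
              abs(sum(zones[[z]]$temp_anomaly)) < 1e-6,
              abs(sum(zones[[z]]$landuse_mean) - 1) < 1e-9,
              abs(sum(zones[[z]]$crop_share_mean) - 1) < 1e-9)
  }
  structure(
    list(n_cells = as.integer(n_cells), sahel_fraction = sahel_fraction,
         area_ha = area_ha, years = as.integer(years), seed = as.integer(seed),
         precip_sigma = precip_sigma, temp_sigma = temp_sigma,
         biomass_sigma = biomass_sigma,
         landuse_concentration = landuse_concentration,
         crop_share_concentration = crop_share_concentration,
         livestock_alpha = livestock_alpha,
         growth_per_decade = growth_per_decade,
         density_scale = density_scale,
         zones = zones),
    class = "domain_config")
}

# One master seed drives all generators through named substreams so the whole
# pipeline is reproducible from a single integer.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sw <- rowSums(g)
  # degenerate all-zero rows (possible for tiny alpha) fall back to the mean
  bad <- sw <= 0
  if (any(bad)) {
    g[bad, ] <- matrix(alpha / sum(alpha), nrow = sum(bad), ncol = k,
                       byrow = TRUE)
    sw[bad] <- 1
  }
  g / sw
}

#' Build the synthetic grid-cell table
#'
#' Assigns `round(n_cells * sahel_fraction)` cells to the Sahelian zone and
#' the rest to the Sudanian zone, and draws per-cell land-use fractions, crop
#' shares and woody cover from seeded Dirichlet/Beta distributions around the
#' zone means. Cells are abstract (no coordinates): geography is irrelevant
#' to the energy arithmetic.
#'
#' @param config a [domain_config()].
#' @return tibble with one row per cell: `cell_id`, `zone`, `area_ha`,
#'   land-use fractions (summing to 1), crop shares of `frac_crop`
#'   (`share_maize`, ..., summing to 1) and `woody_cover`.
#' @export
build_domain <- function(config) {
  stopifnot(inherits(config, "domain_config"))
  n <- config$n_cells
  n_sahel <- round(n * config$sahel_fraction)
  zone <- rep(c("sahelian", "sudanian"), times = c(n_sahel, n - n_sahel))
  set.seed(substream_seed(config$seed, "domain"))

  lu <- matrix(NA_real_, nrow = n, ncol = 5)
  cs <- matrix(NA_real_, nrow = n, ncol = 4)
  wc <- numeric(n)
  for (z in c("sahelian", "sudanian")) {
    idx <- which(zone == z)
    if (!length(idx)) next
    zp <- config$zones[[z]]
    lu[idx, ] <- rdirichlet_rows(length(idx),
                                 zp$landuse_mean * config$landuse_concentration)
    cs[idx, ] <- rdirichlet_rows(length(idx),
                                 zp$crop_share_mean * config$crop_share_concentration)
    k <- 200
    wc[idx] <- stats::rbeta(length(idx), zp$woody_cover_mean * k,
                            (1 - zp$woody_cover_mean) * k)
  }
  lu <- lu / rowSums(lu)
  cs <- cs / rowSums(cs)
  colnames(lu) <- c("frac_grass", "frac_crop", "frac_tree",
                    "frac_settlement", "frac_other")
  colnames(cs) <- paste0("share_", c("maize", "millet", "sorghum", "groundnut"))
  tibble::tibble(cell_id = seq_len(n) - 1L, zone = zone,
                 area_ha = config$area_ha) |>
    dplyr::bind_cols(tibble::as_tibble(lu), tibble::as_tibble(cs)) |>
    dplyr::mutate(woody_cover = wc)
}

#' Generate monthly climate series for every cell-year
#'
#' Annual precipitation per cell-year is the zone MAP plus a linear trend
#' centred on the middle of the year range (so the 40-year zone mean equals
#' the configured MAP for any trend), times mean-one lognormal interannual
#' noise; monthly values are the annual total spread over the fixed zone
#' weight vector. Monthly temperature is the zone MAT plus a fixed seasonal
#' anomaly profile, a centred linear warming trend, and an additive Gaussian
#' annual anomaly.
#'
#' @param cells output of [build_domain()].
#' @param config a [domain_config()]; `config$years` must be non-empty.
#' @return tibble `cell_id`, `year`, `month`, `precip_mm`, `tmean_c`.
#' @export
generate_climate <- function(cells, config) {
  stopifnot(inherits(config, "domain_config"))
  years <- config$years
  if (length(years) < 1) stop("empty year range", call. = FALSE)
  y_mid <- mean(years)
  set.seed(substream_seed(config$seed, "climate"))

  grid <- tidyr::expand_grid(cell_id = cells$cell_id, year = years) |>
    dplyr::left_join(dplyr::select(cells, "cell_id", "zone"), by = "cell_id")

  zp <- config$zones
  map <- vapply(zp, function(z) z$map_mm, 0)[grid$zone]
  trend <- vapply(zp, function(z) z$precip_trend_mm_yr, 0)[grid$zone]
  annual <- map + trend * (grid$year - y_mid)
  if (config$precip_sigma > 0) {
    s <- config$precip_sigma
    annual <- annual * stats::rlnorm(nrow(grid), meanlog = -s^2 / 2, sdlog = s)
  }
  annual <- pmax(annual, 0)

  mat <- vapply(zp, function(z) z$mat_c, 0)[grid$zone]
  warm <- vapply(zp, function(z) z$warming_c_per_40yr, 0)[grid$zone] / 40
  t_anom <- if (config$temp_sigma > 0) {
    stats::rnorm(nrow(grid), sd = config$temp_sigma)
  } else 0
  t_year <- mat + warm * (grid$year - y_mid) + t_anom

  pw <- do.call(rbind, lapply(zp, function(z) z$precip_weights))
  ta <- do.call(rbind, lapply(zp, function(z) z$temp_anomaly))
  zi <- match(grid$zone, rownames(pw))

  out <- tidyr::expand_grid(row = seq_len(nrow(grid)), month = 1:12)
  out$cell_id <- grid$cell_id[out$row]
  out$year <- grid$year[out$row]
  out$precip_mm <- annual[out$row] * pw[cbind(zi[out$row], out$month)]
  out$tmean_c <- t_year[out$row] + ta[cbind(zi[out$row], out$month)]
  dplyr::select(out, "cell_id", "year", "month", "precip_mm", "tmean_c")
}

#' Generate livestock headcounts per cell, year and species
#'
#' Per-cell spatial weights are drawn once per species (Dirichlet over cells,
#' tilted by cell area and zone stocking density) and held fixed over the
#' whole period, mirroring the assumption that the relative livestock
#' distribution does not change over the historical period. Species totals
#' grow geometrically at the configured per-decade rate from the first year.
#'
#' @param cells output of [build_domain()].
#' @param config a [domain_config()].
#' @return tibble `cell_id`, `year`, `species`, `headcount` (fractional
#'   animals allowed).
#' @export
generate_livestock <- function(cells, config) {
  stopifnot(inherits(config, "domain_config"))
  years <- config$years
  y0 <- years[1]
  set.seed(substream_seed(config$seed, "livestock"))
  species <- c("cattle", "sheep", "goat")

  out <- vector("list", length(species))
  for (i in seq_along(species)) {
    sp <- species[i]
    dens <- vapply(config$zones, function(z) z$density_head_ha[[sp]], 0)
    base_cell <- cells$area_ha * dens[cells$zone] * config$density_scale
    total0 <- sum(base_cell)
    g <- stats::rgamma(nrow(cells), shape = config$livestock_alpha,
                       rate = config$livestock_alpha)
    w <- base_cell * g
    w <- w / sum(w)
    growth <- (1 + config$growth_per_decade)^((years - y0) / 10)
    out[[i]] <- tibble::tibble(
      cell_id = rep(cells$cell_id, times = length(years)),
      year = rep(years, each = nrow(cells)),
      species = sp,
      headcount = rep(w, times = length(years)) *
        rep(total0 * growth, each = nrow(cells)))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$year, .data$species, .data$cell_id)
}
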