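# End-to-end orchestration: synthetic domain -> biomass -> supply -> demand
# -> balance -> trends, with CSV artifacts and a run manifest.

#' Pipeline configuration
#'
#' @param domain a [domain_config()].
#' @param feed_params_path optional feed parameter YAML (default: shipped
#'   file).
#' @param herd_params_path optional herd parameter YAML (default: shipped
#'   file).
#' @param out_dir output directory for [run_pipeline()].
#' @param sd_method default regional S/D aggregation, `"ratio_of_totals"` or
#'   `"mean_of_ratios"` (both are always computed and written).
#' @param uncertainty_band if TRUE, [run_analysis()] adds two extra supply
#'   runs using the minimum and maximum ME contents.
#' @param write_breakdown write the (large) per-category MER breakdown CSV.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(domain = domain_config(),
                            feed_params_path = NULL,
                            herd_params_path = NULL,
                            out_dir = "results",
                            sd_method = c("ratio_of_totals", "mean_of_ratios"),
                            uncertainty_band = FALSE,
                            write_breakdown = FALSE) {
  stopifnot(inherits(domain, "domain_config"))
  sd_method <- match.arg(sd_method)
  if (any(domain$years < 1900 | domain$years > 2100)) {
    stop("years must lie within 1900-2100", call. = FALSE)
  }
  for (p in c(feed_params_path, herd_params_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("parameter file not found: ", p, call. = FALSE)
    }
  }
  structure(list(domain = domain, feed_params_path = feed_params_path,
                 herd_params_path = herd_params_path, out_dir = out_dir,
                 sd_method = sd_method, uncertainty_band = uncertainty_band,
                 write_breakdown = write_breakdown),
            class = "pipeline_config")
}

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.2fs", stage,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis in memory
#'
#' Executes every stage of the pipeline and returns the tables without
#' touching the file system. [run_pipeline()] is the file-writing wrapper.
#'
#' @param config a [pipeline_config()] (a bare [domain_config()] is wrapped
#'   with defaults).
#' @return list of tibbles: `cells`, `climate`, `livestock`, `seasons`,
#'   `biomass`, `supply`, `supply_annual`, `demand`, `breakdown`, `balance`,
#'   `regional`, `regional_zone`, `decadal`, `bioclim`, `trends`, and (with
#'   `uncertainty_band`) `regional_band`.
#' @export
run_analysis <- function(config) {
  if (inherits(config, "domain_config")) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dom <- config$domain
  feed <- load_feed_params(config$feed_params_path)
  herd <- load_herd_params(config$herd_params_path)

  run_stage <- function(stage, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stage_msg(stage, t0)
    res
  }

  cells <- run_stage("synthgrid", build_domain(dom))
  climate <- run_stage("climate", generate_climate(cells, dom))
  livestock <- run_stage("livestock", generate_livestock(cells, dom))
  seasons <- run_stage("seasons", classify_seasons(climate))
  biomass <- run_stage("biomass", simulate_biomass(cells, climate, dom))
  supply <- run_stage("supply", cell_supply(biomass, cells, seasons, feed))
  s_annual <- annual_supply(supply)
  dem <- run_stage("demand", cell_demand(livestock, cells, seasons, herd))
  balance <- run_stage("balance",
                       cell_balance(s_annual, dem$demand, cells))
  regional <- regional_sd(balance)
  regional_zone <- balance |>
    dplyr::group_by(.data$zone) |>
    dplyr::group_modify(~ regional_sd(.x)) |>
    dplyr::ungroup()
  decadal <- decadal_summary(balance)
  bioclim <- run_stage("bioclim", bioclim_indices(climate))

  trend_input <- list(
    supply_region = regional$s_mj,
    demand_region = regional$d_mj,
    sd_region = regional$ratio_of_totals)
  for (z in unique(regional_zone$zone)) {
    trend_input[[paste0("supply_", z)]] <-
      regional_zone$s_mj[regional_zone$zone == z]
  }
  trends <- dplyr::bind_rows(lapply(names(trend_input), function(nm) {
    dplyr::mutate(mann_kendall(trend_input[[nm]]), series_id = nm,
                  .before = 1)
  }))

  out <- list(cells = cells, climate = climate, livestock = livestock,
              seasons = seasons, biomass = biomass, supply = supply,
              supply_annual = s_annual, demand = dem$demand,
              breakdown = dem$breakdown, balance = balance,
              regional = regional, regional_zone = regional_zone,
              decadal = decadal, bioclim = bioclim, trends = trends)

  if (isTRUE(config$uncertainty_band)) {
    band <- lapply(c(lo = "me_min", hi = "me_max"), function(col) {
      s <- annual_supply(cell_supply(biomass, cells, seasons, feed, col))
      regional_sd(cell_balance(s, dem$demand, cells))
    })
    out$regional_band <- dplyr::bind_rows(band, .id = "bound")
  }
  out
}

#' Run the pipeline and write its artifact set
#'
#' Writes the stage CSVs (`cells.csv`, `climate.csv`, `livestock.csv`,
#' `biomass.csv`, `supply.csv`, `demand.csv`, `balance.csv`,
#' `regional_sd.csv`, `decadal_summary.csv`, `bioclim.csv`, `trends.csv`,
#' optionally `mer_breakdown.csv`) plus `manifest.json` recording the seed,
#' a config fingerprint, and per-file row counts and MD5 checksums. Re-running
#' with the same config reproduces identical tables.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the [run_analysis()] result list, with the manifest
#'   attached as attribute `manifest`.
#' @export
run_pipeline <- function(config) {
  if (inherits(config, "domain_config")) config <- pipeline_config(config)
  res <- run_analysis(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  files <- list(cells = res$cells, climate = res$climate,
                livestock = res$livestock, biomass = res$biomass,
                supply = res$supply, demand = res$demand,
                balance = res$balance, regional_sd = res$regional,
                decadal_summary = res$decadal, bioclim = res$bioclim,
                trends = res$trends)
  if (isTRUE(config$write_breakdown)) files$mer_breakdown <- res$breakdown

  entries <- lapply(names(files), function(nm) {
    path <- file.path(config$out_dir, paste0(nm, ".csv"))
    utils::write.csv(files[[nm]], path, row.names = FALSE)
    list(file = basename(path), rows = nrow(files[[nm]]),
         md5 = unname(tools::md5sum(path)))
  })
  manifest <- list(
    package = "lccbalance",
    version = as.character(utils::packageVersion("lccbalance")),
    seed = res$cells |> attr("seed") %||% config$domain$seed,
    n_cells = config$domain$n_cells,
    years = range(config$domain$years),
    sd_method = config$sd_method,
    config_md5 = digest_config(config),
    outputs = entries)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(res, "manifest") <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable fingerprint of a config: md5 of its deparsed, serialized form
digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}
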