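test_that("herd split conserves headcounts and rejects unknown species", {
  herd <- load_herd_params()
  lv <- tibble::tibble(cell_id = 0L, year = 2000L,
                       species = c("cattle", "sheep", "goat"),
                       headcount = c(100, 40, 0))
  sp <- split_herd(lv, herd)
  sums <- tapply(sp$headcount, sp$species, sum)
  expect_equal(unname(sums[["cattle"]]), 100, tolerance = 1e-9)
  expect_equal(unname(sums[["sheep"]]), 40, tolerance = 1e-9)
  expect_equal(unname(sums[["goat"]]), 0)
  expect_equal(sp$headcount[sp$category == "cow"],
               100 * herd$categories$share[herd$categories$category == "cow"])
  expect_error(split_herd(dplyr::mutate(lv, species = "camel"), herd),
               "camel")
})

test_that("maintenance requirement follows the CSIRO-style closed form", {
  expect_equal(mer_maintenance(250, 4, 1, 1.2, 6.5), 27.63, tolerance = 1e-3)
  # zero age: exponential factor is 1
  expect_equal(mer_maintenance(100, 0, 1, 1.2, 6.5),
               1.2 * 0.26 * 100^0.75 / 0.63, tolerance = 1e-9)
  # proportional in the species factor
  expect_equal(mer_maintenance(250, 4, 1, 2.4, 6.5),
               2 * mer_maintenance(250, 4, 1, 1.2, 6.5))
  expect_error(mer_maintenance(-1, 2), "weight")
})

test_that("growth, lactation and travel components evaluate to their closed forms", {
  expect_equal(mer_growth(0.2, 17, 6.5), 0.2 * 17 / 0.279, tolerance = 1e-9)
  expect_equal(mer_growth(0.2, 17, 6.5), 12.19, tolerance = 1e-3)
  expect_equal(mer_growth(0), 0)
  expect_equal(mer_growth(0.1, 17, 6.5), mer_growth(0.2, 17, 6.5) / 2)

  expect_equal(mer_lactation(1.5), 7.75, tolerance = 1e-9)
  expect_equal(mer_lactation(0), 0)
  expect_equal(mer_lactation(3), 2 * mer_lactation(1.5))
  expect_error(mer_lactation(1, k_l = 0), "k_l")

  expect_equal(mer_travel(250, 10, 2.6, 6.5), 10.32, tolerance = 1e-2)
  expect_equal(mer_travel(250, 0), 0)
  expect_equal(mer_travel(250, 5, 2.6, 6.5), mer_travel(250, 10, 2.6, 6.5) / 2)
})

test_that("seasonal demand applies weight loss, mobilization credit and ADG rules", {
  herd <- load_herd_params()
  cow <- herd$categories[herd$categories$category == "cow" &
                           herd$categories$species == "cattle", ]
  wet <- seasonal_category_demand(cow, "wet", 183, "sudanian", herd)
  expect_equal(wet$mobilization_credit, 0)
  dry <- seasonal_category_demand(cow, "dry", 182, "sudanian", herd)
  expect_equal(dry$mobilization_credit, 250 * 0.12 * 28 * 0.84)  # 705.6
  # dry-season maintenance uses the season-mean reduced weight
  expect_lt(dry$mer_m / 182, wet$mer_m / 183)

  goat_young <- herd$categories[herd$categories$category == "young" &
                                  herd$categories$species == "goat", ]
  gw <- seasonal_category_demand(goat_young, "wet", 183, "sudanian", herd)
  gd <- seasonal_category_demand(goat_young, "dry", 183, "sudanian", herd)
  expect_equal(gd$mer_g / gw$mer_g, 0.7, tolerance = 1e-9)
  expect_equal(gd$mobilization_credit, 0)  # immatures do not mobilize

  expect_error(seasonal_category_demand(cow, "monsoon", 100, "sudanian", herd),
               "season")
  # components non-negative, total floored at zero
  all_rows <- lapply(seq_len(nrow(herd$categories)), function(i) {
    dplyr::bind_rows(
      seasonal_category_demand(herd$categories[i, ], "wet", 91, "sahelian", herd),
      seasonal_category_demand(herd$categories[i, ], "dry", 274, "sahelian", herd))
  })
  all_rows <- dplyr::bind_rows(all_rows)
  expect_true(all(all_rows$mer_m >= 0 & all_rows$mer_g >= 0 &
                    all_rows$mer_l >= 0 & all_rows$mer_t >= 0 &
                    all_rows$mer_total >= 0))
})

test_that("TLU aggregation follows the 250-kg reference formula", {
  herd <- load_herd_params()
  herd$categories <- tibble::tibble(
    species = "cattle", category = c("a", "b"), share = c(0.4, 0.6),
    mlw_kg = c(300, 125), age_yr = 2, maintenance_k = 1.2,
    sex_multiplier = 1, mature = TRUE, adg_wet = 0, adg_dry = 0,
    milk_kg_day = 0, distance_km_day_wet = 0, distance_km_day_dry = 0)
  counts <- tibble::tibble(species = "cattle", category = c("a", "b"),
                           headcount = c(400, 600))
  expect_equal(compute_tlu(counts, herd), (1.2 * 0.4 + 0.5 * 0.6) * 1000)  # 780
  counts$headcount <- c(0, 0)
  expect_equal(compute_tlu(counts, herd), 0)
  one <- tibble::tibble(species = "cattle", category = "a", headcount = 100)
  herd$categories$mlw_kg <- c(250, 125)
  expect_equal(compute_tlu(one, herd), 100)
})

test_that("cell demand sums categories and seasons, monotone in headcount", {
  res <- tiny_result()
  dem <- res$demand
  expect_true(all(dem$d_mj >= 0))
  expect_true(all(dem$tlu >= 0))

  # zero livestock -> zero demand
  lv0 <- dplyr::mutate(res$livestock, headcount = 0)
  d0 <- cell_demand(lv0, res$cells, res$seasons)
  expect_true(all(d0$demand$d_mj == 0))
  expect_true(all(is.na(d0$demand$mer_per_tlu)))

  # doubling headcounts doubles demand, leaves mer_per_tlu unchanged
  lv2 <- dplyr::mutate(res$livestock, headcount = headcount * 2)
  d2 <- cell_demand(lv2, res$cells, res$seasons)
  expect_equal(d2$demand$d_mj, 2 * dem$d_mj, tolerance = 1e-12)
  expect_equal(d2$demand$mer_per_tlu, dem$mer_per_tlu, tolerance = 1e-12)

  # demand equals the breakdown aggregation exactly
  agg <- aggregate(headcount * mer_total ~ cell_id + year, res$breakdown, sum)
  names(agg)[3] <- "d_check"
  m <- merge(dem, agg)
  expect_equal(m$d_mj, m$d_check, tolerance = 1e-12)
})

test_that("implied intake stays inside the FAO bodyweight band", {
  res <- tiny_result()
  herd <- load_herd_params()
  # mean per-TLU requirement as a daily DM intake fraction of a 250-kg animal
  me <- mean(herd$diet_me_mj_kg)
  intake_frac <- mean(res$demand$mer_per_tlu, na.rm = TRUE) / me / 365 / 250
  expect_gt(intake_frac, 0.012)
  expect_lt(intake_frac, 0.025)
})
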