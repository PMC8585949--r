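test_that("zone assignment follows the configured area split", {
  cfg <- domain_config(n_cells = 10, sahel_fraction = 0.2, seed = 1)
  cells <- build_domain(cfg)
  expect_equal(sum(cells$zone == "sahelian"), 2)
  expect_equal(sum(cells$zone == "sudanian"), 8)
  expect_error(domain_config(n_cells = 0), "n_cells")
})

test_that("domain generation is deterministic per seed and simplex-valid", {
  cfg <- domain_config(n_cells = 100, seed = 7)
  a <- build_domain(cfg)
  b <- build_domain(cfg)
  expect_identical(a, b)
  c2 <- build_domain(domain_config(n_cells = 100, seed = 8))
  expect_false(identical(a, c2))

  big <- build_domain(domain_config(n_cells = 500, seed = 3))
  lu <- big$frac_grass + big$frac_crop + big$frac_tree +
    big$frac_settlement + big$frac_other
  expect_true(all(abs(lu - 1) < 1e-9))
  cs <- big$share_maize + big$share_millet + big$share_sorghum +
    big$share_groundnut
  expect_true(all(abs(cs - 1) < 1e-9))
  expect_true(all(big$area_ha > 0))
  expect_true(all(big$woody_cover >= 0 & big$woody_cover <= 1))
})

test_that("noise-free climate reproduces configured MAP exactly, with trend arithmetic", {
  cfg <- tiny_config(n_cells = 4, years = 1981:2020)
  cells <- build_domain(cfg)
  clim <- generate_climate(cells, cfg)
  annual <- aggregate(precip_mm ~ cell_id + year, clim, sum)
  annual <- merge(annual, cells[, c("cell_id", "zone")])
  sahel <- subset(annual, zone == "sahelian")
  expect_true(all(abs(sahel$precip_mm - 245) < 1e-9))
  sudan <- subset(annual, zone == "sudanian")
  expect_true(all(abs(sudan$precip_mm - 670) < 1e-9))

  cfg$zones$sahelian$precip_trend_mm_yr <- 0.7
  clim2 <- generate_climate(cells, cfg)
  a2 <- aggregate(precip_mm ~ cell_id + year, clim2, sum)
  a2 <- merge(a2, cells[, c("cell_id", "zone")])
  s2 <- subset(a2, zone == "sahelian" & cell_id == min(a2$cell_id))
  expect_equal(s2$precip_mm[s2$year == 2020] - s2$precip_mm[s2$year == 1981],
               0.7 * 39, tolerance = 1e-9)

  cfg_empty <- cfg
  cfg_empty$years <- integer(0)
  expect_error(generate_climate(cells, cfg_empty), "year")
})

test_that("Sahelian profile yields a 3-4 month wet season", {
  cfg <- tiny_config(n_cells = 10, years = 1981:1981)
  cells <- build_domain(cfg)
  clim <- generate_climate(cells, cfg)
  sahel_id <- cells$cell_id[cells$zone == "sahelian"][1]
  m <- clim[clim$cell_id == sahel_id, ]
  wet <- m$month[m$precip_mm >= 50]
  expect_true(length(wet) %in% c(3, 4))
  expect_true(all(wet %in% 6:9))
})

test_that("with noise, zone-mean MAP/MAT match configuration within 3 SE", {
  cfg <- domain_config(n_cells = 300, years = 1981:1990, seed = 5)
  cells <- build_domain(cfg)
  clim <- generate_climate(cells, cfg)
  annual <- aggregate(cbind(precip_mm, tmean_c) ~ cell_id + year, clim,
                      function(x) sum(x))
  annual$tmean_c <- annual$tmean_c / 12
  annual <- merge(annual, cells[, c("cell_id", "zone")])
  for (z in c("sahelian", "sudanian")) {
    sub <- subset(annual, zone == z)
    target <- cfg$zones[[z]]$map_mm
    se <- sd(sub$precip_mm) / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$precip_mm) - target), 3 * se)
    se_t <- sd(sub$tmean_c) / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$tmean_c) - cfg$zones[[z]]$mat_c),
              max(3 * se_t, 1e-6))
  }
})

test_that("livestock totals grow geometrically with fixed spatial shares", {
  cfg <- tiny_config(n_cells = 15, years = 1981:1995, seed = 2)
  cells <- build_domain(cfg)
  lv <- generate_livestock(cells, cfg)
  totals <- aggregate(headcount ~ year + species, lv, sum)
  cattle <- subset(totals, species == "cattle")
  expect_equal(cattle$headcount[cattle$year == 1991] /
                 cattle$headcount[cattle$year == 1981],
               1.37, tolerance = 1e-9)

  # per-cell share of the species total is constant across years
  lv <- merge(lv, totals, by = c("year", "species"),
              suffixes = c("", "_total"))
  lv$share <- lv$headcount / lv$headcount_total
  spread <- aggregate(share ~ cell_id + species, lv,
                      function(x) diff(range(x)))
  expect_true(all(spread$share < 1e-9))

  cfg0 <- tiny_config(n_cells = 15, years = 1981:1995, seed = 2,
                      growth_per_decade = 0)
  lv0 <- generate_livestock(cells, cfg0)
  t0 <- aggregate(headcount ~ year + species, lv0, sum)
  expect_true(all(abs(t0$headcount - ave(t0$headcount, t0$species)) < 1e-9))
  expect_true(all(lv$headcount >= 0))
})
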