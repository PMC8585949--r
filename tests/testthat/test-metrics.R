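test_that("temperature seasonality is 100 times the population SD", {
  expect_equal(temperature_seasonality(rep(25, 12)), 0)
  expect_equal(temperature_seasonality(rep(c(20, 30), 6)), 500)
  x <- c(20, 22, 25, 30, 32, 31, 28, 27, 27, 26, 23, 21)
  expect_equal(temperature_seasonality(x + 7), temperature_seasonality(x))
  expect_error(temperature_seasonality(1:11), "12 monthly")
})

test_that("precipitation seasonality uses the damped coefficient of variation", {
  expect_equal(precipitation_seasonality(rep(30, 12)), 0)
  p <- c(120, rep(0, 11))
  expect_equal(precipitation_seasonality(p), sqrt(1100) / 11 * 100,
               tolerance = 1e-9)
  expect_equal(precipitation_seasonality(p), 301.5, tolerance = 1e-3)
  # for large totals the index approaches the plain CV
  big <- p * 1000
  cv <- sd(big) * sqrt(11 / 12) / mean(big) * 100
  expect_equal(precipitation_seasonality(big), cv, tolerance = 1e-3)
  # literal annual-sum divisor variant
  expect_equal(precipitation_seasonality(p, literal_sum = TRUE),
               sqrt(1100) / 121 * 100, tolerance = 1e-9)
  expect_error(precipitation_seasonality(c(-1, rep(0, 11))), ">= 0")
})

test_that("De Martonne aridity matches its closed form", {
  p245 <- rep(245 / 12, 12)
  t29 <- rep(29, 12)
  expect_equal(de_martonne(p245, t29), (245 / 12) / 39, tolerance = 1e-9)
  expect_equal(de_martonne(p245, t29), 0.5235, tolerance = 1e-4)
  expect_equal(de_martonne(rep(0, 12), t29), 0)
  expect_equal(de_martonne(2 * p245, t29), 2 * de_martonne(p245, t29))
  expect_error(de_martonne(p245, rep(-30, 12)), "-10")
})

test_that("Mann-Kendall statistic matches hand-computed examples", {
  mk <- mann_kendall(c(1, 2, 3, 4, 5))
  expect_equal(mk$mk_s, 10)  # n(n-1)/2, all pairs increasing
  expect_equal(mann_kendall(c(3, 1, 2))$mk_s, -1)
  const <- mann_kendall(rep(4, 10))
  expect_equal(const$mk_s, 0)
  expect_false(const$significant)
  expect_equal(const$p_value, 1)
  expect_error(mann_kendall(c(1, 2)), ">= 3")
})

test_that("Mann-Kendall agrees with a brute-force oracle, with ties and symmetry", {
  set.seed(421)
  for (rep in 1:60) {
    n <- sample(5:50, 1)
    x <- rnorm(n)
    if (rep %% 2 == 0) x <- round(x, 1)  # induce ties
    got <- mann_kendall(x)
    ref <- mk_oracle(x)
    expect_identical(got$mk_s, ref$s)
    expect_equal(got$var_s, ref$var, tolerance = 1e-12)
    expect_equal(got$p_value, ref$p, tolerance = 1e-12)
    # reversing the series negates S and preserves p
    rev_mk <- mann_kendall(rev(x))
    expect_identical(rev_mk$mk_s, -got$mk_s)
    expect_equal(rev_mk$p_value, got$p_value, tolerance = 1e-12)
  }
})

test_that("Sen slope is the median pairwise slope", {
  expect_equal(sen_slope(c(1, 3, 5, 7)), 2)
  expect_equal(sen_slope(c(0, 10, 5)), 2.5)  # slopes {10, -5, 2.5}
  expect_equal(sen_slope(rep(2, 6)), 0)
  expect_error(sen_slope(1), ">= 2")
  set.seed(77)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1))
    expect_equal(sen_slope(x), sen_oracle(x), tolerance = 1e-12)
  }
})

test_that("percent per decade normalizes the Sen slope by the series mean", {
  expect_equal(pct_per_decade(c(10, 20, 30, 40)), 400)
  expect_equal(pct_per_decade(rep(5, 10)), 0)
  x <- 100 - 2 * (0:9)
  expect_lt(pct_per_decade(x), 0)
  expect_true(is.na(pct_per_decade(c(-1, 0, 1))))
})

test_that("LCC-bioclimate association recovers exact and null relationships", {
  set.seed(9)
  aridity <- runif(1000, 5, 40)
  fit <- lcc_bioclim_association(2 * aridity, data.frame(aridity = aridity))
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$b, 1, tolerance = 1e-6)

  noise <- rlnorm(1000)
  nullfit <- lcc_bioclim_association(noise, data.frame(aridity = aridity))
  expect_lt(abs(nullfit$r), 0.15)

  constfit <- lcc_bioclim_association(rep(1, 10),
                                      data.frame(aridity = runif(10)))
  expect_true(is.na(constfit$r))
  expect_error(lcc_bioclim_association(1:2, data.frame(a = 1:2)), ">= 3")
})

test_that("bioclim indices over generated climate separate the zones", {
  res <- tiny_result()
  bc <- merge(res$bioclim, res$cells[, c("cell_id", "zone")])
  agg <- aggregate(cbind(aridity, precip_seasonality) ~ zone, bc, mean)
  expect_gt(agg$aridity[agg$zone == "sudanian"],
            agg$aridity[agg$zone == "sahelian"])
  expect_gt(agg$precip_seasonality[agg$zone == "sahelian"],
            agg$precip_seasonality[agg$zone == "sudanian"])
  expect_true(all(bc$temp_seasonality >= 0 & bc$precip_seasonality >= 0))
})
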