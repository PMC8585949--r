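# Bioclimatic indices and trend statistics: temperature/precipitation
# seasonality, De Martonne aridity, Mann-Kendall trend test, Sen slope and
# percent-per-decade normalization, plus the LCC-bioclimate association.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Temperature seasonality index
#'
#' Population standard deviation of the 12 monthly mean temperatures,
#' multiplied by 100.
#'
#' @param monthly_t 12 monthly temperatures (degC).
#' @return unitless index (>= 0).
#' @export
temperature_seasonality <- function(monthly_t) {
  if (length(monthly_t) != 12) stop("need 12 monthly values", call. = FALSE)
  pop_sd(monthly_t) * 100
}

#' Precipitation seasonality index
#'
#' Coefficient-of-variation form: population SD of the 12 monthly totals
#' over `1 +` the monthly mean, times 100. The `+1` damps the index for very
#' dry climates; with `literal_sum = TRUE` the divisor is `1 +` the *annual*
#' total instead (an alternative reading of the typeset formula).
#'
#' @param monthly_p 12 monthly precipitation totals (mm, >= 0).
#' @param literal_sum use the annual-sum divisor variant.
#' @return unitless index (>= 0).
#' @export
precipitation_seasonality <- function(monthly_p, literal_sum = FALSE) {
  if (length(monthly_p) != 12) stop("need 12 monthly values", call. = FALSE)
  if (any(monthly_p < 0)) stop("precipitation must be >= 0", call. = FALSE)
  denom <- if (literal_sum) 1 + sum(monthly_p) else 1 + mean(monthly_p)
  pop_sd(monthly_p) / denom * 100
}

#' De Martonne aridity index
#'
#' `(sum(P) / 12) / (mean(T) + 10)`: monthly-mean precipitation over shifted
#' mean temperature; lower values indicate drier climate.
#'
#' @param monthly_p 12 monthly precipitation totals (mm).
#' @param monthly_t 12 monthly temperatures (degC); mean must exceed -10.
#' @return index in mm/degC units.
#' @export
de_martonne <- function(monthly_p, monthly_t) {
  if (length(monthly_p) != 12 || length(monthly_t) != 12) {
    stop("need 12 monthly values", call. = FALSE)
  }
  denom <- mean(monthly_t) + 10
  if (denom <= 0) stop("mean temperature must exceed -10 degC", call. = FALSE)
  (sum(monthly_p) / 12) / denom
}

#' Bioclimatic indices per cell-year
#'
#' @param climate output of [generate_climate()].
#' @return tibble `cell_id`, `year`, `temp_seasonality`,
#'   `precip_seasonality`, `aridity`.
#' @export
bioclim_indices <- function(climate) {
  climate |>
    dplyr::group_by(.data$cell_id, .data$year) |>
    dplyr::arrange(.data$month, .by_group = TRUE) |>
    dplyr::summarise(
      temp_seasonality = temperature_seasonality(.data$tmean_c),
      precip_seasonality = precipitation_seasonality(.data$precip_mm),
      aridity = de_martonne(.data$precip_mm, .data$tmean_c),
      .groups = "drop")
}

#' Mann-Kendall trend test
#'
#' Rank-based test for a monotonic trend: `S = sum_{i<j} sign(x_j - x_i)`,
#' variance with the standard tie correction, Z with the +/-1 continuity
#' correction (`Z = 0` when `S = 0`), two-sided normal p-value. The
#' companion Sen slope (median of pairwise slopes) and its mean-normalized
#' percent-per-decade are included.
#'
#' @param series numeric series at unit (annual) time steps, `n >= 3`.
#' @param alpha significance level (default 0.05).
#' @return one-row tibble: `n`, `mk_s`, `var_s`, `z`, `p_value`,
#'   `significant`, `sen_slope`, `pct_per_decade`.
#' @export
mann_kendall <- function(series, alpha = 0.05) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 3 || anyNA(x)) stop("need >= 3 non-missing values", call. = FALSE)
  d <- outer(x, x, "-")          # d[i, j] = x_i - x_j
  up <- upper.tri(d)             # pairs with i < j, value x_i - x_j
  s <- -sum(sign(d[up]))         # sum over i<j of sign(x_j - x_i)
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(n = n, mk_s = s, var_s = var_s, z = z, p_value = p,
                 significant = p < alpha,
                 sen_slope = sen_slope(x),
                 pct_per_decade = pct_per_decade(x))
}

#' Sen's slope
#'
#' Median of all pairwise slopes `(x_j - x_i) / (j - i)`; a robust trend
#' magnitude per time step.
#'
#' @param series numeric series, `n >= 2`.
#' @return slope in series units per step.
#' @export
sen_slope <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 2) stop("need >= 2 values", call. = FALSE)
  idx <- seq_len(n)
  num <- outer(x, x, "-")        # x_i - x_j
  den <- outer(idx, idx, "-")
  up <- upper.tri(num)
  stats::median(-num[up] / -den[up])
}

#' Relative trend in percent per decade
#'
#' `10 * sen_slope / mean(series) * 100`, the reporting unit for relative
#' trends of annual series.
#'
#' @param series numeric annual series.
#' @return percent per decade (NA when the series mean is 0).
#' @export
pct_per_decade <- function(series) {
  m <- mean(series)
  if (m == 0) return(NA_real_)
  10 * sen_slope(series) / m * 100
}

#' Association between carrying capacity and bioclimatic indices
#'
#' For each index, the Pearson correlation with LCC across cells plus a
#' least-squares power-law fit `LCC = a * x^b` (log-log start refined by
#' `nls`; fit diagnostics only, no significance claims). Constant indices or
#' constant LCC yield `NA` correlations.
#'
#' @param lcc_by_cell numeric LCC per cell.
#' @param bioclim_by_cell data frame of index columns, rows matching
#'   `lcc_by_cell`.
#' @return tibble `index`, `r`, `a`, `b`.
#' @export
lcc_bioclim_association <- function(lcc_by_cell, bioclim_by_cell) {
  if (length(lcc_by_cell) < 3) stop("need >= 3 cells", call. = FALSE)
  out <- lapply(names(bioclim_by_cell), function(nm) {
    x <- bioclim_by_cell[[nm]]
    y <- lcc_by_cell
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)
    a <- b <- NA_real_
    ok <- x > 0 & y > 0
    if (sum(ok) >= 3 && !is.na(r)) {
      start <- stats::coef(stats::lm(log(y[ok]) ~ log(x[ok])))
      fit <- tryCatch(
        stats::nls(y ~ a * x^b,
                   data = data.frame(x = x[ok], y = y[ok]),
                   start = list(a = exp(start[1]), b = start[2])),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- stats::coef(fit)
        a <- unname(cf["a"]); b <- unname(cf["b"])
      } else {
        a <- unname(exp(start[1])); b <- unname(start[2])
      }
    }
    tibble::tibble(index = nm, r = r, a = a, b = b)
  })
  dplyr::bind_rows(out)
}
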