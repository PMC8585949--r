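# Small seeded fixtures shared across tests; everything is generated in code.

tiny_config <- function(n_cells = 20, years = 1981:1985, seed = 11,
                        noise = FALSE, ...) {
  domain_config(
    n_cells = n_cells, years = years, seed = seed,
    precip_sigma = if (noise) 0.15 else 0,
    temp_sigma = if (noise) 0.3 else 0,
    biomass_sigma = if (noise) 0.10 else 0,
    ...)
}

# one noise-free tiny end-to-end result, computed once per test run
tiny_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(
        suppressMessages(run_analysis(pipeline_config(tiny_config()))))
    }
    cache
  }
})

# brute-force Mann-Kendall oracle: explicit double loop plus closed-form
# normal p-value, independent of the package implementation
mk_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  tie_counts <- as.numeric(table(x))
  tie_counts <- tie_counts[tie_counts > 1]
  v <- (n * (n - 1) * (2 * n + 5) -
          sum(tie_counts * (tie_counts - 1) * (2 * tie_counts + 5))) / 18
  z <- if (s == 0) 0 else (s - sign(s)) / sqrt(v)
  list(s = s, var = v, z = z, p = 2 * stats::pnorm(-abs(z)))
}

sen_oracle <- function(x) {
  n <- length(x)
  slopes <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) slopes <- c(slopes, (x[j] - x[i]) / (j - i))
  }
  stats::median(slopes)
}
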