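# Shared fixtures: small generator configs and independent brute-force
# oracles kept deliberately naive (loops, direct counting) so they stay
# independent of the package's vectorised implementations.

tiny_config <- function(...) {
  args <- modifyList(
    list(n_basins = 5, pixels_per_basin = 200, n_models = 3,
         year_range = c(1984, 2030), seed = 42L),
    list(...))
  do.call(generator_config, args)
}

# brute-force saturated fraction: explicit loop over pixels
oracle_fraction <- function(cti, thr) {
  hits <- 0L
  for (v in cti) if (v >= thr) hits <- hits + 1L
  hits / length(cti)
}

# brute-force Mann-Kendall S: explicit double loop over ordered pairs
oracle_mk_S <- function(x) {
  n <- length(x)
  S <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S <- S + sign(x[j] - x[i])
    }
  }
  as.integer(S)
}

# a monthly series with a prescribed annual-mean trajectory
monthly_series <- function(annual_means, start_year, sm_sat = 900,
                           column_depth_m = 2) {
  times <- numeric(0); values <- numeric(0)
  for (k in seq_along(annual_means)) {
    times <- c(times, start_year + k - 1 + (1:12 - 0.5) / 12)
    values <- c(values, rep(annual_means[k], 12))
  }
  sm_series(times, values, sm_sat, column_depth_m)
}
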