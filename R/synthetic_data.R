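# Seeded synthetic-data generator: basins with heavy-right-tailed CTI
# distributions, seasonal+trend+noise soil-moisture cubes for a pseudo-model
# ensemble, observed wetland areas produced by the forward model under a
# hidden per-basin M, and labelled sample points for accuracy assessment.

#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the generator in one validated object. Defaults are
#' the package's standing study conditions: 200 basins of 4000 CTI pixels
#' drawn from a gamma(4, scale 2) law (right-skewed and positive, like real
#' CTI histograms; mean 8), a 14-member pseudo-model ensemble over the four
#' SSP scenarios for 1984-2100, a 0-200 cm column saturating at 900 kg/m2
#' (porosity 0.45 x 2 m of water-equivalent depth), and scenario soil-moisture
#' trends ordered mild to severe.
#'
#' @param n_basins number of basins.
#' @param pixels_per_basin CTI pixels drawn per basin.
#' @param cti_shape,cti_scale gamma parameters of the CTI pixel law; both
#'   positive (mean CTI = shape * scale).
#' @param basin_area_km2_range range the basin areas are drawn from, km2.
#' @param n_models number of ensemble pseudo-models; member 1 is the
#'   designated "truth" model that generates observations.
#' @param scenarios scenario labels, ordered mild to severe.
#' @param year_range first and last simulated calendar year.
#' @param sm_sat column saturation, kg/m2.
#' @param sm_baseline_frac baseline soil moisture as a fraction of `sm_sat`.
#' @param sm_trend_frac_per_decade per-scenario trend, fraction of `sm_sat`
#'   per decade (recycled to `length(scenarios)`); `|trend| <= 1`.
#' @param sm_seasonal_amp_frac seasonal sinusoid amplitude, fraction of
#'   `sm_sat`.
#' @param sm_noise_sd_frac monthly Gaussian noise s.d., fraction of `sm_sat`.
#' @param true_M_range integer range the hidden per-basin M is drawn from;
#'   must lie within `[1, 15]`.
#' @param obs_noise_cv coefficient of variation of the multiplicative
#'   lognormal observation noise on observed areas.
#' @param label_error_rate probability a sample point's mapped label differs
#'   from its reference label.
#' @param column_depth_m soil column depth, metres.
#' @param model_baseline_sd,model_trend_sd ensemble spread: s.d. of the
#'   per-model baseline offset (fraction of `sm_sat`) and of the per-model
#'   multiplicative trend factor. The truth model gets the nominal values.
#' @param lon_range,lat_range box the basin centroids are scattered in,
#'   decimal degrees (default roughly continental Africa).
#' @param seed integer RNG seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @return Object of class `generator_config` (a validated named list).
#' @examples
#' cfg <- generator_config(n_basins = 5, pixels_per_basin = 100, seed = 1)
#' @export
generator_config <- function(n_basins = 200,
                             pixels_per_basin = 4000,
                             cti_shape = 4,
                             cti_scale = 2,
                             basin_area_km2_range = c(100, 5000),
                             n_models = 14,
                             scenarios = c("SSP126", "SSP245", "SSP370", "SSP585"),
                             year_range = c(1984, 2100),
                             sm_sat = 900,
                             sm_baseline_frac = 0.6,
                             sm_trend_frac_per_decade = c(0.005, 0.010, 0.015, 0.020),
                             sm_seasonal_amp_frac = 0.05,
                             sm_noise_sd_frac = 0.02,
                             true_M_range = c(1L, 15L),
                             obs_noise_cv = 0.05,
                             label_error_rate = 0.1,
                             column_depth_m = 2,
                             model_baseline_sd = 0.02,
                             model_trend_sd = 0.15,
                             lon_range = c(-17, 50),
                             lat_range = c(-34, 37),
                             seed = 1L) {
  cfg <- list(n_basins = as.integer(n_basins),
              pixels_per_basin = as.integer(pixels_per_basin),
              cti_shape = cti_shape, cti_scale = cti_scale,
              basin_area_km2_range = as.numeric(basin_area_km2_range),
              n_models = as.integer(n_models),
              scenarios = as.character(scenarios),
              year_range = as.integer(year_range),
              sm_sat = as.numeric(sm_sat),
              sm_baseline_frac = sm_baseline_frac,
              sm_trend_frac_per_decade =
                rep_len(as.numeric(sm_trend_frac_per_decade), length(scenarios)),
              sm_seasonal_amp_frac = sm_seasonal_amp_frac,
              sm_noise_sd_frac = sm_noise_sd_frac,
              true_M_range = as.integer(true_M_range),
              obs_noise_cv = as.numeric(obs_noise_cv),
              label_error_rate = as.numeric(label_error_rate),
              column_depth_m = as.numeric(column_depth_m),
              model_baseline_sd = as.numeric(model_baseline_sd),
              model_trend_sd = as.numeric(model_trend_sd),
              lon_range = as.numeric(lon_range),
              lat_range = as.numeric(lat_range),
              seed = as.integer(seed))

  counts <- c("n_basins", "pixels_per_basin", "n_models")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      .stopf("invalid config: %s must be a count >= 1", nm)
  if (!is.finite(cfg$cti_shape) || !is.finite(cfg$cti_scale) ||
      cfg$cti_shape <= 0 || cfg$cti_scale <= 0)
    .stopf("invalid config: gamma parameters cti_shape/cti_scale must be positive")
  fracs <- c("sm_baseline_frac", "sm_seasonal_amp_frac", "sm_noise_sd_frac")
  for (nm in fracs)
    if (any(cfg[[nm]] < 0) || any(cfg[[nm]] > 1))
      .stopf("invalid config: %s must lie in [0, 1]", nm)
  if (any(abs(cfg$sm_trend_frac_per_decade) > 1))
    .stopf("invalid config: |sm_trend_frac_per_decade| must be <= 1")
  if (cfg$obs_noise_cv < 0 || cfg$label_error_rate < 0 ||
      cfg$label_error_rate > 1)
    .stopf("invalid config: obs_noise_cv >= 0 and label_error_rate in [0, 1] required")
  if (length(cfg$true_M_range) != 2L || cfg$true_M_range[1] < 1L ||
      cfg$true_M_range[2] > 15L || cfg$true_M_range[1] > cfg$true_M_range[2])
    .stopf("invalid config: true_M_range must be an ordered integer range within [1, 15]")
  if (length(cfg$year_range) != 2L || cfg$year_range[1] > cfg$year_range[2])
    .stopf("invalid config: year_range must be an ordered pair of years")
  if (length(cfg$basin_area_km2_range) != 2L ||
      any(cfg$basin_area_km2_range <= 0) ||
      cfg$basin_area_km2_range[1] > cfg$basin_area_km2_range[2])
    .stopf("invalid config: basin_area_km2_range must be positive and ordered")
  if (cfg$sm_sat <= 0 || cfg$column_depth_m <= 0)
    .stopf("invalid config: sm_sat and column_depth_m must be positive")
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    .stopf("invalid config: seed must be a single integer")
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic-data config: %d basins x %d CTI pixels, %d models x %d scenarios, %d-%d, seed %d\n",
    x$n_basins, x$pixels_per_basin, x$n_models, length(x$scenarios),
    x$year_range[1], x$year_range[2], x$seed))
  invisible(x)
}

#' Generate a set of synthetic basins
#'
#' Draws, per basin, `pixels_per_basin` CTI values from the configured gamma
#' law, an area uniform in `basin_area_km2_range`, a centroid uniform in the
#' configured box, and a hidden "true" M uniform on the integers of
#' `true_M_range`. The true M drives [generate_observed_areas()] and is
#' recorded for parameter-recovery experiments.
#'
#' @param config a [generator_config].
#' @return Object of class `basin_set`: a list with `basins` (list of
#'   [basin_record]), `true_M` (named integer vector, the hidden truth) and
#'   `config`. `as.data.frame()` gives one row per basin.
#' @examples
#' bs <- generate_basins(generator_config(n_basins = 3, pixels_per_basin = 50))
#' as.data.frame(bs)
#' @export
generate_basins <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(.stage_seed(config$seed, "basins"))
  n <- config$n_basins
  ids <- sprintf("basin%04d", seq_len(n))
  areas <- runif(n, config$basin_area_km2_range[1], config$basin_area_km2_range[2])
  lons <- runif(n, config$lon_range[1], config$lon_range[2])
  lats <- runif(n, config$lat_range[1], config$lat_range[2])
  true_M <- sample(seq(config$true_M_range[1], config$true_M_range[2]),
                   n, replace = TRUE)
  basins <- vector("list", n)
  for (i in seq_len(n)) {
    cti <- rgamma(config$pixels_per_basin, shape = config$cti_shape,
                  scale = config$cti_scale)
    basins[[i]] <- basin_record(ids[i], areas[i], cti,
                                lon = lons[i], lat = lats[i])
  }
  names(basins) <- ids
  structure(list(basins = basins,
                 true_M = setNames(as.integer(true_M), ids),
                 config = config),
            class = "basin_set")
}

#' @export
length.basin_set <- function(x) length(x$basins)

#' @export
as.data.frame.basin_set <- function(x, ...) {
  data.frame(
    basin_id = names(x$basins),
    area_km2 = vapply(x$basins, `[[`, numeric(1), "area_km2"),
    cti_mean = vapply(x$basins, `[[`, numeric(1), "cti_mean"),
    lon = vapply(x$basins, `[[`, numeric(1), "lon"),
    lat = vapply(x$basins, `[[`, numeric(1), "lat"),
    true_M = unname(x$true_M),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.basin_set <- function(x, ...) {
  cat(sprintf("Synthetic basin set: %d basins, %d CTI pixels each, seed %d\n",
              length(x$basins), x$config$pixels_per_basin, x$config$seed))
  invisible(x)
}

#' Generate a multi-model multi-scenario soil-moisture cube
#'
#' Monthly basin-mean soil moisture per (model, scenario, basin):
#' `sm_sat * (baseline_m + trend_sm * (t - t0)/10 + seasonal sinusoid +
#' Gaussian noise)`, clipped to `[0, sm_sat]`. Each pseudo-model perturbs the
#' baseline and scales the scenario trend (the designated truth model, member
#' 1, keeps the nominal values); scenario trend magnitudes stay ordered as
#' configured.
#'
#' @param basins a [basin_set] (or list of [basin_record]).
#' @param config a [generator_config].
#' @param year_range optional override of the config's simulated span (used
#'   to generate e.g. only the historical years).
#' @return Object of class `sm_cube`: list with `values` (4-d array
#'   `model x scenario x time x basin`), `times` (decimal years, month
#'   midpoints), `sm_sat`, `column_depth_m`, `models`, `scenarios`,
#'   `basin_ids`, `model_params`.
#' @examples
#' cfg <- generator_config(n_basins = 2, pixels_per_basin = 50, n_models = 3,
#'                         year_range = c(2000, 2002))
#' cube <- generate_sm_cube(generate_basins(cfg), cfg)
#' dim(cube$values)
#' @export
generate_sm_cube <- function(basins, config, year_range = config$year_range) {
  stopifnot(inherits(config, "generator_config"))
  blist <- if (inherits(basins, "basin_set")) basins$basins else basins
  if (length(blist) == 0L) .stopf("basins must be non-empty")
  basin_ids <- unname(vapply(blist, `[[`, character(1), "basin_id"))
  set.seed(.stage_seed(config$seed, "sm"))

  years <- seq(year_range[1], year_range[2])
  times <- rep(years, each = 12L) + (rep(1:12, length(years)) - 0.5) / 12
  nt <- length(times)
  nm <- config$n_models
  ns <- length(config$scenarios)
  nb <- length(blist)
  models <- sprintf("model%02d", seq_len(nm))

  # per-model perturbations; member 1 is the truth model (nominal values)
  base_off <- c(0, rnorm(nm - 1L, 0, config$model_baseline_sd))
  trend_fac <- c(1, rnorm(nm - 1L, 1, config$model_trend_sd))
  model_params <- data.frame(model = models, baseline_offset = base_off,
                             trend_factor = trend_fac,
                             stringsAsFactors = FALSE)

  t0 <- times[1]
  seasonal <- config$sm_seasonal_amp_frac * sin(2 * pi * (times %% 1))
  decades <- (times - t0) / 10

  vals <- array(NA_real_, dim = c(nm, ns, nt, nb),
                dimnames = list(model = models, scenario = config$scenarios,
                                time = NULL, basin = basin_ids))
  # deterministic part
  for (m in seq_len(nm)) {
    for (s in seq_len(ns)) {
      mu <- config$sm_baseline_frac + base_off[m] +
        trend_fac[m] * config$sm_trend_frac_per_decade[s] * decades + seasonal
      vals[m, s, , ] <- mu
    }
  }
  # one draw in a fixed order => byte-identical under the seed
  if (config$sm_noise_sd_frac > 0)
    vals <- vals + array(rnorm(length(vals), 0, config$sm_noise_sd_frac),
                         dim = dim(vals), dimnames = dimnames(vals))
  vals <- config$sm_sat * pmin(pmax(vals, 0), 1)

  # a series clipped flat to zero is almost surely a configuration mistake
  if (any(apply(vals, c(1, 2, 4), function(v) all(v == 0))))
    .warnf("at least one soil-moisture series is constant at 0 after clipping")

  structure(list(values = vals, times = times, sm_sat = config$sm_sat,
                 column_depth_m = config$column_depth_m, models = models,
                 scenarios = config$scenarios, basin_ids = basin_ids,
                 model_params = model_params),
            class = "sm_cube")
}

#' @export
print.sm_cube <- function(x, ...) {
  cat(sprintf(
    "Soil-moisture cube: %d models x %d scenarios x %d months x %d basins (%.0f-%.0f), sm_sat %.1f kg/m2\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], dim(x$values)[4],
    floor(x$times[1]), floor(x$times[length(x$times)]), x$sm_sat))
  invisible(x)
}

#' Extract one basin's soil-moisture series from a cube
#'
#' @param cube an `sm_cube`.
#' @param basin_id basin identifier present in the cube.
#' @param model,scenario ensemble member and scenario; defaults are the
#'   designated truth member (the first) and the first scenario.
#' @return An [sm_series].
#' @export
extract_sm_series <- function(cube, basin_id, model = cube$models[1],
                              scenario = cube$scenarios[1]) {
  stopifnot(inherits(cube, "sm_cube"))
  if (!model %in% cube$models) .stopf("model '%s' not in cube", model)
  if (!scenario %in% cube$scenarios) .stopf("scenario '%s' not in cube", scenario)
  if (!basin_id %in% cube$basin_ids) .stopf("basin '%s' not in cube", basin_id)
  sm_series(cube$times, cube$values[model, scenario, , basin_id],
            sm_sat = cube$sm_sat, column_depth_m = cube$column_depth_m)
}

#' Default historical mapping periods
#'
#' Nine multi-year windows partitioning 1984-2021, mirroring a nine-map
#' historical wetland record whose first window is 1984-1990 and last is
#' 2019-2021. The partition is a default, not a constant: any period table
#' with `start`/`end` columns can be used in its place.
#'
#' @return data.frame with columns `label`, `start`, `end`.
#' @export
default_historical_periods <- function() {
  starts <- c(1984, 1991, 1995, 1999, 2003, 2007, 2011, 2015, 2019)
  ends   <- c(1990, 1994, 1998, 2002, 2006, 2010, 2014, 2018, 2021)
  data.frame(label = sprintf("%d-%d", starts, ends),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Generate observed wetland areas per basin and period
#'
#' The observation model: per basin and historical period, the forward model
#' ([simulate_area_series]) is run with the basin's hidden true M on the
#' period-mean soil moisture of the designated truth ensemble member, and the
#' resulting area is multiplied by lognormal noise with coefficient of
#' variation `obs_noise_cv` (multiplicative, mean one — classification error
#' scales with extent and areas stay positive). With `obs_noise_cv = 0` the
#' observed areas are exactly the forward-model areas (closed loop).
#'
#' @param basins a [basin_set] (carries the hidden true M).
#' @param sm_cube an `sm_cube` covering the periods.
#' @param historical_periods period table with `start`/`end` (default
#'   [default_historical_periods()]).
#' @param config a [generator_config] (`obs_noise_cv`, `seed`).
#' @return data.frame of class `observed_areas` with columns `basin_id`,
#'   `label`, `start`, `end`, `area_km2`; attributes `true_M` (named integer
#'   vector) and `truth_model`/`truth_scenario`.
#' @export
generate_observed_areas <- function(basins, sm_cube,
                                    historical_periods = default_historical_periods(),
                                    config) {
  stopifnot(inherits(basins, "basin_set"), inherits(sm_cube, "sm_cube"),
            inherits(config, "generator_config"))
  w <- .normalize_windows(historical_periods, sm_cube$times)
  yr0 <- floor(sm_cube$times[1]); yr1 <- floor(sm_cube$times[length(sm_cube$times)])
  if (any(w$start < yr0) || any(w$end > yr1))
    .stopf("historical period %s-%s outside the cube's year range %d-%d",
           min(w$start), max(w$end), yr0, yr1)
  set.seed(.stage_seed(config$seed, "obs"))
  truth_model <- sm_cube$models[1]
  truth_scenario <- sm_cube$scenarios[1]
  rows <- vector("list", length(basins$basins))
  for (i in seq_along(basins$basins)) {
    b <- basins$basins[[i]]
    s <- extract_sm_series(sm_cube, b$basin_id, truth_model, truth_scenario)
    sim <- simulate_area_series(b, basins$true_M[[b$basin_id]], s, w)
    area <- sim$area_km2
    if (config$obs_noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$obs_noise_cv^2))
      area <- area * rlnorm(length(area), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    rows[[i]] <- data.frame(basin_id = b$basin_id, label = sim$label,
                            start = sim$start, end = sim$end,
                            area_km2 = area, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_M") <- basins$true_M
  attr(out, "truth_model") <- truth_model
  attr(out, "truth_scenario") <- truth_scenario
  class(out) <- c("observed_areas", "data.frame")
  out
}

#' Generate labelled sample points over a categorical truth map
#'
#' Points are drawn uniformly over the cells of a categorical map. Each point
#' carries its reference label (the truth) and a mapped label that equals the
#' truth with probability `1 - label_error_rate` and is otherwise a uniformly
#' random *other* class; a 70/30 train/validation flag is assigned by a
#' seeded Bernoulli draw.
#'
#' @param truth_map character/factor vector of per-cell class labels (a
#'   flattened categorical map).
#' @param config a [generator_config] (`label_error_rate`, `seed`).
#' @param n_points number of sample points to draw.
#' @param train_frac probability a point lands in the training split.
#' @return data.frame with columns `point_id`, `cell`, `reference`, `mapped`,
#'   `split` (`"train"`/`"validation"`).
#' @export
generate_sample_points <- function(truth_map, config, n_points = 10000,
                                   train_frac = 0.7) {
  stopifnot(inherits(config, "generator_config"))
  truth_map <- as.character(truth_map)
  if (length(truth_map) == 0L) .stopf("truth_map is empty")
  classes <- sort(unique(truth_map))
  if (length(classes) < 2L && config$label_error_rate > 0)
    .stopf("invalid config: label_error_rate > 0 needs >= 2 map classes, found %d",
           length(classes))
  set.seed(.stage_seed(config$seed, "points"))
  cell <- sample.int(length(truth_map), n_points, replace = TRUE)
  reference <- truth_map[cell]
  mapped <- reference
  flip <- runif(n_points) < config$label_error_rate
  if (any(flip)) {
    mapped[flip] <- vapply(reference[flip], function(cl) {
      others <- classes[classes != cl]
      others[sample.int(length(others), 1L)]
    }, character(1))
  }
  split <- ifelse(runif(n_points) < train_frac, "train", "validation")
  data.frame(point_id = seq_len(n_points), cell = cell, reference = reference,
             mapped = mapped, split = split, stringsAsFactors = FALSE)
}
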