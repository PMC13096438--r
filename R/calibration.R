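# Per-basin calibration of the transmissivity-decay parameter M by
# exhaustive RMSE grid search over the integers 1..15.

#' RMSE between simulated and observed area series
#'
#' Series are aligned by their window `label` when both are data.frames
#' (misalignment is an error); bare numeric vectors of equal length are
#' compared positionally. NA observations are dropped pairwise.
#'
#' @param sim,obs `area_series`/data.frames with `label` and `area_km2`
#'   columns, or numeric vectors of equal length.
#' @return Root-mean-square error, km2.
#' @examples
#' rmse_areas(c(1, 2, 3), c(2, 2, 2))  # sqrt(2/3)
#' @export
rmse_areas <- function(sim, obs) {
  if (is.data.frame(sim) && is.data.frame(obs)) {
    if (nrow(sim) != nrow(obs) ||
        !setequal(sim$label, obs$label) ||
        anyDuplicated(sim$label) || anyDuplicated(obs$label))
      .stopf("simulated and observed series have misaligned windows")
    s <- sim$area_km2[order(sim$label)]
    o <- obs$area_km2[order(obs$label)]
  } else {
    s <- as.numeric(sim); o <- as.numeric(obs)
    if (length(s) != length(o))
      .stopf("series lengths differ (%d vs %d)", length(s), length(o))
  }
  if (length(s) == 0L) .stopf("empty series")
  keep <- !is.na(o) & !is.na(s)
  if (!any(keep)) .stopf("no non-missing observation pairs")
  sqrt(mean((s[keep] - o[keep])^2))
}

#' Calibrate M for a single basin
#'
#' Runs the forward model at every M in `m_grid` (default the integers
#' 1..15), computes the RMSE against the basin's observed areas over the
#' historical periods, and returns the minimising M. Ties are broken toward
#' the smallest M (deterministic and parsimonious: the weakest topographic
#' control). Periods with missing observations are dropped and the number
#' actually used is recorded.
#'
#' @param basin a [basin_record].
#' @param sm an [sm_series] covering the periods (the calibration-truth soil
#'   moisture).
#' @param obs data.frame with `label` and `area_km2` for this basin's
#'   observed periods.
#' @param periods period table (`start`, `end`, optional `label`).
#' @param m_grid candidate M values, integers within `[1, 15]`.
#' @return list with `basin_id`, `M`, `rmse_km2`, `n_periods_used`.
#' @export
calibrate_basin <- function(basin, sm, obs, periods = default_historical_periods(),
                            m_grid = 1:15) {
  stopifnot(inherits(basin, "basin_record"), inherits(sm, "sm_series"))
  if (any(m_grid < 1) || any(m_grid > 15))
    .stopf("m_grid must lie within [1, 15]")
  m_grid <- sort(unique(as.integer(m_grid)))
  w <- .normalize_windows(periods, sm$times)
  obs_use <- obs[match(w$label, obs$label), , drop = FALSE]
  keep <- !is.na(obs_use$area_km2)
  if (!any(keep))
    .stopf("basin '%s': all observations missing", basin$basin_id)
  best_M <- NA_integer_; best_rmse <- Inf
  for (M in m_grid) {
    sim <- simulate_area_series(basin, M, sm, w)
    r <- sqrt(mean((sim$area_km2[keep] - obs_use$area_km2[keep])^2))
    if (r < best_rmse) {  # strict < with ascending grid => smallest-M tie-break
      best_rmse <- r; best_M <- M
    }
  }
  list(basin_id = basin$basin_id, M = best_M, rmse_km2 = best_rmse,
       n_periods_used = sum(keep))
}

#' Fit the wetland diagnostic: calibrate M for every basin
#'
#' The model-fitting entry point. For each basin an exhaustive grid search
#' over M in 1..15 minimises the RMSE between forward-model wetland areas
#' (driven by the supplied historical soil moisture) and the observed areas
#' over the historical periods. Basins are independent, so the result does
#' not depend on their order; basins missing from `obs_table` are collected
#' in an exceptions table rather than failing the fit.
#'
#' @param basins a [basin_set], or a list of [basin_record].
#' @param sm_hist historical soil moisture: an `sm_cube` (the designated
#'   truth member/scenario is used, overridable via `model`/`scenario`), or a
#'   named list of [sm_series] keyed by basin id.
#' @param obs_table data.frame with `basin_id`, `label`, `area_km2` (e.g.
#'   from [generate_observed_areas()]).
#' @param periods period table (default [default_historical_periods()]).
#' @param m_grid candidate M values, integers within `[1, 15]`.
#' @param model,scenario which cube member supplies the calibration soil
#'   moisture when `sm_hist` is an `sm_cube`; defaults to the first (truth)
#'   member and first scenario.
#' @return Object of class `wetland_calibration`: list with `calibration`
#'   (data.frame `basin_id`, `M`, `rmse_km2`, `n_periods_used`), `basins`,
#'   `periods`, `obs`, `fitted` (forward-model areas at the chosen M),
#'   `exceptions` (basins without observations), `sm_meta`, `call`. Methods:
#'   `print`, `summary`, `coef` (named integer M), `fitted`, `residuals`,
#'   `predict` (ensemble projection), `plot`, `simulate`.
#' @examples
#' cfg <- generator_config(n_basins = 4, pixels_per_basin = 300,
#'                         n_models = 2, year_range = c(1984, 2021),
#'                         obs_noise_cv = 0, seed = 7)
#' bs <- generate_basins(cfg)
#' cube <- generate_sm_cube(bs, cfg)
#' obs <- generate_observed_areas(bs, cube, config = cfg)
#' fit <- calibrate_wetlands(bs, cube, obs)
#' coef(fit)
#' @export
calibrate_wetlands <- function(basins, sm_hist, obs_table,
                               periods = default_historical_periods(),
                               m_grid = 1:15, model = NULL, scenario = NULL) {
  cl <- match.call()
  blist <- if (inherits(basins, "basin_set")) basins$basins else basins
  if (length(blist) == 0L) .stopf("no basins to calibrate")
  ids <- vapply(blist, `[[`, character(1), "basin_id")
  names(blist) <- ids

  get_series <- function(id) {
    if (inherits(sm_hist, "sm_cube")) {
      extract_sm_series(sm_hist, id,
                        model = if (is.null(model)) sm_hist$models[1] else model,
                        scenario = if (is.null(scenario)) sm_hist$scenarios[1] else scenario)
    } else {
      s <- sm_hist[[id]]
      if (is.null(s)) .stopf("no soil-moisture series for basin '%s'", id)
      s
    }
  }
  sm_meta <- if (inherits(sm_hist, "sm_cube")) {
    list(model = if (is.null(model)) sm_hist$models[1] else model,
         scenario = if (is.null(scenario)) sm_hist$scenarios[1] else scenario)
  } else list(model = NA_character_, scenario = NA_character_)

  have_obs <- ids %in% obs_table$basin_id
  exceptions <- data.frame(basin_id = ids[!have_obs],
                           reason = if (any(!have_obs)) "no observations" else character(0),
                           stringsAsFactors = FALSE)

  rows <- vector("list", sum(have_obs))
  fitted_rows <- vector("list", sum(have_obs))
  k <- 0L
  for (id in ids[have_obs]) {
    k <- k + 1L
    b <- blist[[id]]
    s <- get_series(id)
    obs_b <- obs_table[obs_table$basin_id == id, c("label", "area_km2")]
    res <- calibrate_basin(b, s, obs_b, periods, m_grid)
    rows[[k]] <- as.data.frame(res, stringsAsFactors = FALSE)
    fitted_rows[[k]] <- simulate_area_series(b, res$M, s, periods)
  }
  calib <- do.call(rbind, rows)
  rownames(calib) <- NULL
  fitted <- do.call(rbind, fitted_rows)
  rownames(fitted) <- NULL

  structure(list(calibration = calib,
                 basins = blist,
                 periods = .normalize_windows(periods, NULL),
                 obs = obs_table,
                 fitted = fitted,
                 exceptions = exceptions,
                 sm_meta = sm_meta,
                 call = cl),
            class = "wetland_calibration")
}

#' @export
print.wetland_calibration <- function(x, ...) {
  cat("TOPMODEL wetland-extent calibration\n")
  cat(sprintf("  basins calibrated: %d (skipped: %d)\n",
              nrow(x$calibration), nrow(x$exceptions)))
  cat(sprintf("  periods: %d (%s .. %s)\n", nrow(x$periods),
              x$periods$label[1], x$periods$label[nrow(x$periods)]))
  cat(sprintf("  M: median %d, range %d-%d; median RMSE %.2f km2\n",
              as.integer(median(x$calibration$M)), min(x$calibration$M),
              max(x$calibration$M), median(x$calibration$rmse_km2)))
  invisible(x)
}

#' @export
summary.wetland_calibration <- function(object, ...) {
  out <- list(
    n_basins = nrow(object$calibration),
    n_skipped = nrow(object$exceptions),
    M_table = table(factor(object$calibration$M, levels = 1:15)),
    rmse_quantiles = quantile(object$calibration$rmse_km2,
                              c(0, 0.25, 0.5, 0.75, 1)),
    periods = object$periods$label)
  class(out) <- "summary.wetland_calibration"
  out
}

#' @export
print.summary.wetland_calibration <- function(x, ...) {
  cat("TOPMODEL wetland-extent calibration\n")
  cat(sprintf("  %d basins calibrated, %d skipped\n", x$n_basins, x$n_skipped))
  cat("  distribution of calibrated M (1..15):\n")
  print(x$M_table)
  cat("  RMSE quantiles (km2):\n")
  print(round(x$rmse_quantiles, 3))
  invisible(x)
}

#' @export
coef.wetland_calibration <- function(object, ...) {
  setNames(as.integer(object$calibration$M), object$calibration$basin_id)
}

#' @export
fitted.wetland_calibration <- function(object, ...) object$fitted

#' @rdname calibrate_wetlands
#' @param newdata an `sm_cube` to drive the calibrated model with (e.g. a
#'   multi-model scenario cube); passed to [project_wetlands()] together
#'   with the fit's basins and coefficients.
#' @param years,models,scenarios optional subsets, as in
#'   [project_wetlands()].
#' @export
predict.wetland_calibration <- function(object, newdata, years = NULL,
                                        models = NULL, scenarios = NULL, ...) {
  project_wetlands(object$basins, object, newdata, years = years,
                   models = models, scenarios = scenarios)
}

#' @rdname calibrate_wetlands
#' @param object a `wetland_calibration`.
#' @param ... unused.
#' @export
residuals.wetland_calibration <- function(object, ...) {
  m <- merge(object$fitted[, c("basin_id", "label", "area_km2")],
             object$obs[, c("basin_id", "label", "area_km2")],
             by = c("basin_id", "label"), suffixes = c("_fit", "_obs"))
  m$residual_km2 <- m$area_km2_fit - m$area_km2_obs
  m[order(m$basin_id, m$label), ]
}

#' @export
plot.wetland_calibration <- function(x, ...) {
  r <- residuals(x)
  plot(r$area_km2_obs, r$area_km2_fit,
       xlab = "observed wetland area (km2)",
       ylab = "fitted wetland area (km2)",
       main = "Calibrated forward model vs observations", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.wetland_calibration <- function(object, nsim = 1, seed = NULL,
                                         obs_noise_cv = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + obs_noise_cv^2))
  lapply(seq_len(nsim), function(i) {
    out <- object$fitted[, c("basin_id", "label", "start", "end", "area_km2")]
    if (obs_noise_cv > 0)
      out$area_km2 <- out$area_km2 *
        rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    out
  })
}
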