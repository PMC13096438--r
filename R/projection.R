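# Ensemble projection: apply calibrated M to multi-model multi-scenario
# soil-moisture cubes; ensemble means, net change, grid-cell agreement maps.

#' Project wetland areas under a model-scenario ensemble
#'
#' For every (model, scenario, basin, year): monthly soil moisture is averaged
#' to one annual mean first, then passed through the forward chain with the
#' basin's calibrated M. Requested models/scenarios missing from the cube are
#' skipped with a warning.
#'
#' @param basins a [basin_set] or list of [basin_record].
#' @param calib a `wetland_calibration` (or a data.frame with `basin_id`,
#'   `M`).
#' @param sm_cube an `sm_cube` covering the requested years.
#' @param years optional integer vector of years to project (default: all in
#'   the cube).
#' @param models,scenarios optional subsets (default: all in the cube).
#' @return Object of class `ensemble_area_cube`: list with `area` (4-d array
#'   `model x scenario x year x basin`, km2), `years`, `models`, `scenarios`,
#'   `basin_ids`, `basin_area_km2`, `M`.
#' @export
project_wetlands <- function(basins, calib, sm_cube, years = NULL,
                             models = NULL, scenarios = NULL) {
  stopifnot(inherits(sm_cube, "sm_cube"))
  blist <- if (inherits(basins, "basin_set")) basins$basins else basins
  ids <- vapply(blist, `[[`, character(1), "basin_id")
  names(blist) <- ids
  M <- if (inherits(calib, "wetland_calibration")) coef(calib)
       else setNames(as.integer(calib$M), calib$basin_id)
  miss <- setdiff(ids, names(M))
  if (length(miss) > 0L)
    .stopf("basin(s) not calibrated: %s", paste(miss, collapse = ", "))

  cube_years <- sort(unique(floor(sm_cube$times)))
  if (is.null(years)) years <- cube_years
  if (!all(years %in% cube_years))
    .stopf("requested years %s not covered by the cube",
           paste(setdiff(years, cube_years), collapse = ", "))
  use_models <- if (is.null(models)) sm_cube$models else models
  use_scen <- if (is.null(scenarios)) sm_cube$scenarios else scenarios
  drop_m <- setdiff(use_models, sm_cube$models)
  drop_s <- setdiff(use_scen, sm_cube$scenarios)
  if (length(drop_m) || length(drop_s)) {
    .warnf("skipping model/scenario absent from cube: %s",
           paste(c(drop_m, drop_s), collapse = ", "))
    use_models <- intersect(use_models, sm_cube$models)
    use_scen <- intersect(use_scen, sm_cube$scenarios)
  }
  if (!length(use_models) || !length(use_scen))
    .stopf("no model/scenario left to project")

  yr_of_t <- floor(sm_cube$times)
  sel_t <- yr_of_t %in% years
  yr_idx <- factor(yr_of_t[sel_t], levels = years)

  area <- array(NA_real_,
                dim = c(length(use_models), length(use_scen), length(years),
                        length(ids)),
                dimnames = list(model = use_models, scenario = use_scen,
                                year = as.character(years), basin = ids))
  for (id in ids) {
    b <- blist[[id]]
    cti_sorted <- sort(b$cti_values)
    n_px <- length(cti_sorted)
    for (m in use_models) {
      for (s in use_scen) {
        sm_ann <- tapply(sm_cube$values[m, s, sel_t, id], yr_idx, mean)
        wtd <- wtd_from_sm(as.numeric(sm_ann), sm_sat = sm_cube$sm_sat,
                           column_depth_m = sm_cube$column_depth_m)
        thr <- cti_threshold(b$cti_mean, M[[id]], wtd)
        f <- (n_px - findInterval(thr, cti_sorted, left.open = TRUE)) / n_px
        if (!is.null(b$f_max)) f <- pmin(f, b$f_max)
        area[m, s, , id] <- f * b$area_km2
      }
    }
  }
  structure(list(area = area, years = years, models = use_models,
                 scenarios = use_scen, basin_ids = ids,
                 basin_area_km2 = setNames(
                   vapply(blist, `[[`, numeric(1), "area_km2"), ids),
                 M = M[ids]),
            class = "ensemble_area_cube")
}

#' @export
print.ensemble_area_cube <- function(x, ...) {
  cat(sprintf(
    "Ensemble wetland-area cube: %d models x %d scenarios x %d years x %d basins\n",
    length(x$models), length(x$scenarios), length(x$years), length(x$basin_ids)))
  invisible(x)
}

#' Continental (all-basin) area series per model and scenario
#'
#' @param cube an `ensemble_area_cube`.
#' @return 3-d array `model x scenario x year`, km2 (sum over basins).
#' @export
continental_series <- function(cube) {
  stopifnot(inherits(cube, "ensemble_area_cube"))
  apply(cube$area, c(1, 2, 3), sum)
}

#' Ensemble-mean area series per scenario
#'
#' Unweighted arithmetic mean across ensemble members per (scenario, year).
#'
#' @param cube an `ensemble_area_cube`.
#' @param by_basin if `TRUE`, return the per-basin mean array
#'   `scenario x year x basin`; otherwise (default) the continental mean
#'   matrix `scenario x year`.
#' @return Matrix `scenario x year` (km2), or a 3-d array when
#'   `by_basin = TRUE`.
#' @export
ensemble_mean <- function(cube, by_basin = FALSE) {
  stopifnot(inherits(cube, "ensemble_area_cube"))
  if (by_basin) apply(cube$area, c(2, 3, 4), mean)
  else apply(continental_series(cube), c(2, 3), mean)
}

#' Net change of an area series between two years, percent
#'
#' `100 * (series[year1] - series[year0]) / series[year0]`.
#'
#' @param series numeric vector named by year (or an unnamed vector indexed
#'   by `year0`/`year1` positions).
#' @param year0,year1 base and end year (names into `series`).
#' @return Percent change (positive = gain).
#' @examples
#' net_change_pct(c(`1984` = 1200800, `2021` = 1194700), 1984, 2021)
#' @export
net_change_pct <- function(series, year0, year1) {
  pick <- function(y) {
    if (!is.null(names(series))) {
      if (!as.character(y) %in% names(series))
        .stopf("year %s not in series", format(y))
      series[[as.character(y)]]
    } else series[[y]]
  }
  a0 <- pick(year0); a1 <- pick(year1)
  if (!is.finite(a0) || a0 == 0)
    .stopf("undefined percent change: base-year area is %s", format(a0))
  100 * (a1 - a0) / a0
}

#' Assign basins to equal-angle grid cells by centroid
#'
#' Cells are `cell_deg` x `cell_deg`, anchored at integer degrees; a basin
#' belongs to the cell containing its centroid.
#'
#' @param basins a [basin_set] or list of [basin_record] with `lon`/`lat`.
#' @param cell_deg cell size in degrees (default 0.2).
#' @return data.frame `basin_id`, `cell_id`, `cell_lon_s`, `cell_lat_s`
#'   (south-west corner, degrees).
#' @export
assign_cells <- function(basins, cell_deg = 0.2) {
  blist <- if (inherits(basins, "basin_set")) basins$basins else basins
  ids <- vapply(blist, `[[`, character(1), "basin_id")
  lon <- vapply(blist, `[[`, numeric(1), "lon")
  lat <- vapply(blist, `[[`, numeric(1), "lat")
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    .stopf("basin centroids must be finite to assign grid cells")
  ix <- floor(lon / cell_deg); iy <- floor(lat / cell_deg)
  data.frame(basin_id = ids,
             cell_id = sprintf("c%+06d%+06d", as.integer(ix), as.integer(iy)),
             cell_lon_s = ix * cell_deg, cell_lat_s = iy * cell_deg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Model-agreement map of wetland change per grid cell
#'
#' Per cell and ensemble member, the net wetland-area change between two
#' years is classified as loss (`< -epsilon`), gain (`> +epsilon`) or
#' unchanged; the counts of members in each class are tallied. By default
#' `epsilon` is 1% of that member's initial wetland area in the cell.
#'
#' @param cube an `ensemble_area_cube`.
#' @param cell_assignment data.frame `basin_id`, `cell_id` (see
#'   [assign_cells()]). Basins without an assignment are reported in the
#'   result's `exceptions` attribute and excluded.
#' @param year0,year1 comparison years.
#' @param epsilon_km2 half-width of the "unchanged" band, km2; `NULL`
#'   (default) uses 1% of the member's initial cell area.
#' @param scenario scenario to evaluate (default: first in the cube).
#' @return data.frame of class `agreement_map` with `cell_id`, `n_loss`,
#'   `n_gain`, `n_unchanged`, `net_change_km2_mean`; attribute `net_change`
#'   holds the full per-cell x per-model net-change matrix.
#' @export
agreement_map <- function(cube, cell_assignment, year0, year1,
                          epsilon_km2 = NULL, scenario = cube$scenarios[1]) {
  stopifnot(inherits(cube, "ensemble_area_cube"))
  if (!is.null(epsilon_km2) && (!is.finite(epsilon_km2) || epsilon_km2 < 0))
    .stopf("epsilon_km2 must be >= 0")
  if (!scenario %in% cube$scenarios)
    .stopf("scenario '%s' not in cube", scenario)
  y0 <- as.character(year0); y1 <- as.character(year1)
  if (!all(c(y0, y1) %in% as.character(cube$years)))
    .stopf("years %s/%s not in cube", y0, y1)

  unassigned <- setdiff(cube$basin_ids, cell_assignment$basin_id)
  ca <- cell_assignment[cell_assignment$basin_id %in% cube$basin_ids, ]
  cells <- sort(unique(ca$cell_id))
  nm <- length(cube$models)

  a0 <- cube$area[, scenario, y0, ca$basin_id, drop = FALSE]
  a1 <- cube$area[, scenario, y1, ca$basin_id, drop = FALSE]
  # model x basin matrices
  d <- matrix(a1 - a0, nrow = nm,
              dimnames = list(cube$models, ca$basin_id))
  b0 <- matrix(a0, nrow = nm, dimnames = list(cube$models, ca$basin_id))
  cell_f <- factor(ca$cell_id, levels = cells)
  # per-cell x per-model sums
  net <- t(apply(d, 1, function(row) tapply(row, cell_f, sum)))
  init <- t(apply(b0, 1, function(row) tapply(row, cell_f, sum)))
  if (length(cells) == 1L) {  # tapply/t collapse guards
    net <- matrix(net, nrow = nm, dimnames = list(cube$models, cells))
    init <- matrix(init, nrow = nm, dimnames = list(cube$models, cells))
  }
  eps <- if (is.null(epsilon_km2)) 0.01 * init
         else matrix(epsilon_km2, nrow = nm, ncol = length(cells))
  is_loss <- net < -eps
  is_gain <- net > eps
  out <- data.frame(cell_id = cells,
                    n_loss = colSums(is_loss),
                    n_gain = colSums(is_gain),
                    n_unchanged = colSums(!is_loss & !is_gain),
                    net_change_km2_mean = colMeans(net),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "net_change") <- t(net)  # cells x models
  attr(out, "exceptions") <-
    data.frame(basin_id = unassigned,
               reason = if (length(unassigned)) "no cell assignment" else character(0),
               stringsAsFactors = FALSE)
  attr(out, "scenario") <- scenario
  class(out) <- c("agreement_map", "data.frame")
  out
}
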