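# Forward model: column soil moisture -> water-table depth -> CTI threshold
# -> saturated (wetland) fraction -> basin wetland area.

#' Basin record: area and empirical CTI distribution
#'
#' A basin is described by its land area and the empirical distribution of the
#' compound topographic index (CTI) over its pixels. The CTI mean anchors the
#' saturation threshold; the full pixel sample supplies the quantile function
#' that converts a threshold into a saturated fraction.
#'
#' @param basin_id identifier (coerced to character).
#' @param area_km2 basin land area, km2; must be positive.
#' @param cti_values numeric vector of CTI pixel values (dimensionless),
#'   non-empty, finite.
#' @param f_max optional cap on the wetland fraction, in (0, 1]. Default
#'   `NULL` (no cap).
#' @param lon,lat optional basin centroid, decimal degrees (used for grid-cell
#'   assignment in agreement maps).
#' @return An object of class `basin_record`: a list with fields `basin_id`,
#'   `area_km2`, `cti_values`, `cti_mean`, `f_max`, `lon`, `lat`.
#' @examples
#' b <- basin_record("b1", 100, c(5, 6, 7, 8, 9, 10))
#' b$cti_mean
#' @export
basin_record <- function(basin_id, area_km2, cti_values, f_max = NULL,
                         lon = NA_real_, lat = NA_real_) {
  if (length(area_km2) != 1L || !is.finite(area_km2) || area_km2 <= 0)
    .stopf("area_km2 must be a single positive number (basin '%s')", basin_id)
  if (length(cti_values) == 0L || !all(is.finite(cti_values)))
    .stopf("cti_values must be non-empty and finite (basin '%s')", basin_id)
  if (!is.null(f_max)) {
    if (length(f_max) != 1L || !is.finite(f_max) || f_max <= 0 || f_max > 1)
      .stopf("f_max must lie in (0, 1] (basin '%s')", basin_id)
  }
  structure(
    list(basin_id = as.character(basin_id),
         area_km2 = as.numeric(area_km2),
         cti_values = as.numeric(cti_values),
         cti_mean = mean(as.numeric(cti_values)),
         f_max = f_max,
         lon = as.numeric(lon), lat = as.numeric(lat)),
    class = "basin_record"
  )
}

#' @export
print.basin_record <- function(x, ...) {
  cat(sprintf("Basin '%s': %.1f km2, %d CTI pixels (mean %.3f)%s\n",
              x$basin_id, x$area_km2, length(x$cti_values), x$cti_mean,
              if (is.null(x$f_max)) "" else sprintf(", f_max %.2f", x$f_max)))
  invisible(x)
}

#' Basin-mean column soil-moisture series
#'
#' A time-indexed series of basin-mean soil moisture integrated over a soil
#' column (default 0-200 cm), in kg/m2, together with the column's saturation
#' value. Times are decimal years; monthly stamps use the month midpoint.
#'
#' @param times numeric vector of strictly increasing decimal years.
#' @param values soil moisture, kg/m2, each in `[0, sm_sat]`.
#' @param sm_sat column saturation, kg/m2, positive.
#' @param column_depth_m soil column depth, metres (default 2).
#' @return Object of class `sm_series`.
#' @examples
#' s <- sm_series(2000 + (1:12 - 0.5) / 12, rep(540, 12), sm_sat = 900)
#' @export
sm_series <- function(times, values, sm_sat, column_depth_m = 2) {
  if (length(sm_sat) != 1L || !is.finite(sm_sat) || sm_sat <= 0)
    .stopf("sm_sat must be a single positive number, got %s", format(sm_sat))
  if (length(column_depth_m) != 1L || !is.finite(column_depth_m) ||
      column_depth_m <= 0)
    .stopf("column_depth_m must be positive")
  if (length(times) != length(values))
    .stopf("times and values differ in length (%d vs %d)",
           length(times), length(values))
  if (length(values) == 0L) .stopf("empty soil-moisture series")
  if (is.unsorted(times, strictly = TRUE)) .stopf("times must be increasing")
  if (any(!is.finite(values)) || any(values < 0) || any(values > sm_sat))
    .stopf("soil moisture must lie in [0, sm_sat = %g]", sm_sat)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 sm_sat = as.numeric(sm_sat),
                 column_depth_m = as.numeric(column_depth_m)),
            class = "sm_series")
}

#' @export
print.sm_series <- function(x, ...) {
  cat(sprintf(
    "Soil-moisture series: %d steps, %.2f-%.2f, sm_sat %.1f kg/m2, %.1f m column\n",
    length(x$values), x$times[1], x$times[length(x$times)], x$sm_sat,
    x$column_depth_m))
  invisible(x)
}

#' Water-table depth from column soil moisture
#'
#' Saturation-deficit form: the water table sits at depth
#' `wtd = D * (1 - sm / sm_sat)` where `D` is the column depth. A saturated
#' column puts the water table at the surface (0 m); an empty column puts it
#' at the bottom of the column. Values are clipped to `[0, D]`.
#'
#' @param sm an [sm_series] object, or a numeric vector of soil moisture
#'   (kg/m2) if `sm_sat` is given.
#' @param sm_sat column saturation, kg/m2 (ignored when `sm` is an
#'   `sm_series`).
#' @param column_depth_m column depth, metres (ignored when `sm` is an
#'   `sm_series`).
#' @return Numeric vector of water-table depths, metres below surface,
#'   same length as the input series.
#' @examples
#' wtd_from_sm(c(0, 450, 900), sm_sat = 900)  # 2, 1, 0
#' @export
wtd_from_sm <- function(sm, sm_sat = NULL, column_depth_m = 2) {
  if (inherits(sm, "sm_series")) {
    values <- sm$values; sm_sat <- sm$sm_sat; column_depth_m <- sm$column_depth_m
  } else {
    values <- as.numeric(sm)
    if (is.null(sm_sat)) .stopf("sm_sat is required for a bare numeric series")
  }
  if (length(sm_sat) != 1L || !is.finite(sm_sat) || sm_sat <= 0)
    .stopf("sm_sat must be a single positive number, got %s", format(sm_sat))
  pmin(pmax(column_depth_m * (1 - values / sm_sat), 0), column_depth_m)
}

#' CTI saturation threshold from basin-mean CTI, M and water-table depth
#'
#' Exponential-transmissivity TOPMODEL relation: pixels with CTI at or above
#' `cti_star = cti_mean + M * wtd` are diagnosed saturated. Larger M or a
#' deeper water table raises the threshold and shrinks the saturated area.
#'
#' @param cti_mean basin-mean CTI (dimensionless).
#' @param M transmissivity-decay parameter, integer-valued in `[1, 15]`.
#' @param wtd_m water-table depth, metres, `>= 0`; may be a vector.
#' @return Threshold(s), dimensionless, same length as `wtd_m`.
#' @examples
#' cti_threshold(8, M = 10, wtd_m = 0.5)  # 13
#' @export
cti_threshold <- function(cti_mean, M, wtd_m) {
  if (length(M) != 1L || !is.finite(M) || M < 1 || M > 15 ||
      abs(M - round(M)) > 1e-9)
    .stopf("M must be a single integer in [1, 15], got %s", format(M))
  if (any(!is.finite(wtd_m)) || any(wtd_m < 0))
    .stopf("wtd_m must be finite and >= 0")
  cti_mean + M * wtd_m
}

#' Saturated (wetland) fraction of a basin at a CTI threshold
#'
#' The fraction of basin pixels whose CTI is at or above the threshold
#' (inclusive: a pixel exactly at the threshold counts as saturated), capped
#' at the basin's `f_max` if one is set.
#'
#' @param basin a [basin_record], or a bare numeric vector of CTI pixel
#'   values (then no cap applies).
#' @param cti_star threshold(s), dimensionless; may be a vector.
#' @return Fraction(s) in `[0, 1]`, same length as `cti_star`.
#' @examples
#' wetland_fraction(basin_record("b", 10, 5:10), cti_star = 8)  # 0.5
#' @export
wetland_fraction <- function(basin, cti_star) {
  if (inherits(basin, "basin_record")) {
    cti <- basin$cti_values; f_max <- basin$f_max
  } else {
    cti <- as.numeric(basin); f_max <- NULL
    if (length(cti) == 0L) .stopf("empty CTI pixel set")
  }
  n <- length(cti)
  # count of pixels >= t  ==  n - count of pixels < t, exact under ties
  f <- (n - findInterval(cti_star, sort(cti), left.open = TRUE)) / n
  if (!is.null(f_max)) f <- pmin(f, f_max)
  f
}

#' Basin wetland area from a saturated fraction
#'
#' @param basin a [basin_record] (or a single positive area in km2).
#' @param f saturated fraction(s) in `[0, 1]`.
#' @return Wetland area(s), km2.
#' @examples
#' basin_wetland_area(basin_record("b", 100, 5:10), f = 0.5)  # 50
#' @export
basin_wetland_area <- function(basin, f) {
  area <- if (inherits(basin, "basin_record")) basin$area_km2 else as.numeric(basin)
  if (length(area) != 1L || !is.finite(area) || area <= 0)
    .stopf("basin area must be a single positive number")
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    .stopf("wetland fraction must lie in [0, 1]")
  f * area
}

# Normalise an aggregation argument into a data.frame(label, start, end).
# "annual" expands to one window per calendar year present in `times`;
# otherwise accept a data.frame with start/end (label optional) or a list of
# length-2 numeric vectors.
#' @noRd
.normalize_windows <- function(aggregation, times) {
  if (identical(aggregation, "annual")) {
    yrs <- sort(unique(floor(times)))
    return(data.frame(label = as.character(yrs), start = yrs, end = yrs,
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(aggregation)) {
    w <- aggregation
    if (!all(c("start", "end") %in% names(w)))
      .stopf("period table must have 'start' and 'end' columns")
    if (is.null(w$label))
      w$label <- sprintf("%d-%d", as.integer(w$start), as.integer(w$end))
  } else if (is.list(aggregation)) {
    w <- data.frame(
      start = vapply(aggregation, function(p) p[[1]], numeric(1)),
      end = vapply(aggregation, function(p) p[[2]], numeric(1)))
    w$label <- sprintf("%d-%d", as.integer(w$start), as.integer(w$end))
  } else {
    .stopf("aggregation must be \"annual\", a period data.frame, or a list of year pairs")
  }
  if (any(w$end < w$start)) .stopf("period end before start")
  w[, c("label", "start", "end")]
}

#' Simulate a basin wetland-area series
#'
#' Composes the forward chain per aggregation window: the soil-moisture series
#' is averaged over the window first, then mapped through water-table depth,
#' CTI threshold and saturated fraction to one wetland area per window
#' (window-mean first, because calibration compares against one observed map
#' per period).
#'
#' @param basin a [basin_record].
#' @param M transmissivity-decay parameter, integer in `[1, 15]`.
#' @param sm an [sm_series].
#' @param aggregation `"annual"` (default), a data.frame with columns
#'   `start`, `end` (years, inclusive) and optionally `label`, or a list of
#'   `c(start, end)` year pairs.
#' @return A data.frame of class `area_series` with columns `basin_id`,
#'   `label`, `start`, `end`, `sm_mean`, `wtd_m`, `area_km2`.
#' @examples
#' b <- basin_record("b", 100, rgamma(500, 4, scale = 2))
#' s <- sm_series(1984 + (seq_len(24) - 0.5) / 12,
#'                rep(540, 24), sm_sat = 900)
#' simulate_area_series(b, M = 7, s)
#' @export
simulate_area_series <- function(basin, M, sm, aggregation = "annual") {
  stopifnot(inherits(basin, "basin_record"), inherits(sm, "sm_series"))
  w <- .normalize_windows(aggregation, sm$times)
  yr <- floor(sm$times)
  sm_mean <- vapply(seq_len(nrow(w)), function(i) {
    sel <- yr >= w$start[i] & yr <= w$end[i]
    if (!any(sel))
      .stopf("window %s-%s contains no soil-moisture samples",
             format(w$start[i]), format(w$end[i]))
    mean(sm$values[sel])
  }, numeric(1))
  wtd <- wtd_from_sm(sm_mean, sm_sat = sm$sm_sat,
                     column_depth_m = sm$column_depth_m)
  f <- wetland_fraction(basin, cti_threshold(basin$cti_mean, M, wtd))
  out <- data.frame(basin_id = basin$basin_id, label = w$label,
                    start = w$start, end = w$end, sm_mean = sm_mean,
                    wtd_m = wtd, area_km2 = basin_wetland_area(basin, f),
                    stringsAsFactors = FALSE)
  class(out) <- c("area_series", "data.frame")
  out
}
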