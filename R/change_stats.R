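# Descriptive machinery: gross/net change accounting, Mann-Kendall and
# linear trends, equal-angle grid-cell areas, zonal driver series, and
# confusion-matrix map-accuracy assessment.

#' Gross/net wetland change ledger between two dates
#'
#' Per-unit (basin, cell or class) area differences are partitioned into
#' gross loss (the negative differences) and gross gain (the positive ones);
#' net change is their difference, and the percent change is reported against
#' the total base-date area. Exposing gross and net separately lets either
#' reading of "change" be reproduced.
#'
#' @param area_t0,area_t1 non-negative numeric vectors of per-unit areas
#'   (km2) at the base and end date; aligned by name when both are named,
#'   positionally otherwise.
#' @return Object of class `change_ledger`: list with `gross_loss_km2`,
#'   `gross_gain_km2`, `net_change_km2`, `base_area_km2`, `pct_change`.
#' @examples
#' # one unit losing 138,500 km2 and one gaining 132,400 km2
#' change_ledger(c(500000, 700800), c(500000 - 138500, 700800 + 132400))
#' @export
change_ledger <- function(area_t0, area_t1) {
  a0 <- as.numeric(area_t0); a1 <- as.numeric(area_t1)
  if (!is.null(names(area_t0)) && !is.null(names(area_t1))) {
    if (!setequal(names(area_t0), names(area_t1)))
      .stopf("area tables cover different units")
    a1 <- a1[match(names(area_t0), names(area_t1))]
  }
  if (length(a0) != length(a1))
    .stopf("area tables differ in length (%d vs %d)", length(a0), length(a1))
  if (any(!is.finite(a0)) || any(!is.finite(a1)) || any(a0 < 0) || any(a1 < 0))
    .stopf("areas must be finite and non-negative")
  d <- a1 - a0
  gross_loss <- -sum(d[d < 0])
  gross_gain <- sum(d[d > 0])
  base <- sum(a0)
  net <- gross_gain - gross_loss
  structure(list(gross_loss_km2 = gross_loss,
                 gross_gain_km2 = gross_gain,
                 net_change_km2 = net,
                 base_area_km2 = base,
                 pct_change = if (base > 0) 100 * net / base else NA_real_),
            class = "change_ledger")
}

#' @export
print.change_ledger <- function(x, ...) {
  cat(sprintf(paste0(
    "Change ledger: gross loss %.1f km2, gross gain %.1f km2,\n",
    "  net %+.1f km2 on a base of %.1f km2 (%+.2f%%)\n"),
    x$gross_loss_km2, x$gross_gain_km2, x$net_change_km2,
    x$base_area_km2, x$pct_change))
  invisible(x)
}

#' Mann-Kendall nonparametric trend test
#'
#' `S = sum over i < j of sign(x_j - x_i)`; the variance uses the standard
#' tie correction, Z applies the +-1 continuity correction, and the p-value
#' is two-sided normal. An all-tied series returns `S = 0`, `Z = 0`, `p = 1`.
#'
#' @param x numeric series, length >= 3.
#' @return Object of class `trend_test`: list with `S` (integer), `Z`,
#'   `p_two_sided`, `var_S`, `n`.
#' @examples
#' mann_kendall(c(1, 3, 2, 4, 6, 5, 7, 9, 8, 10))
#' @export
mann_kendall <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) .stopf("Mann-Kendall needs a series of length >= 3")
  if (any(!is.finite(x))) .stopf("series must be finite")
  n <- length(x)
  sgn <- sign(outer(x, x, "-"))
  S <- sum(sgn[lower.tri(sgn)])  # sign(x_j - x_i) for i < j
  ties <- table(x)
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_S <= 0) {  # all observations tied
    Z <- 0; p <- 1
  } else if (S > 0) {
    Z <- (S - 1) / sqrt(var_S); p <- 2 * pnorm(-abs(Z))
  } else if (S < 0) {
    Z <- (S + 1) / sqrt(var_S); p <- 2 * pnorm(-abs(Z))
  } else {
    Z <- 0; p <- 1
  }
  structure(list(S = as.integer(S), Z = Z, p_two_sided = p,
                 var_S = var_S, n = n),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  if (!is.null(x$S))
    cat(sprintf("Mann-Kendall: S = %d, Z = %.3f, two-sided p = %.4f (n = %d)\n",
                x$S, x$Z, x$p_two_sided, x$n))
  if (!is.null(x$slope))
    cat(sprintf("Linear fit: slope = %.4g, intercept = %.4g, R2 = %.3f (n = %d)\n",
                x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' One-dimensional linear trend fit
#'
#' Ordinary least squares of the series on its time index; `r_squared` is the
#' squared Pearson correlation between series and time.
#'
#' @param x numeric series, length >= 2.
#' @param t time index (default `seq_along(x)`).
#' @return Object of class `trend_test`: list with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @examples
#' linear_trend(2 * (1:10) + 1)
#' @export
linear_trend <- function(x, t = seq_along(x)) {
  x <- as.numeric(x); t <- as.numeric(t)
  if (length(x) < 2L) .stopf("linear trend needs a series of length >= 2")
  if (length(t) != length(x)) .stopf("time index length mismatch")
  if (sd(t) == 0) .stopf("degenerate input: time index has zero variance")
  fit <- lm(x ~ t)
  r2 <- if (sd(x) == 0) 1 else cor(x, t)^2  # flat series: fit is exact
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n = length(x)),
            class = "trend_test")
}

#' Area of an equal-angle grid cell, km2
#'
#' Spherical band formula `A = R^2 * dlambda * (sin(lat_n) - sin(lat_s))`
#' with R = 6371 km, for a `cell_deg x cell_deg` cell whose southern edge is
#' at `lat_south`.
#'
#' @param lat_south southern edge latitude, degrees; the cell must fit in
#'   `[-90, 90]`. Vectorised.
#' @param cell_deg cell size, degrees (default 0.2).
#' @return Cell area(s), km2.
#' @examples
#' grid_cell_area(0)  # ~494.6 km2 at the equator
#' @export
grid_cell_area <- function(lat_south, cell_deg = 0.2) {
  if (any(!is.finite(lat_south)) || any(lat_south < -90) ||
      any(lat_south + cell_deg > 90 + 1e-9))
    .stopf("cell must fit within [-90, 90] degrees latitude")
  rad <- pi / 180
  .EARTH_RADIUS_KM^2 * (cell_deg * rad) *
    (sin((lat_south + cell_deg) * rad) - sin(lat_south * rad))
}

#' Zonal mean series of a driver field, with correlation to an area series
#'
#' Averages a gridded driver (one column per time window) over a spatial
#' mask, and, when an area series is supplied, reports the Pearson
#' correlation between the zonal-mean series and that series.
#'
#' @param driver numeric matrix, cells x windows.
#' @param mask logical vector over cells (the wetland distribution zone).
#' @param area_series optional numeric series, one value per window.
#' @return list with `mean_series` (length = number of windows) and
#'   `pearson_r` (`NA` when no area series is given).
#' @export
zonal_driver_series <- function(driver, mask, area_series = NULL) {
  driver <- as.matrix(driver)
  mask <- as.logical(mask)
  if (length(mask) != nrow(driver))
    .stopf("mask length (%d) does not match driver cells (%d)",
           length(mask), nrow(driver))
  if (!any(mask)) .stopf("empty mask: no cells to average")
  mean_series <- colMeans(driver[mask, , drop = FALSE])
  r <- NA_real_
  if (!is.null(area_series)) {
    if (length(area_series) != ncol(driver))
      .stopf("area series length (%d) does not match driver windows (%d)",
             length(area_series), ncol(driver))
    r <- cor(mean_series, as.numeric(area_series))
  }
  list(mean_series = unname(mean_series), pearson_r = r)
}

#' Map-accuracy assessment from labelled sample points
#'
#' Cross-tabulates reference labels (rows) against mapped labels (columns)
#' over the validation split only, and reports producer's accuracy (per-class
#' recall, reference-conditioned), user's accuracy (per-class precision,
#' map-conditioned) and overall accuracy, in percent.
#'
#' @param samples data.frame with `reference` and `mapped` columns and,
#'   optionally, a `split` column (only `"validation"` rows are used when it
#'   is present).
#' @param validation_only use only the validation split when a `split`
#'   column exists (default `TRUE`).
#' @return Object of class `confusion_matrix`: list with `classes`, `counts`
#'   (reference x mapped), `producer_accuracy`, `user_accuracy` (percent,
#'   per class), `overall_accuracy` (percent), `n`.
#' @examples
#' s <- data.frame(reference = c("w", "w", "u"), mapped = c("w", "u", "u"))
#' accuracy_assessment(s)
#' @export
accuracy_assessment <- function(samples, validation_only = TRUE) {
  if (!all(c("reference", "mapped") %in% names(samples)))
    .stopf("samples must have 'reference' and 'mapped' columns")
  if (validation_only && "split" %in% names(samples))
    samples <- samples[samples$split == "validation", , drop = FALSE]
  if (nrow(samples) == 0L) .stopf("no validation samples")
  classes <- sort(unique(c(samples$reference, samples$mapped)))
  counts <- table(factor(samples$reference, levels = classes),
                  factor(samples$mapped, levels = classes))
  counts <- unclass(counts)
  dimnames(counts) <- list(reference = classes, mapped = classes)
  diagc <- diag(counts)
  row_s <- rowSums(counts); col_s <- colSums(counts)
  pa <- ifelse(row_s > 0, 100 * diagc / row_s, NA_real_)
  ua <- ifelse(col_s > 0, 100 * diagc / col_s, NA_real_)
  structure(list(classes = classes, counts = counts,
                 producer_accuracy = setNames(pa, classes),
                 user_accuracy = setNames(ua, classes),
                 overall_accuracy = 100 * sum(diagc) / sum(counts),
                 n = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (%d validation points; rows = reference):\n", x$n))
  print(x$counts)
  cat("Producer's accuracy (%):\n"); print(round(x$producer_accuracy, 2))
  cat("User's accuracy (%):\n"); print(round(x$user_accuracy, 2))
  cat(sprintf("Overall accuracy: %.2f%%\n", x$overall_accuracy))
  invisible(x)
}
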