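# File formats: headered long-format CSV for the soil-moisture cube, plain
# CSVs for basins, areas, calibrations and sample points. Headers carry
# units and provenance as '#key: value' comment lines; numeric columns are
# written at full precision so cubes round-trip bit-identically.

#' @noRd
.write_headered_csv <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("#", h), con)
  is_num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(is_num)) out[[j]] <- sprintf("%.17g", df[[j]])
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

#' @noRd
.read_headered_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    kv <- regmatches(h, regexec("^#([^:]+): ?(.*)$", h))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- kv[3]
  }
  df <- read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                              collapse = "\n"),
                 stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Write a soil-moisture cube to headered CSV
#'
#' Long format (`model, scenario, time, basin_id, sm`) with `#`-prefixed
#' header lines recording units, saturation and column depth. Values are
#' written at full double precision, so [read_sm_cube()] reproduces the cube
#' bit-identically.
#'
#' @param cube an `sm_cube`.
#' @param path output file path.
#' @param extra_header optional extra `"key: value"` header lines (e.g. run
#'   provenance).
#' @return `path`, invisibly.
#' @export
write_sm_cube <- function(cube, path, extra_header = character(0)) {
  stopifnot(inherits(cube, "sm_cube"))
  grid <- expand.grid(model = cube$models, scenario = cube$scenarios,
                      ti = seq_along(cube$times), basin_id = cube$basin_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- data.frame(model = grid$model, scenario = grid$scenario,
                   time = cube$times[grid$ti], basin_id = grid$basin_id,
                   sm = as.numeric(cube$values[cbind(
                     match(grid$model, cube$models),
                     match(grid$scenario, cube$scenarios),
                     grid$ti,
                     match(grid$basin_id, cube$basin_ids))]),
                   stringsAsFactors = FALSE)
  .write_headered_csv(df, path, c(
    "topwet_sm_cube: v1",
    "units: kg/m2",
    sprintf("sm_sat: %.17g", cube$sm_sat),
    sprintf("column_depth_m: %.17g", cube$column_depth_m),
    extra_header))
  invisible(path)
}

#' Read a soil-moisture cube from headered CSV
#'
#' Validates units (must be kg/m2 — anything else is a hard error quoting
#' the offending attribute) and value range. A file without a `scenario`
#' column is promoted to a single-scenario cube with a warning; negative
#' soil-moisture values are a validation error naming the first offending
#' row.
#'
#' @param path file written by [write_sm_cube()] (or matching its layout).
#' @return An `sm_cube`.
#' @export
read_sm_cube <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- .read_headered_csv(path)
  meta <- attr(df, "meta")
  units <- meta[["units"]]
  if (is.null(units) || units != "kg/m2")
    .stopf("soil-moisture units must be kg/m2; file declares 'units: %s'",
           if (is.null(units)) "<missing>" else units)
  if (is.null(meta[["sm_sat"]])) .stopf("header is missing 'sm_sat'")
  sm_sat <- as.numeric(meta[["sm_sat"]])
  depth <- if (is.null(meta[["column_depth_m"]])) 2
           else as.numeric(meta[["column_depth_m"]])
  need <- c("model", "time", "basin_id", "sm")
  if (!all(need %in% names(df)))
    .stopf("cube file lacks column(s): %s",
           paste(setdiff(need, names(df)), collapse = ", "))
  if (!"scenario" %in% names(df)) {
    .warnf("no 'scenario' column: promoting to a single unnamed scenario")
    df$scenario <- "scenario1"
  }
  bad <- which(!is.finite(df$sm) | df$sm < 0)
  if (length(bad))
    .stopf("invalid soil moisture at data row %d (value %s)",
           bad[1], format(df$sm[bad[1]]))
  if (any(df$sm > sm_sat))
    .stopf("soil moisture exceeds sm_sat = %g", sm_sat)

  models <- unique(df$model); scens <- unique(df$scenario)
  times <- sort(unique(df$time)); basins <- unique(df$basin_id)
  vals <- array(NA_real_,
                dim = c(length(models), length(scens), length(times),
                        length(basins)),
                dimnames = list(model = models, scenario = scens,
                                time = NULL, basin = basins))
  vals[cbind(match(df$model, models), match(df$scenario, scens),
             match(df$time, times), match(df$basin_id, basins))] <- df$sm
  if (any(is.na(vals))) .warnf("cube has missing (model, scenario, time, basin) cells")
  structure(list(values = vals, times = times, sm_sat = sm_sat,
                 column_depth_m = depth, models = models, scenarios = scens,
                 basin_ids = basins, model_params = NULL),
            class = "sm_cube")
}

#' Write a basin set to CSV (summary + CTI pixels)
#'
#' @param basins a [basin_set].
#' @param path summary CSV path (`basin_id, area_km2, cti_mean, lon, lat,
#'   true_M`).
#' @param pixels_path optional CSV path for the per-basin CTI pixel values
#'   (`basin_id, cti`).
#' @param extra_header optional header lines.
#' @return `path`, invisibly.
#' @export
write_basins <- function(basins, path, pixels_path = NULL,
                         extra_header = character(0)) {
  stopifnot(inherits(basins, "basin_set"))
  .write_headered_csv(as.data.frame(basins), path,
                      c("topwet_basins: v1", extra_header))
  if (!is.null(pixels_path)) {
    px <- data.frame(
      basin_id = rep(names(basins$basins),
                     vapply(basins$basins, function(b) length(b$cti_values),
                            integer(1))),
      cti = unlist(lapply(basins$basins, `[[`, "cti_values"), use.names = FALSE),
      stringsAsFactors = FALSE)
    .write_headered_csv(px, pixels_path, c("topwet_cti_pixels: v1", extra_header))
  }
  invisible(path)
}

#' Read a basin set from CSV
#'
#' @param path summary CSV written by [write_basins()].
#' @param pixels_path CSV of per-basin CTI pixels (`basin_id, cti`); required
#'   to rebuild the empirical CTI distributions.
#' @return A [basin_set] (the `config` field is `NULL`; `true_M` is carried
#'   over when present in the file).
#' @export
read_basins <- function(path, pixels_path) {
  df <- .read_headered_csv(path)
  px <- .read_headered_csv(pixels_path)
  basins <- lapply(seq_len(nrow(df)), function(i) {
    basin_record(df$basin_id[i], df$area_km2[i],
                 px$cti[px$basin_id == df$basin_id[i]],
                 lon = if ("lon" %in% names(df)) df$lon[i] else NA_real_,
                 lat = if ("lat" %in% names(df)) df$lat[i] else NA_real_)
  })
  names(basins) <- df$basin_id
  true_M <- if ("true_M" %in% names(df))
    setNames(as.integer(df$true_M), df$basin_id)
  else setNames(rep(NA_integer_, nrow(df)), df$basin_id)
  structure(list(basins = basins, true_M = true_M, config = NULL),
            class = "basin_set")
}
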