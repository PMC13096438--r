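# Ensemble projection, ensemble means, net change, agreement maps.

make_toy_projection <- function(...) {
  cfg <- tiny_config(...)
  bs <- generate_basins(cfg)
  cube <- generate_sm_cube(bs, cfg)
  obs <- generate_observed_areas(bs, cube, config = cfg)
  fit <- calibrate_wetlands(bs, cube, obs)
  list(cfg = cfg, bs = bs, cube = cube, fit = fit,
       proj = project_wetlands(bs, fit, cube))
}

test_that("constant soil moisture projects a flat series with zero net change", {
  cfg <- tiny_config(n_basins = 2, n_models = 2,
                     sm_trend_frac_per_decade = 0, sm_seasonal_amp_frac = 0,
                     sm_noise_sd_frac = 0, obs_noise_cv = 0,
                     year_range = c(2000, 2020))
  bs <- generate_basins(cfg)
  cube <- generate_sm_cube(bs, cfg)
  obs <- generate_observed_areas(
    bs, cube, data.frame(start = c(2000, 2005), end = c(2004, 2009)), cfg)
  fit <- calibrate_wetlands(bs, cube, obs,
                            data.frame(start = c(2000, 2005),
                                       end = c(2004, 2009)))
  proj <- project_wetlands(bs, fit, cube)
  cont <- continental_series(proj)
  for (m in proj$models) for (s in proj$scenarios)
    expect_equal(unname(diff(cont[m, s, ])), rep(0, length(proj$years) - 1))
  em <- ensemble_mean(proj)
  expect_equal(net_change_pct(em[1, ], 2000, 2020), 0)
})

test_that("projection equals per-basin hand calculation on a 2-basin 2-year toy", {
  set.seed(5)
  b1 <- basin_record("x1", 200, rgamma(150, 4, scale = 2))
  b2 <- basin_record("x2", 900, rgamma(150, 5, scale = 1.5))
  cfg <- tiny_config(n_basins = 2, n_models = 2, year_range = c(2020, 2021))
  bs <- generate_basins(cfg)  # template for cube layout only
  bs$basins <- list(x1 = b1, x2 = b2); bs$true_M <- c(x1 = 4L, x2 = 9L)
  cube <- generate_sm_cube(bs, cfg)
  calib <- data.frame(basin_id = c("x1", "x2"), M = c(4L, 9L))
  proj <- project_wetlands(bs, calib, cube)
  for (m in proj$models) for (s in proj$scenarios) for (b in list(b1, b2)) {
    yr <- factor(floor(cube$times))
    ann <- tapply(cube$values[m, s, , b$basin_id], yr, mean)
    want <- vapply(as.numeric(ann), function(a) {
      wtd <- cfg$column_depth_m * (1 - a / cfg$sm_sat)
      oracle_fraction(b$cti_values,
                      b$cti_mean + bs$true_M[[b$basin_id]] * wtd) * b$area_km2
    }, numeric(1))
    expect_equal(unname(proj$area[m, s, , b$basin_id]), unname(want))
  }
  # continental = sum of the two basins
  cont <- continental_series(proj)
  expect_equal(cont[1, 1, ],
               proj$area[1, 1, , "x1"] + proj$area[1, 1, , "x2"])
})

test_that("positive SM trends in all members give nondecreasing continental areas", {
  tp <- make_toy_projection(n_basins = 3, n_models = 3, sm_noise_sd_frac = 0,
                            sm_trend_frac_per_decade = c(0.01, 0.02, 0.03, 0.04),
                            year_range = c(1984, 2050))
  cont <- continental_series(tp$proj)
  for (m in tp$proj$models) for (s in tp$proj$scenarios)
    expect_true(all(diff(cont[m, s, ]) >= -1e-9))
})

test_that("ensemble mean is the unweighted member average", {
  tp <- make_toy_projection(n_basins = 3, n_models = 4)
  cont <- continental_series(tp$proj)
  em <- ensemble_mean(tp$proj)
  # independent recomputation through a second code path
  for (s in tp$proj$scenarios) {
    want <- rep(0, length(tp$proj$years))
    for (m in tp$proj$models) want <- want + cont[m, s, ]
    expect_equal(unname(em[s, ]), unname(want / length(tp$proj$models)))
  }
  # two identical members -> mean equals either
  a2 <- tp$proj
  a2$area <- a2$area[c(1, 1), , , , drop = FALSE]
  a2$models <- c("m1", "m2"); dimnames(a2$area)[[1]] <- a2$models
  em2 <- ensemble_mean(a2)
  expect_equal(unname(em2[1, ]), unname(continental_series(a2)[1, 1, ]))
})

test_that("net change percent follows its definition and guards a zero base", {
  expect_equal(net_change_pct(c(`2000` = 100, `2010` = 110), 2000, 2010), 10)
  expect_equal(net_change_pct(c(`2000` = 5, `2010` = 5), 2000, 2010), 0)
  expect_equal(round(net_change_pct(c(`1984` = 1200800,
                                      `2021` = 1200800 - 6100), 1984, 2021), 2),
               -0.51)
  expect_error(net_change_pct(c(`2000` = 0, `2010` = 5), 2000, 2010),
               "undefined percent")
  expect_error(net_change_pct(c(`2000` = 1, `2010` = 5), 1999, 2010),
               "not in series")
})

test_that("agreement counts match a brute-force per-model reclassification", {
  tp <- make_toy_projection(n_basins = 8, n_models = 5, seed = 31L)
  cells <- assign_cells(tp$bs)
  y0 <- tp$proj$years[1]; y1 <- tp$proj$years[length(tp$proj$years)]
  eps <- 0.5
  am <- agreement_map(tp$proj, cells, y0, y1, epsilon_km2 = eps)
  for (cell in am$cell_id) {
    ids <- cells$basin_id[cells$cell_id == cell]
    n_loss <- n_gain <- n_unch <- 0L
    for (m in tp$proj$models) {
      net <- 0
      for (id in ids)
        net <- net + tp$proj$area[m, 1, as.character(y1), id] -
          tp$proj$area[m, 1, as.character(y0), id]
      if (net < -eps) n_loss <- n_loss + 1L
      else if (net > eps) n_gain <- n_gain + 1L
      else n_unch <- n_unch + 1L
    }
    row <- am[am$cell_id == cell, ]
    expect_equal(row$n_loss, n_loss)
    expect_equal(row$n_gain, n_gain)
    expect_equal(row$n_unchanged, n_unch)
  }
})

test_that("agreement counts always sum to the member count, and a huge band freezes all cells", {
  tp <- make_toy_projection(n_basins = 10, n_models = 6, seed = 37L)
  cells <- assign_cells(tp$bs)
  y0 <- tp$proj$years[1]; y1 <- tp$proj$years[length(tp$proj$years)]
  am <- agreement_map(tp$proj, cells, y0, y1)
  expect_true(all(am$n_loss + am$n_gain + am$n_unchanged == 6))
  am_inf <- agreement_map(tp$proj, cells, y0, y1, epsilon_km2 = 1e12)
  expect_true(all(am_inf$n_unchanged == 6))
  # strong uniform gain -> every member classified as gain
  cfg <- tiny_config(n_basins = 4, n_models = 3, sm_noise_sd_frac = 0,
                     sm_trend_frac_per_decade = 0.05,
                     year_range = c(2000, 2050))
  bs <- generate_basins(cfg)
  cube <- generate_sm_cube(bs, cfg)
  calib <- data.frame(basin_id = names(bs$basins),
                      M = unname(bs$true_M))
  proj <- project_wetlands(bs, calib, cube)
  am_gain <- agreement_map(proj, assign_cells(bs), 2000, 2050,
                           epsilon_km2 = 0.01)
  expect_true(all(am_gain$n_gain == 3))
  expect_true(all(am_gain$n_loss == 0))
})

test_that("continental net change equals the sum of cell net changes", {
  tp <- make_toy_projection(n_basins = 9, n_models = 4, seed = 41L)
  cells <- assign_cells(tp$bs)
  y0 <- tp$proj$years[1]; y1 <- tp$proj$years[length(tp$proj$years)]
  am <- agreement_map(tp$proj, cells, y0, y1)
  net_mat <- attr(am, "net_change")  # cells x models
  cont <- continental_series(tp$proj)
  for (m in tp$proj$models)
    expect_equal(sum(net_mat[, m]),
                 cont[m, 1, as.character(y1)] - cont[m, 1, as.character(y0)])
})

test_that("unassigned basins are reported, missing members skipped with warning", {
  tp <- make_toy_projection(n_basins = 4, n_models = 2)
  cells <- assign_cells(tp$bs)
  cells_cut <- cells[-1, ]
  am <- agreement_map(tp$proj, cells_cut, tp$proj$years[1],
                      tp$proj$years[length(tp$proj$years)])
  expect_equal(attr(am, "exceptions")$basin_id, cells$basin_id[1])
  expect_warning(
    project_wetlands(tp$bs, tp$fit, tp$cube, models = c("model01", "nope")),
    "skipping")
  expect_error(project_wetlands(tp$bs, tp$fit, tp$cube, years = 1900),
               "not covered")
})

test_that("ordered scenario trends order end-of-century ensemble-mean areas", {
  cfg <- tiny_config(n_basins = 6, n_models = 6,
                     sm_trend_frac_per_decade = c(0.002, 0.008, 0.014, 0.02),
                     year_range = c(1984, 2060), seed = 43L)
  bs <- generate_basins(cfg)
  cube <- generate_sm_cube(bs, cfg)
  calib <- data.frame(basin_id = names(bs$basins), M = unname(bs$true_M))
  proj <- project_wetlands(bs, calib, cube)
  em <- ensemble_mean(proj)
  final <- em[, ncol(em)]
  expect_true(all(diff(final[c("SSP126", "SSP245", "SSP370", "SSP585")]) > 0))
})
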