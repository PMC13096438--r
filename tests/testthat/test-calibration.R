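# M calibration: RMSE, grid-search exhaustiveness, tie-break, recovery.

test_that("RMSE matches hand-computed values and detects misalignment", {
  expect_equal(rmse_areas(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse_areas(c(4, 5, 6), c(1, 2, 3)), 3)  # constant offset -> |c|
  expect_equal(rmse_areas(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
  sim <- data.frame(label = c("a", "b"), area_km2 = c(1, 2))
  obs <- data.frame(label = c("b", "a"), area_km2 = c(2, 1))
  expect_equal(rmse_areas(sim, obs), 0)  # aligned by label, not position
  expect_error(rmse_areas(sim, data.frame(label = c("a", "c"),
                                          area_km2 = c(1, 2))),
               "misaligned")
  expect_error(rmse_areas(c(1, 2), c(1, 2, 3)), "lengths differ")
})

test_that("noiseless observations recover the hidden M with zero RMSE", {
  cfg <- tiny_config(obs_noise_cv = 0, n_basins = 8,
                     pixels_per_basin = 2000)
  bs <- generate_basins(cfg)
  cube <- generate_sm_cube(bs, cfg)
  obs <- generate_observed_areas(bs, cube, config = cfg)
  fit <- calibrate_wetlands(bs, cube, obs)
  expect_identical(coef(fit), bs$true_M)
  expect_equal(fit$calibration$rmse_km2, rep(0, 8))
  expect_equal(fit$calibration$n_periods_used, rep(9L, 8))
})

test_that("the returned RMSE is the minimum over the whole M grid", {
  cfg <- tiny_config(n_basins = 4, obs_noise_cv = 0.1, seed = 13L)
  bs <- generate_basins(cfg)
  cube <- generate_sm_cube(bs, cfg)
  obs <- generate_observed_areas(bs, cube, config = cfg)
  periods <- default_historical_periods()
  fit <- calibrate_wetlands(bs, cube, obs, periods)
  for (i in seq_len(nrow(fit$calibration))) {
    id <- fit$calibration$basin_id[i]
    s <- extract_sm_series(cube, id)
    obs_b <- obs[obs$basin_id == id, ]
    all_rmse <- vapply(1:15, function(M) {
      rmse_areas(simulate_area_series(bs$basins[[id]], M, s, periods),
                 obs_b)
    }, numeric(1))
    expect_equal(fit$calibration$rmse_km2[i], min(all_rmse))
    expect_equal(fit$calibration$M[i], which.min(all_rmse))
  }
})

test_that("a point-mass CTI basin ties every M and resolves to M = 1", {
  b <- basin_record("pm", 100, rep(8, 50))
  s <- monthly_series(c(500, 550, 600), 2000)
  obs <- simulate_area_series(b, 9, s)[, c("label", "area_km2")]
  res <- calibrate_basin(b, s, obs, data.frame(start = 2000:2002,
                                               end = 2000:2002,
                                               label = obs$label))
  expect_equal(res$M, 1L)
  expect_equal(res$rmse_km2, 0)
})

test_that("calibration is order-independent and repeatable", {
  cfg <- tiny_config(n_basins = 6, seed = 17L)
  bs <- generate_basins(cfg)
  cube <- generate_sm_cube(bs, cfg)
  obs <- generate_observed_areas(bs, cube, config = cfg)
  fit1 <- calibrate_wetlands(bs, cube, obs)
  perm <- rev(seq_along(bs$basins))
  bs2 <- bs; bs2$basins <- bs$basins[perm]; bs2$true_M <- bs$true_M[perm]
  fit2 <- calibrate_wetlands(bs2, cube, obs)
  tab1 <- fit1$calibration[order(fit1$calibration$basin_id), ]
  tab2 <- fit2$calibration[order(fit2$calibration$basin_id), ]
  rownames(tab1) <- rownames(tab2) <- NULL
  expect_identical(tab1, tab2)
  # repeated run: identical M everywhere
  fit3 <- calibrate_wetlands(bs, cube, obs)
  expect_identical(coef(fit1), coef(fit3))
})

test_that("identical basins with identical inputs calibrate identically", {
  cti <- rgamma(500, 4, scale = 2)
  b1 <- basin_record("twin1", 300, cti)
  b2 <- basin_record("twin2", 300, cti)
  s <- monthly_series(c(520, 560, 480, 610), 2000)
  periods <- data.frame(start = 2000:2003, end = 2000:2003)
  obs <- simulate_area_series(b1, 11, s, periods)
  obs_tab <- rbind(
    data.frame(basin_id = "twin1", label = obs$label, area_km2 = obs$area_km2),
    data.frame(basin_id = "twin2", label = obs$label, area_km2 = obs$area_km2))
  fit <- calibrate_wetlands(list(b1, b2), list(twin1 = s, twin2 = s),
                            obs_tab, periods)
  expect_equal(unname(coef(fit)[1]), unname(coef(fit)[2]))
  expect_equal(fit$calibration$rmse_km2[1], fit$calibration$rmse_km2[2])
})

test_that("basins without observations land in the exceptions table", {
  cfg <- tiny_config(n_basins = 4)
  bs <- generate_basins(cfg)
  cube <- generate_sm_cube(bs, cfg)
  obs <- generate_observed_areas(bs, cube, config = cfg)
  obs_cut <- obs[obs$basin_id != "basin0002", ]
  fit <- calibrate_wetlands(bs, cube, obs_cut)
  expect_equal(fit$exceptions$basin_id, "basin0002")
  expect_equal(nrow(fit$calibration), 3)
})

test_that("missing periods reduce n_periods_used; all-missing is an error", {
  cfg <- tiny_config(n_basins = 2, obs_noise_cv = 0)
  bs <- generate_basins(cfg)
  cube <- generate_sm_cube(bs, cfg)
  obs <- generate_observed_areas(bs, cube, config = cfg)
  obs$area_km2[obs$basin_id == "basin0001" &
                 obs$label %in% c("1984-1990", "1991-1994")] <- NA
  fit <- calibrate_wetlands(bs, cube, obs)
  tab <- fit$calibration
  expect_equal(tab$n_periods_used[tab$basin_id == "basin0001"], 7L)
  expect_equal(tab$n_periods_used[tab$basin_id == "basin0002"], 9L)
  # still recovers under the remaining periods (noiseless)
  expect_identical(setNames(tab$M, tab$basin_id), bs$true_M)
  obs$area_km2[obs$basin_id == "basin0001"] <- NA
  expect_error(calibrate_wetlands(bs, cube, obs), "all observations missing")
})

test_that("median calibration RMSE shrinks as observation noise vanishes", {
  meds <- vapply(c(0.2, 0.05, 0), function(cv) {
    cfg <- tiny_config(n_basins = 10, obs_noise_cv = cv, seed = 23L)
    bs <- generate_basins(cfg)
    cube <- generate_sm_cube(bs, cfg)
    obs <- generate_observed_areas(bs, cube, config = cfg)
    median(calibrate_wetlands(bs, cube, obs)$calibration$rmse_km2)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
  expect_equal(meds[3], 0)
})

test_that("fit methods expose coefficients, residuals and simulations", {
  cfg <- tiny_config(n_basins = 3, seed = 29L)
  bs <- generate_basins(cfg)
  cube <- generate_sm_cube(bs, cfg)
  obs <- generate_observed_areas(bs, cube, config = cfg)
  fit <- calibrate_wetlands(bs, cube, obs)
  expect_named(coef(fit), names(bs$basins))
  r <- residuals(fit)
  expect_equal(nrow(r), 3 * 9)
  expect_equal(r$residual_km2, r$area_km2_fit - r$area_km2_obs)
  sims <- simulate(fit, nsim = 2, seed = 1, obs_noise_cv = 0)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$area_km2, fit$fitted$area_km2)
  # predict() drives the calibrated model with a new soil-moisture cube
  pr <- predict(fit, cube, years = 2020:2025)
  expect_s3_class(pr, "ensemble_area_cube")
  expect_identical(pr$M, coef(fit))
  expect_equal(pr$years, 2020:2025)
  s <- summary(fit)
  expect_s3_class(s, "summary.wetland_calibration")
  expect_equal(sum(s$M_table), 3)
})
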