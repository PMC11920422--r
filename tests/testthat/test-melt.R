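reg0 <- irf_regression(0, 0)           # always-zero forcing
reg_pub <- irf_regression(5.52, -24.03, residual_sd = 10.8)

test_that("sensible heat flux follows the humidity-adjusted bulk formula", {
  expect_equal(sensible_heat_flux(0, 5, 80), 0)
  expect_equal(sensible_heat_flux(3.15, 0, 80), 0)
  expect_equal(sensible_heat_flux(3.15, 5, 80),
               1.29 * 1005 * 1.5e-3 * 0.8 * 5 * 3.15, tolerance = 1e-12)
  expect_equal(sensible_heat_flux(3.15, 5, 80), 24.50, tolerance = 1e-3)
  expect_lt(sensible_heat_flux(-2, 5, 80), 0)   # sub-zero air cools the surface
  expect_error(sensible_heat_flux(3, 5, 120), "0, 100")
  expect_error(sensible_heat_flux(3, -1, 80), ">= 0")
})

test_that("net shortwave combines albedo and algal forcing additively", {
  expect_equal(shortwave_net(300, 0.8), 60)
  expect_equal(shortwave_net(300, 0.8, 10), 70)
  expect_equal(shortwave_net(300, 0.999999, 0), 300 * (1 - 0.999999))
  expect_error(shortwave_net(300, 1), "0, 1")
  expect_error(shortwave_net(-1, 0.5), ">= 0")
  expect_error(shortwave_net(300, 0.5, -1), ">= 0")
})

test_that("melt_from_energy converts via the latent heat of fusion", {
  expect_equal(melt_from_energy(3.34e5), 1)
  expect_equal(melt_from_energy(0), 0)
  expect_equal(melt_from_energy(-1e5), 0)   # no refreezing modelled
})

test_that("a dark, freezing day produces zero melt and zero contribution", {
  w <- make_constant_weather(par = 0, air_temp = -5, wind = 4, rh = 80)
  res <- run_melt_model(w, surface_params(0.78, 400, "snow"), reg_pub, 2.5e5)
  expect_equal(res$daily$total_melt_mm, 0)
  expect_equal(res$daily$algal_melt_mm, 0)
  expect_equal(res$daily$percent_contribution, 0)
})

test_that("constant forcing matches the closed-form melt expression", {
  # shortwave 100 W m-2 in, albedo 0.6, sensible heat exactly 10 W m-2
  qh_temp <- 10 / (1.29 * 1005 * 1.5e-3 * 1 * 2)   # rh 100%, wind 2 m s-1
  w <- make_constant_weather(par = 100 * 4.57, air_temp = qh_temp,
                             wind = 2, rh = 100)
  res <- run_melt_model(w, surface_params(0.6, 500, "snow"), reg0, 2.5e5)
  expected <- (100 * 0.4 + 10) * 86400 / 3.34e5    # 12.93 mm w.e.
  expect_equal(res$daily$clean_melt_mm, expected, tolerance = 1e-9)
  expect_equal(res$daily$total_melt_mm, expected, tolerance = 1e-9)
  expect_equal(res$daily$algal_melt_mm, 0, tolerance = 1e-12)

  # with constant positive forcing the algal melt has a closed form too
  res2 <- run_melt_model(w, surface_params(0.6, 500, "snow"), reg_pub, 2.5e5)
  irf <- predict_irf(2.5e5, reg_pub, par = 100 * 4.57)
  expect_equal(res2$daily$algal_melt_mm, irf * 86400 / 3.34e5, tolerance = 1e-9)
  expect_equal(res2$daily$percent_contribution,
               100 * res2$daily$algal_melt_mm / res2$daily$total_melt_mm,
               tolerance = 1e-12)
})

test_that("energy closure holds exactly per run", {
  for (seed in 1:5) {
    w <- make_weather_series(mean_par = 300 + 50 * seed, mean_temp = seed - 2,
                             par_jitter_sd = 0.3, seed = seed)
    res <- run_melt_model(w, surface_params(0.55, 550, "weathering_crust"),
                          reg_pub, 2.5e5)
    lf <- res$constants$lf
    expect_equal(sum(res$steps$melt_algal_mm) * lf,
                 sum(pmax(res$steps$energy_net_algal, 0)) * 300)
    expect_equal(sum(res$steps$melt_clean_mm) * lf,
                 sum(pmax(res$steps$energy_net_clean, 0)) * 300)
    # algae can only add melt
    expect_gte(sum(res$steps$melt_algal_mm), sum(res$steps$melt_clean_mm))
  }
})

test_that("splitting a day into two half-series preserves the totals", {
  w <- make_weather_series(mean_par = 399, mean_temp = 2.42, seed = 9)
  surface <- surface_params(0.55, 550, "weathering_crust")
  full <- run_melt_model(w, surface, reg_pub, 2.5e5)
  first <- run_melt_model(w[1:144, ], surface, reg_pub, 2.5e5)
  second <- run_melt_model(w[145:288, ], surface, reg_pub, 2.5e5)
  expect_equal(first$daily$total_melt_mm + second$daily$total_melt_mm,
               full$daily$total_melt_mm, tolerance = 1e-12)
  expect_equal(first$daily$algal_melt_mm + second$daily$algal_melt_mm,
               full$daily$algal_melt_mm, tolerance = 1e-12)
})

test_that("percent contribution is insensitive to the time discretisation", {
  surface <- surface_params(0.55, 550, "weathering_crust")
  w5 <- make_halfsine_weather(399, 2.42, dt = 300)
  w1 <- make_halfsine_weather(399, 2.42, dt = 60)
  r5 <- run_melt_model(w5, surface, reg_pub, 2.5e5)
  r1 <- run_melt_model(w1, surface, reg_pub, 2.5e5)
  expect_equal(r5$daily$percent_contribution, r1$daily$percent_contribution,
               tolerance = 1e-3)
  expect_equal(r5$daily$total_melt_mm, r1$daily$total_melt_mm, tolerance = 1e-3)
})

test_that("run_melt_model validates its inputs", {
  w <- make_weather_series(seed = 1)
  surface <- surface_params(0.78, 400, "snow")
  expect_error(run_melt_model(w[0, ], surface, reg_pub, 2.5e5), "empty")
  irregular <- w[c(1:10, 12:20), ]
  expect_error(run_melt_model(irregular, surface, reg_pub, 2.5e5),
               "regularly spaced")
  expect_error(run_melt_model(w, surface, reg_pub, -1), "positive")
  expect_error(surface_params(1.2, 400), "0, 1")
  expect_error(surface_params(0.5, 20), "50, 917")
})

test_that("melt uncertainty propagates the regression residual linearly", {
  # zero residual and density SD give zero uncertainty
  w <- make_constant_weather(par = 457, air_temp = 2, wind = 4, rh = 80)
  surface <- surface_params(0.6, 500, "snow")
  res0 <- run_melt_model(w, surface, irf_regression(5.52, -24.03), 2.5e5)
  u0 <- melt_uncertainty(res0)
  expect_equal(u0$algal_melt_sd_mm, 0)
  expect_equal(u0$algal_melt_sd_combined_mm, 0)
  # constant forcing: SD = residual_sd * (par/ref) * 86400 / Lf
  res <- run_melt_model(w, surface, reg_pub, 2.5e5)
  u <- melt_uncertainty(res)
  expect_equal(u$algal_melt_sd_mm, 10.8 * (457 / 351) * 86400 / 3.34e5,
               tolerance = 1e-9)
  # non-decreasing in the residual SD
  res_wide <- run_melt_model(w, surface,
                             irf_regression(5.52, -24.03, residual_sd = 15), 2.5e5)
  expect_gte(melt_uncertainty(res_wide)$algal_melt_sd_mm[1], u$algal_melt_sd_mm[1])
  # the density variant reports separately and combines in quadrature
  ud <- melt_uncertainty(res, density_sd = 2.7e5)
  expect_gt(ud$algal_melt_sd_density_mm[1], 0)
  expect_equal(ud$algal_melt_sd_combined_mm,
               sqrt(ud$algal_melt_sd_mm^2 + ud$algal_melt_sd_density_mm^2))
})

test_that("percent contribution and volume extrapolation use Table-style units", {
  expect_equal(percent_contribution(0, 21.4), 0)
  expect_equal(percent_contribution(21.4, 21.4), 100)
  expect_equal(percent_contribution(0.51, 21.4), 100 * 0.51 / 21.4)
  expect_error(percent_contribution(1, 0), "positive")
  expect_error(percent_contribution(-1, 10), "0 <= algal_melt")
  expect_error(percent_contribution(11, 10), "0 <= algal_melt")
  expect_equal(extrapolate_volume(1, 1), 1e6)
  expect_equal(extrapolate_volume(0.51, 2.7), 1.377e6)
  expect_equal(extrapolate_volume(5, 0), 0)
  expect_error(extrapolate_volume(1, -1), ">= 0")
})
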