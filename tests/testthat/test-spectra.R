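test_that("spectrum construction enforces its invariants", {
  expect_s3_class(new_spectrum(400:410, rep(0.5, 11)), "bioalbedo_spectrum")
  expect_error(new_spectrum(c(400, 400, 410), c(1, 1, 1)), "strictly increasing")
  expect_error(new_spectrum(400:410, rep(0.5, 5)), "equal length")
  expect_error(new_spectrum(400:410, c(rep(0.5, 10), NA)), "finite")
  expect_error(new_spectrum(400:410, c(rep(0.5, 10), -0.1)), "non-negative")
  expect_error(new_spectrum(400:410, c(rep(0.5, 10), 1.6)), "1.5")
  # HDRF may mildly exceed 1; radiance has no 1.5 cap
  expect_silent(new_spectrum(400:410, rep(1.2, 11)))
  expect_silent(new_spectrum(400:410, rep(900, 11), kind = "radiance"))
})

test_that("compute_hdrf reproduces the target/panel ratio with panel bracketing", {
  g <- 400:700
  panel <- new_spectrum(g, rep(2, length(g)), "radiance")
  # identity: target == both panels, beta == 1
  rho <- compute_hdrf(panel, panel, panel, panel_calibration(1.0))
  expect_equal(rho$value, rep(1, length(g)))
  expect_equal(rho$kind, "reflectance")
  # half-panel target with the nominal 98% panel
  target <- new_spectrum(g, rep(1, length(g)), "radiance")
  rho <- compute_hdrf(target, panel, panel)  # default beta 0.98
  expect_equal(rho$value, rep(0.49, length(g)), tolerance = 1e-12)
  # bracketing: mean of before/after panel scans
  p1 <- new_spectrum(g, rep(1, length(g)), "radiance")
  p3 <- new_spectrum(g, rep(3, length(g)), "radiance")
  rho <- compute_hdrf(target, p1, p3, panel_calibration(1.0))
  expect_equal(rho$value, rep(0.5, length(g)))
})

test_that("compute_hdrf is invariant to rescaling target and panels together", {
  g <- 400:700
  set.seed(42)
  for (i in 1:10) {
    p <- runif(length(g), 1, 3)
    v <- runif(length(g), 0.2, 1.2) * p   # true HDRF in [0.19, 1.15]
    ccc <- runif(1, 0.1, 50)
    r1 <- compute_hdrf(new_spectrum(g, v, "radiance"),
                       new_spectrum(g, p, "radiance"),
                       new_spectrum(g, p * 1.1, "radiance"))
    r2 <- compute_hdrf(new_spectrum(g, ccc * v, "radiance"),
                       new_spectrum(g, ccc * p, "radiance"),
                       new_spectrum(g, ccc * p * 1.1, "radiance"))
    expect_equal(r1$value, r2$value, tolerance = 1e-12)
  }
})

test_that("compute_hdrf rejects bad panels and mismatched grids", {
  g <- 400:700
  target <- new_spectrum(g, rep(1, length(g)), "radiance")
  short_panel <- new_spectrum(450:700, rep(1, 251), "radiance")
  expect_error(compute_hdrf(target, short_panel, short_panel), "grid mismatch")
  zero_panel <- new_spectrum(g, c(rep(1, 150), 0, rep(1, 150)), "radiance")
  expect_error(compute_hdrf(target, zero_panel, zero_panel), "550 nm")
  refl <- new_spectrum(g, rep(0.5, length(g)), "reflectance")
  expect_error(compute_hdrf(refl, target, target), "radiance")
})

test_that("panel calibration validates beta and supports per-wavelength tables", {
  expect_error(panel_calibration(0), "0, 1.1")
  expect_error(panel_calibration(1.2), "0, 1.1")
  g <- 400:700
  cal <- panel_calibration(seq(0.97, 0.99, length.out = length(g)), g)
  target <- new_spectrum(g, rep(1, length(g)), "radiance")
  panel <- new_spectrum(g, rep(1, length(g)), "radiance")
  rho <- compute_hdrf(target, panel, panel, cal)
  expect_equal(rho$value, seq(0.97, 0.99, length.out = length(g)), tolerance = 1e-12)
})

test_that("resample_spectrum interpolates linearly and refuses extrapolation", {
  s <- new_spectrum(c(400, 700), c(0, 1))
  same <- resample_spectrum(s, c(400, 700))
  expect_equal(same$wavelength, s$wavelength)
  expect_equal(same$value, s$value)
  mid <- resample_spectrum(s, c(400, 550, 700))
  expect_equal(mid$value[2], 0.5)
  expect_error(resample_spectrum(new_spectrum(400:700, rep(0.5, 301)), 399:500),
               "extrapolation")
})

test_that("broadband_mean is the trapezoidal window mean", {
  flat <- new_spectrum(350:1000, rep(0.8, 651))
  expect_equal(broadband_mean(flat, 350, 1000), 0.8)
  expect_equal(broadband_mean(flat, 412.5, 902.2), 0.8)
  lin <- new_spectrum(c(400, 700), c(0, 1))
  expect_equal(broadband_mean(lin, 400, 700), 0.5)
  expect_error(broadband_mean(flat, 700, 400), "lo < hi")
  expect_error(broadband_mean(flat, 300, 900), "not covered")
})

test_that("window means stay within the value range of the input", {
  for (seed in 1:10) {
    s <- make_gaussian_mixture_spectrum(seed)
    m <- broadband_mean(s, 420, 680)
    expect_gte(m, min(s$value))
    expect_lte(m, max(s$value))
    b <- band_reflectance(s, band_def("B5", 660, 630, 690))
    expect_gte(b, min(s$value))
    expect_lte(b, max(s$value))
  }
})

test_that("band_reflectance behaves as a boxcar mean", {
  b5 <- band_def("B5", 660, 630, 690)
  flat <- new_spectrum(350:1000, rep(0.6, 651))
  expect_equal(band_reflectance(flat, b5), 0.6)
  # a dip centred in the band lowers the band value
  g <- 350:1000
  dip <- new_spectrum(g, 0.6 - 0.2 * exp(-((g - 660) / 10)^2 / 2))
  expect_lt(band_reflectance(dip, b5), 0.6)
  # boxcar of a linear spectrum equals its value at the band midpoint
  lin <- new_spectrum(c(350, 1000), c(0.2, 0.9))
  slope <- (0.9 - 0.2) / 650
  expect_equal(band_reflectance(lin, b5), 0.2 + slope * (660 - 350),
               tolerance = 1e-12)
})

test_that("1-nm window means agree with a 0.01-nm oracle on smooth spectra", {
  for (seed in 1:5) {
    s <- make_gaussian_mixture_spectrum(seed)
    coarse <- broadband_mean(resample_spectrum(s, 420:680), 420, 680)
    lam <- seq(420, 680, by = 0.01)
    fine <- oracle_trapz(lam, oracle_interp(s$wavelength, s$value, lam)) / 260
    expect_equal(coarse, fine, tolerance = 1e-3)
  }
})

test_that("replicate averaging supports both orders of HDRF computation", {
  g <- 400:700
  set.seed(7)
  targets <- lapply(1:3, function(i) new_spectrum(g, runif(length(g), 0.5, 1), "radiance"))
  panels <- lapply(1:3, function(i) new_spectrum(g, rep(2, length(g)), "radiance"))
  avg_h <- hdrf_replicates(targets, panels, panels, panel_calibration(1.0))
  avg_r <- hdrf_replicates(targets, panels, panels, panel_calibration(1.0),
                           order = "average_radiance")
  # identical panels: the two orders coincide
  expect_equal(avg_h$value, avg_r$value, tolerance = 1e-12)
  manual <- (targets[[1]]$value + targets[[2]]$value + targets[[3]]$value) / 3 / 2
  expect_equal(avg_h$value, manual, tolerance = 1e-12)
  expect_error(average_spectra(list(targets[[1]],
                                    new_spectrum(g, rep(0.5, length(g))))),
               "mix")
})
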