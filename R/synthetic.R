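#' Pigment model for synthetic algal spectra
#'
#' Phenomenological description of how algal pigments reshape a clean surface
#' spectrum: a Gaussian chlorophyll-a absorption dip centred at 680 nm, a
#' broad carotenoid absorption across 400-550 nm (stronger in red-cell
#' communities), and a broadband VNIR quench emulating the dark phenolic
#' pigmentation of *Ancylonema*. All depths grow with `ln(1 + density/d0)`,
#' mirroring the log-linear density-forcing relationship; `d0` softens the
#' response so densities near the detection floor (~5e3 cells ml⁻¹) produce
#' shallow dips.
#'
#' @param chl_center Chlorophyll-a dip centre, nm.
#' @param chl_width Gaussian sigma of the chlorophyll dip, nm.
#' @param carotenoid_band Two wavelengths (nm) delimiting the carotenoid
#'   absorption region; the dip is a Gaussian centred on the band with sigma
#'   a quarter of its width.
#' @param depth_per_lndensity Chlorophyll dip depth per unit
#'   `ln(1 + density/d0)` (dimensionless reflectance).
#' @param carotenoid_depth_per_lndensity Same for the carotenoid dip.
#' @param broadband_quench Multiplicative VNIR darkening per unit
#'   `ln(1 + density/d0)` for *Ancylonema*-containing communities.
#' @param red_carotenoid_factor Carotenoid enhancement for red-dominated
#'   communities.
#' @param d0 Density softening constant, cells ml⁻¹.
#' @return A `pigment_model` object.
#' @export
pigment_model <- function(chl_center = 680, chl_width = 12,
                          carotenoid_band = c(400, 550),
                          depth_per_lndensity = 0.05,
                          carotenoid_depth_per_lndensity = 0.03,
                          broadband_quench = 0.015,
                          red_carotenoid_factor = 1.6,
                          d0 = 1000) {
  if (chl_width <= 0 || d0 <= 0 || red_carotenoid_factor <= 0) {
    stop("pigment_model: widths, d0 and factors must be positive", call. = FALSE)
  }
  if (depth_per_lndensity < 0 || carotenoid_depth_per_lndensity < 0 ||
      broadband_quench < 0) {
    stop("pigment_model: depths must be >= 0", call. = FALSE)
  }
  if (length(carotenoid_band) != 2 || diff(carotenoid_band) <= 0) {
    stop("pigment_model: carotenoid_band must be an increasing pair of nm", call. = FALSE)
  }
  structure(list(chl_center = chl_center, chl_width = chl_width,
                 carotenoid_band = carotenoid_band,
                 depth_per_lndensity = depth_per_lndensity,
                 carotenoid_depth_per_lndensity = carotenoid_depth_per_lndensity,
                 broadband_quench = broadband_quench,
                 red_carotenoid_factor = red_carotenoid_factor,
                 d0 = d0),
            class = "pigment_model")
}

gaussian_bump <- function(x, center, sigma) exp(-((x - center) / sigma)^2 / 2)

#' Generate a clean snow or weathering-crust spectrum
#'
#' Smooth parametric reflectance over 350-1000 nm: a bright (snow) or dull
#' (crust) plateau, a quadratic decline into the NIR, and a gentle broad
#' visible maximum near 640 nm. The latter makes the spectrum concave across
#' the 585-745 nm classification bands, so clean surfaces carry a clearly
#' negative chlorophyll band depth — as clean snow does in band-depth mapping
#' — rather than sitting on the classification knife-edge. Coefficients get
#' small seeded jitter; snow is always brighter than crust by construction.
#'
#' @param kind `"snow"` or `"weathering_crust"`.
#' @param seed Integer seed; identical seeds give identical spectra.
#' @param grid Wavelength grid in nm (default 1-nm over 350-1000).
#' @return A reflectance spectrum with values in (0, 1).
#' @export
make_surface_spectrum <- function(kind = c("snow", "weathering_crust"),
                                  seed = 1L, grid = 350:1000) {
  kind <- match.arg(kind)
  p <- withr::with_seed(seed, {
    list(jitter_a = stats::rnorm(1, 0, 0.008),
         jitter_c = stats::rnorm(1, 0, 0.015),
         jitter_g = stats::rnorm(1, 0, 0.004))
  })
  base <- switch(kind,
                 snow = c(a = 0.90, c = 0.35, g = 0.10),
                 weathering_crust = c(a = 0.60, c = 0.28, g = 0.08))
  a <- base["a"] + max(min(p$jitter_a, 0.03), -0.03)
  cc <- max(base["c"] + max(min(p$jitter_c, 0.05), -0.05), 0.05)
  g <- max(base["g"] + max(min(p$jitter_g, 0.015), -0.015), 0.02)
  u <- (grid - 350) / 650
  v <- a - cc * u^2 + g * gaussian_bump(grid, 640, 90 / sqrt(2))
  new_spectrum(grid, pmin(pmax(v, 1e-3), 0.999), kind = "reflectance")
}

# per-wavelength reflectance deficit (dip) and multiplicative quench for a
# given density/community; shared by apply_algal_signal and make_scene
algal_signal_components <- function(grid, density, pm, community) {
  lnf <- log1p(density / pm$d0)
  car_center <- mean(pm$carotenoid_band)
  car_sigma <- diff(pm$carotenoid_band) / 4
  car_factor <- if (community == "red_dominated") pm$red_carotenoid_factor else 1
  dip <- lnf * (pm$depth_per_lndensity *
                  gaussian_bump(grid, pm$chl_center, pm$chl_width) +
                pm$carotenoid_depth_per_lndensity * car_factor *
                  gaussian_bump(grid, car_center, car_sigma))
  quench <- if (community == "ancylonema_present") {
    min(pm$broadband_quench * lnf, 0.5)
  } else {
    0
  }
  list(dip = dip, quench = quench, lnf = lnf)
}

#' Impose an algal signal on a clean spectrum
#'
#' Darkens a clean surface spectrum according to the pigment model: a
#' chlorophyll-a dip at 680 nm, a carotenoid dip over 400-550 nm (enhanced
#' for red-dominated communities), and for *Ancylonema*-containing
#' communities a multiplicative broadband quench. Depths scale with
#' `ln(1 + density/d0)`; density 0 returns the base spectrum unchanged, and
#' the output never exceeds the base at any wavelength. If the requested
#' darkening would drive reflectance to zero or below it is floored at 0.001
#' with a `bioalbedo_floor` warning.
#'
#' @param base Clean reflectance spectrum.
#' @param density Cell density in cells ml⁻¹, `>= 0`.
#' @param pm A [pigment_model()].
#' @param community `"red_dominated"` or `"ancylonema_present"`.
#' @param depth_jitter_sd Lognormal sigma of a seeded multiplicative jitter on
#'   the dip depths; default 0 (fully deterministic).
#' @param seed Seed for the jitter.
#' @return A reflectance spectrum on the base grid.
#' @export
apply_algal_signal <- function(base, density, pm = pigment_model(),
                               community = c("red_dominated", "ancylonema_present"),
                               depth_jitter_sd = 0, seed = 1L) {
  stopifnot_spectrum(base)
  community <- match.arg(community)
  if (!is.numeric(density) || length(density) != 1 || density < 0) {
    stop("apply_algal_signal: density must be a single number >= 0", call. = FALSE)
  }
  comp <- algal_signal_components(base$wavelength, density, pm, community)
  dip <- comp$dip
  if (depth_jitter_sd > 0) {
    dip <- dip * withr::with_seed(seed, exp(stats::rnorm(1, 0, depth_jitter_sd)))
  }
  v <- base$value * (1 - comp$quench) - dip
  if (any(v <= 0)) {
    warning(sprintf(
      "bioalbedo_floor: algal darkening at density %g drove reflectance to <= 0 at %d wavelength(s); floored at 0.001",
      density, sum(v <= 0)))
    v <- pmax(v, 1e-3)
  }
  new_spectrum(base$wavelength, v, kind = "reflectance")
}

#' Generate a density-IRF calibration dataset
#'
#' Draws cell densities log-uniformly over the observed range and simulates
#' IRF from the log-linear relationship `IRF = a ln(d) + b` plus Gaussian
#' residual scatter. Defaults reproduce the field conditions: slope 5.52,
#' intercept -24.03, densities spanning the detection floor to the maximum
#' observed count (1.4e6 cells ml⁻¹), and a residual SD of 10.8 W m⁻², which
#' makes the population R² about 0.41 for this density spread (see the
#' methods vignette for the derivation). Group labels are drawn in the 19:22
#' red:*Ancylonema* proportion of the field sample set.
#'
#' @param n Number of samples, `>= 3`.
#' @param a,b Slope (W m⁻² per unit ln density) and intercept (W m⁻²).
#' @param noise_sd Residual SD, W m⁻².
#' @param density_range Density range (cells ml⁻¹), lower bound `> 0`.
#' @param seed Integer seed.
#' @return A tibble with `cell_density_per_ml`, `irf_w_m2`, `group`.
#' @export
make_density_irf_dataset <- function(n = 41, a = 5.52, b = -24.03,
                                     noise_sd = 10.8,
                                     density_range = c(5e3, 1.4e6),
                                     seed = 1L) {
  if (n < 3) stop("make_density_irf_dataset: n must be >= 3", call. = FALSE)
  if (density_range[1] <= 0 || diff(density_range) <= 0) {
    stop("make_density_irf_dataset: density_range must be increasing with lo > 0",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("make_density_irf_dataset: noise_sd must be >= 0", call. = FALSE)
  withr::with_seed(seed, {
    d <- exp(stats::runif(n, log(density_range[1]), log(density_range[2])))
    irf <- a * log(d) + b + stats::rnorm(n, 0, noise_sd)
    grp <- sample(c("red_dominated", "ancylonema_present"), n,
                  replace = TRUE, prob = c(19, 22) / 41)
    tibble::tibble(cell_density_per_ml = d, irf_w_m2 = irf, group = grp)
  })
}

#' Generate a diurnal weather series
#'
#' 288 five-minute records for one day: PAR follows a half-sine over the
#' daylight window (centred on local noon) and is exactly zero at night,
#' rescaled so the discrete 24-h mean equals `mean_par`; air temperature is a
#' sinusoid about `mean_temp` peaking mid-afternoon; wind and relative
#' humidity are held constant (the field record contains neither). Defaults
#' reproduce the sunny modelled day (mean PAR 399 µmol m⁻² s⁻¹, mean air
#' temperature 2.42 °C).
#'
#' @param date Date of the series (anything `as.Date()` accepts).
#' @param mean_par 24-h mean PAR, µmol m⁻² s⁻¹, `>= 0`.
#' @param mean_temp 24-h mean air temperature, °C.
#' @param daylight_hours Daylight duration, h in (0, 24].
#' @param wind Wind speed, m s⁻¹.
#' @param rh Relative humidity, %.
#' @param temp_amplitude Diurnal temperature half-range, °C.
#' @param par_jitter_sd Lognormal sigma of seeded multiplicative jitter on
#'   daylight PAR (default 0); the series is re-normalised to `mean_par`
#'   after jittering.
#' @param seed Integer seed.
#' @return A tibble with `timestamp` (POSIXct UTC, 300-s spacing), `par`,
#'   `air_temp`, `wind`, `rh`.
#' @export
make_weather_series <- function(date = "2023-02-06", mean_par = 399,
                                mean_temp = 2.42, daylight_hours = 16,
                                wind = 5, rh = 80, temp_amplitude = 1.5,
                                par_jitter_sd = 0, seed = 1L) {
  if (mean_par < 0) stop("make_weather_series: mean_par must be >= 0", call. = FALSE)
  if (daylight_hours <= 0 || daylight_hours > 24) {
    stop("make_weather_series: daylight_hours must lie in (0, 24]", call. = FALSE)
  }
  t0 <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC")
  timestamp <- t0 + 300 * (0:287)
  h <- (0:287) * 300 / 3600
  h0 <- 12 - daylight_hours / 2
  shape <- ifelse(h > h0 & h < h0 + daylight_hours,
                  sin(pi * (h - h0) / daylight_hours), 0)
  shape <- pmax(shape, 0)
  if (par_jitter_sd > 0) {
    shape <- shape * withr::with_seed(seed, exp(stats::rnorm(288, 0, par_jitter_sd)))
  }
  par <- if (mean_par > 0 && mean(shape) > 0) shape * (mean_par / mean(shape)) else rep(0, 288)
  air_temp <- mean_temp + temp_amplitude * cos(2 * pi * (h - 15) / 24)
  tibble::tibble(timestamp = timestamp, par = par, air_temp = air_temp,
                 wind = rep(wind, 288), rh = rep(rh, 288))
}

# trapezoid band-mean weights on a regular unit grid; band limits must lie on
# grid points. Returns a weight vector w with sum(w) == 1 such that
# sum(w * value) equals band_reflectance() exactly.
band_weights <- function(grid, band) {
  i <- which(grid >= band$lower & grid <= band$upper)
  if (length(i) < 2 || grid[i[1]] != band$lower || grid[i[length(i)]] != band$upper) {
    stop("band_weights: band limits must lie on the working grid", call. = FALSE)
  }
  w <- rep(1, length(i))
  w[1] <- 0.5
  w[length(i)] <- 0.5
  out <- numeric(length(grid))
  out[i] <- w / (band$upper - band$lower)
  out
}

#' Generate a labelled multispectral scene
#'
#' Builds a scene of band reflectances with a known bloom mask: exactly
#' `round(bloom_fraction * n_pixels)` pixels, placed by seeded choice, carry
#' an algal signal with density drawn log-uniformly from `density_range`; all
#' other pixels show the clean surface spectrum. Per-pixel spectra are the
#' clean base darkened by [apply_algal_signal()] and convolved to band values
#' by the boxcar band mean; optional Gaussian band noise is added afterwards.
#'
#' @param shape `(rows, cols)` of the scene.
#' @param bloom_fraction Fraction of pixels carrying algae, in [0, 1].
#' @param density_range Algal pixel density range, cells ml⁻¹; the default
#'   floor of 1e4 keeps algal pixels well clear of the detection limit.
#' @param band_defs Named list of [band_def()]s (default [worldview_bands()]).
#' @param noise_sd Per-band Gaussian noise SD (reflectance units); default 0.
#' @param surface Clean surface kind.
#' @param community Algal community applied to bloom pixels.
#' @param pm A [pigment_model()].
#' @param pixel_size Pixel edge length in metres (default 1.6).
#' @param valid Optional logical validity matrix.
#' @param seed Integer seed; the whole scene is a pure function of the
#'   arguments including the seed.
#' @return A list with `scene` (an [scene()]), `truth_mask` (logical matrix)
#'   and `densities` (matrix, 0 where no algae).
#' @export
make_scene <- function(shape = c(100, 100), bloom_fraction = 0.2,
                       density_range = c(1e4, 1.4e6),
                       band_defs = worldview_bands(), noise_sd = 0,
                       surface = c("weathering_crust", "snow"),
                       community = c("ancylonema_present", "red_dominated"),
                       pm = pigment_model(), pixel_size = 1.6,
                       valid = NULL, seed = 1L) {
  surface <- match.arg(surface)
  community <- match.arg(community)
  if (bloom_fraction < 0 || bloom_fraction > 1) {
    stop("make_scene: bloom_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (density_range[1] <= 0 || diff(density_range) < 0) {
    stop("make_scene: density_range must be positive and non-decreasing", call. = FALSE)
  }
  nr <- shape[1]; nc <- shape[2]; n_pix <- nr * nc
  n_algae <- round(bloom_fraction * n_pix)
  withr::with_seed(seed, {
    base <- make_surface_spectrum(surface, seed = seed)
    grid <- base$wavelength
    wts <- lapply(band_defs, function(b) band_weights(grid, b))
    clean_bands <- vapply(wts, function(w) sum(w * base$value), numeric(1))
    idx <- if (n_algae > 0) sample.int(n_pix, n_algae) else integer(0)
    densities <- matrix(0, nr, nc)
    values <- lapply(clean_bands, function(v) matrix(v, nr, nc))
    if (n_algae > 0) {
      d <- exp(stats::runif(n_algae, log(density_range[1]), log(density_range[2])))
      densities[idx] <- d
      for (k in seq_along(idx)) {
        sp <- apply_algal_signal(base, d[k], pm, community)
        for (nm in names(values)) {
          values[[nm]][idx[k]] <- sum(wts[[nm]] * sp$value)
        }
      }
    }
    if (noise_sd > 0) {
      values <- lapply(values, function(m) {
        pmax(m + matrix(stats::rnorm(n_pix, 0, noise_sd), nr, nc), 0)
      })
    }
    truth <- matrix(FALSE, nr, nc)
    truth[idx] <- TRUE
    list(scene = scene(band_defs, values, pixel_size, valid),
         truth_mask = truth,
         densities = densities)
  })
}
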