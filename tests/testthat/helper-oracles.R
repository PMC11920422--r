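# Independent numerical oracles, deliberately avoiding the package's own
# interpolation/quadrature code paths.

# manual linear interpolation (no stats::approx, no package code)
oracle_interp <- function(w, v, x) {
  i <- findInterval(x, w, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), length(w) - 1)
  v[i] + (v[i + 1] - v[i]) * (x - w[i]) / (w[i + 1] - w[i])
}

# manual trapezoid sum
oracle_trapz <- function(x, y) {
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

# brute-force IRF: resample both reflectance spectra onto a 0.01-nm grid by
# linear interpolation and integrate E_e * (rho_clean - rho_algae)
oracle_irf <- function(clean, algal, par, step = 0.01) {
  lam <- seq(400, 700, by = step)
  dc <- oracle_interp(clean$wavelength, clean$value, lam)
  da <- oracle_interp(algal$wavelength, algal$value, lam)
  ee <- rep((par / 4.57) / 300, length(lam))
  oracle_trapz(lam, ee * (dc - da))
}

# smooth Gaussian-mixture clean spectrum on the 1-nm working grid
make_gaussian_mixture_spectrum <- function(seed, grid = 400:700) {
  set.seed(seed)
  level <- runif(1, 0.5, 0.9)
  v <- rep(level, length(grid))
  for (k in seq_len(sample(2:4, 1))) {
    amp <- runif(1, -0.1, 0.1)
    ctr <- runif(1, 450, 650)
    sig <- runif(1, 25, 60)
    v <- v + amp * exp(-((grid - ctr) / sig)^2 / 2)
  }
  new_spectrum(grid, pmin(pmax(v, 0.05), 1.4))
}

# clean/algal pair differing by well-interior Gaussian dips (chlorophyll-like
# at ~680 nm plus a broad carotenoid-like one)
make_gaussian_dip_pair <- function(seed, grid = 400:700) {
  clean <- make_gaussian_mixture_spectrum(seed, grid)
  set.seed(seed + 1000)
  dip <- runif(1, 0.05, 0.25) * exp(-((grid - 680) / runif(1, 5, 15))^2 / 2) +
    runif(1, 0.02, 0.15) * exp(-((grid - 480) / runif(1, 20, 40))^2 / 2)
  algal <- new_spectrum(grid, pmax(clean$value - dip, 0.01))
  list(clean = clean, algal = algal)
}

# constant-forcing weather series at an arbitrary cadence
make_constant_weather <- function(par, air_temp, wind, rh, dt = 300,
                                  date = "2023-02-01") {
  n <- as.integer(86400 / dt)
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  tibble::tibble(timestamp = t0 + dt * (0:(n - 1)),
                 par = rep(par, n), air_temp = rep(air_temp, n),
                 wind = rep(wind, n), rh = rep(rh, n))
}

# half-sine weather at an arbitrary cadence (for discretisation checks)
make_halfsine_weather <- function(mean_par, mean_temp, dt,
                                  daylight_hours = 16, wind = 5, rh = 80,
                                  date = "2023-02-06") {
  n <- as.integer(86400 / dt)
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  h <- (0:(n - 1)) * dt / 3600
  h0 <- 12 - daylight_hours / 2
  shape <- ifelse(h > h0 & h < h0 + daylight_hours,
                  sin(pi * (h - h0) / daylight_hours), 0)
  par <- if (mean(shape) > 0) shape * mean_par / mean(shape) else shape
  tibble::tibble(timestamp = t0 + dt * (0:(n - 1)), par = par,
                 air_temp = mean_temp + 1.5 * cos(2 * pi * (h - 15) / 24),
                 wind = rep(wind, n), rh = rep(rh, n))
}
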