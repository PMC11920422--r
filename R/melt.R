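#' Physical constants of the melt model
#'
#' All constants used by the energy-balance model, exposed in one place so a
#' run can be reconfigured without touching call sites.
#'
#' @param par_to_energy Quantum conversion, µmol J⁻¹ (daylight value 4.57).
#' @param rho_air Air density, kg m⁻³.
#' @param cp_air Specific heat of air, J kg⁻¹ K⁻¹.
#' @param ch0 Bulk sensible-heat transfer coefficient (dimensionless).
#' @param lf Latent heat of fusion, J kg⁻¹.
#' @param rho_water Water density, kg m⁻³.
#' @return A named list of constants.
#' @export
melt_constants <- function(par_to_energy = 4.57, rho_air = 1.29,
                           cp_air = 1005, ch0 = 1.5e-3,
                           lf = 3.34e5, rho_water = 1000) {
  out <- list(par_to_energy = par_to_energy, rho_air = rho_air,
              cp_air = cp_air, ch0 = ch0, lf = lf, rho_water = rho_water)
  if (any(vapply(out, function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("melt_constants: all constants must be positive numbers", call. = FALSE)
  }
  out
}

#' Surface parameters for a melt run
#'
#' @param albedo Broadband albedo in (0, 1), typically the mean broadband
#'   HDRF measured in situ for the surface type.
#' @param density Bulk density of the surface in kg m⁻³ (50-917).
#' @param label `"snow"` or `"weathering_crust"`.
#' @return A `surface_params` object.
#' @export
surface_params <- function(albedo, density, label = c("snow", "weathering_crust")) {
  label <- match.arg(label)
  if (!is.numeric(albedo) || albedo <= 0 || albedo >= 1) {
    stop("surface_params: albedo must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(density) || density < 50 || density > 917) {
    stop("surface_params: density must lie in [50, 917] kg m-3", call. = FALSE)
  }
  structure(list(albedo = albedo, density = density, label = label),
            class = "surface_params")
}

#' Bulk sensible-heat flux over a melting surface
#'
#' \deqn{Q_h = \rho_{air} c_p C_{h0} f(rh)\, u\, (T_{air} - T_{surf})}
#' with the surface held at 0 °C (melting) and the transfer coefficient
#' modulated by relative humidity through `f(rh) = rh/100` by default. The
#' flux may be negative for sub-zero air.
#'
#' @param air_temp Air temperature, °C (vectorised).
#' @param wind Wind speed, m s⁻¹, `>= 0`.
#' @param rh Relative humidity, % in [0, 100].
#' @param constants A [melt_constants()] list.
#' @param rh_factor Function mapping rh (%) to a multiplicative factor on the
#'   transfer coefficient; default `rh/100`.
#' @return Sensible heat flux in W m⁻².
#' @export
sensible_heat_flux <- function(air_temp, wind, rh,
                               constants = melt_constants(),
                               rh_factor = function(rh) rh / 100) {
  if (any(rh < 0 | rh > 100)) stop("sensible_heat_flux: rh must lie in [0, 100]", call. = FALSE)
  if (any(wind < 0)) stop("sensible_heat_flux: wind must be >= 0", call. = FALSE)
  constants$rho_air * constants$cp_air * constants$ch0 *
    rh_factor(rh) * wind * (air_temp - 0)
}

#' Net shortwave flux absorbed by the surface
#'
#' Incoming shortwave (PAR-derived) energy reduced by the surface albedo,
#' plus the algal radiative forcing, which is energy the algae absorb that a
#' clean surface would have reflected.
#'
#' @param irr_total Incoming shortwave flux, W m⁻², `>= 0`.
#' @param albedo Surface albedo in (0, 1).
#' @param algal_irf Algal radiative forcing, W m⁻², `>= 0`.
#' @return Net absorbed shortwave, W m⁻².
#' @export
shortwave_net <- function(irr_total, albedo, algal_irf = 0) {
  if (any(albedo <= 0 | albedo >= 1)) stop("shortwave_net: albedo must lie in (0, 1)", call. = FALSE)
  if (any(irr_total < 0)) stop("shortwave_net: irr_total must be >= 0", call. = FALSE)
  if (any(algal_irf < 0)) stop("shortwave_net: algal_irf must be >= 0", call. = FALSE)
  irr_total * (1 - albedo) + algal_irf
}

#' Meltwater equivalent of an energy input
#'
#' Positive net energy melts ice at the latent heat of fusion; negative net
#' energy produces no melt (no refreezing or cold content is modelled).
#' 1 kg m⁻² of meltwater is 1 mm w.e.
#'
#' @param energy Energy in J m⁻² (vectorised).
#' @param constants A [melt_constants()] list.
#' @return Melt in mm water equivalent.
#' @export
melt_from_energy <- function(energy, constants = melt_constants()) {
  pmax(energy, 0) / constants$lf
}

# shared engine: one model pass with a fixed IRF offset (W m-2 at reference
# PAR) and a fixed cell density; returns per-step tibble
melt_model_pass <- function(weather, surface, reg, density, constants,
                            with_algae, irf_offset = 0, sensible = TRUE) {
  dt <- weather_spacing(weather)
  irr_total <- weather$par / constants$par_to_energy
  irf <- if (with_algae) {
    predict_irf(density, reg, par = weather$par, irf_offset = irf_offset)
  } else {
    rep(0, nrow(weather))
  }
  sw <- shortwave_net(irr_total, surface$albedo, irf)
  qh <- if (sensible) {
    sensible_heat_flux(weather$air_temp, weather$wind, weather$rh, constants)
  } else {
    rep(0, nrow(weather))
  }
  e_net <- sw + qh
  tibble::tibble(timestamp = weather$timestamp,
                 par = weather$par,
                 irr_total = irr_total,
                 algal_irf = irf,
                 shortwave_net = sw,
                 sensible = qh,
                 energy_net = e_net,
                 melt_mm = melt_from_energy(e_net * dt, constants))
}

weather_spacing <- function(weather) {
  if (!is.data.frame(weather) || nrow(weather) == 0) {
    stop("melt model: weather series is empty", call. = FALSE)
  }
  need <- c("timestamp", "par", "air_temp", "wind", "rh")
  if (!all(need %in% names(weather))) {
    stop(sprintf("melt model: weather series needs columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (nrow(weather) == 1) return(300)
  d <- diff(as.numeric(weather$timestamp))
  if (any(abs(d - d[1]) > 1e-6)) {
    stop("melt model: weather timestamps are not regularly spaced", call. = FALSE)
  }
  d[1]
}

#' Run the energy-balance melt model with and without algae
#'
#' For each weather step the net energy is the albedo-adjusted shortwave flux
#' plus the bulk sensible-heat flux; in the algal run the shortwave term also
#' receives the algal radiative forcing predicted from the cell density and
#' scaled by instantaneous PAR. Positive net energy is converted to melt via
#' the latent heat of fusion and summed per day. The algal melt is the
#' difference between the two runs, and the percentage contribution is taken
#' relative to the algal-run total.
#'
#' @param weather A weather series (see [make_weather_series()] /
#'   [read_weather()]): regular steps with `timestamp`, `par`, `air_temp`,
#'   `wind`, `rh`.
#' @param surface A [surface_params()] object.
#' @param reg An `irf_regression`.
#' @param density Cell density applied in the algal run, cells ml⁻¹.
#' @param constants A [melt_constants()] list.
#' @param sensible Include the sensible-heat flux (default `TRUE`).
#' @return A `melt_result` with `steps` (per-step fluxes and melt for both
#'   runs), `daily` (per-date totals: `total_melt_mm`, `clean_melt_mm`,
#'   `algal_melt_mm`, `percent_contribution`, `lowering_mm`), and the run
#'   inputs (needed by [melt_uncertainty()]).
#' @export
run_melt_model <- function(weather, surface, reg, density,
                           constants = melt_constants(), sensible = TRUE) {
  if (!inherits(surface, "surface_params")) {
    stop("run_melt_model: surface must be surface_params", call. = FALSE)
  }
  if (!inherits(reg, "irf_regression")) {
    stop("run_melt_model: reg must be an irf_regression", call. = FALSE)
  }
  if (!is.numeric(density) || density <= 0) {
    stop("run_melt_model: density must be positive", call. = FALSE)
  }
  algal <- melt_model_pass(weather, surface, reg, density, constants,
                           with_algae = TRUE, sensible = sensible)
  clean <- melt_model_pass(weather, surface, reg, density, constants,
                           with_algae = FALSE, sensible = sensible)
  steps <- algal
  names(steps)[names(steps) == "melt_mm"] <- "melt_algal_mm"
  names(steps)[names(steps) == "shortwave_net"] <- "shortwave_net_algal"
  names(steps)[names(steps) == "energy_net"] <- "energy_net_algal"
  steps$shortwave_net_clean <- clean$shortwave_net
  steps$energy_net_clean <- clean$energy_net
  steps$melt_clean_mm <- clean$melt_mm
  date <- as.Date(steps$timestamp, tz = "UTC")
  total <- tapply(steps$melt_algal_mm, date, sum)
  clean_tot <- tapply(steps$melt_clean_mm, date, sum)
  algal_melt <- total - clean_tot
  pct <- ifelse(total > 0, 100 * algal_melt / total, 0)
  daily <- tibble::tibble(
    date = as.Date(names(total)),
    total_melt_mm = as.numeric(total),
    clean_melt_mm = as.numeric(clean_tot),
    algal_melt_mm = as.numeric(algal_melt),
    percent_contribution = as.numeric(pct),
    lowering_mm = as.numeric(total) * constants$rho_water / surface$density)
  structure(list(steps = steps, daily = daily,
                 weather = weather, surface = surface, reg = reg,
                 density = density, constants = constants,
                 sensible = sensible),
            class = "melt_result")
}

#' @export
print.melt_result <- function(x, ...) {
  cat(sprintf("<melt_result: %s, %d steps, %d day(s)>\n",
              x$surface$label, nrow(x$steps), nrow(x$daily)))
  print(x$daily)
  invisible(x)
}

#' Uncertainty of the algal melt
#'
#' Propagates the scatter of the IRF-density relationship through the melt
#' model: the model is re-run with the predicted IRF shifted by plus/minus
#' one residual standard deviation (the shift scales with PAR exactly as the
#' IRF does) and the reported SD is half the spread of the resulting algal
#' melt. When a cell-density SD is supplied, a second variant re-runs the
#' model at density plus/minus one SD (floored at 1 cell ml⁻¹) and is
#' reported separately.
#'
#' @param result A [run_melt_model()] result.
#' @param density_sd Standard deviation of the observed cell densities
#'   (cells ml⁻¹); default 0 disables the density variant.
#' @return A list with `algal_melt_sd_mm` (per day, from the IRF residual),
#'   `algal_melt_sd_density_mm` (per day, from the density SD; zeros when
#'   disabled) and `algal_melt_sd_combined_mm` (quadrature sum).
#' @export
melt_uncertainty <- function(result, density_sd = 0) {
  if (!inherits(result, "melt_result")) {
    stop("melt_uncertainty: result must come from run_melt_model", call. = FALSE)
  }
  if (density_sd < 0) stop("melt_uncertainty: density_sd must be >= 0", call. = FALSE)
  rerun_algal <- function(offset, density) {
    pass <- melt_model_pass(result$weather, result$surface, result$reg,
                            density, result$constants,
                            with_algae = TRUE, irf_offset = offset,
                            sensible = result$sensible)
    clean <- result$daily$clean_melt_mm
    date <- as.Date(pass$timestamp, tz = "UTC")
    as.numeric(tapply(pass$melt_mm, date, sum)) - clean
  }
  s <- result$reg$residual_sd
  hi <- rerun_algal(+s, result$density)
  lo <- rerun_algal(-s, result$density)
  sd_irf <- (hi - lo) / 2
  if (density_sd > 0) {
    dhi <- rerun_algal(0, result$density + density_sd)
    dlo <- rerun_algal(0, max(result$density - density_sd, 1))
    sd_den <- abs(dhi - dlo) / 2
  } else {
    sd_den <- rep(0, length(sd_irf))
  }
  list(algal_melt_sd_mm = sd_irf,
       algal_melt_sd_density_mm = sd_den,
       algal_melt_sd_combined_mm = sqrt(sd_irf^2 + sd_den^2))
}

#' Percentage contribution of algae to total melt
#'
#' @param algal_melt Algal melt, mm w.e., with `0 <= algal_melt <= total_melt`.
#' @param total_melt Total melt of the algal run, mm w.e., `> 0`.
#' @return Percentage in [0, 100].
#' @export
percent_contribution <- function(algal_melt, total_melt) {
  if (!is.numeric(total_melt) || total_melt <= 0) {
    stop("percent_contribution: total_melt must be positive", call. = FALSE)
  }
  if (any(algal_melt < 0) || any(algal_melt > total_melt)) {
    stop("percent_contribution: need 0 <= algal_melt <= total_melt", call. = FALSE)
  }
  100 * algal_melt / total_melt
}

#' Extrapolate melt over a bloom area
#'
#' 1 mm w.e. over 1 m² is 1 litre, so `litres = mm * km2 * 1e6`.
#'
#' @param algal_melt Melt depth in mm w.e.
#' @param area Bloom area in km², `>= 0`.
#' @return Meltwater volume in litres.
#' @export
extrapolate_volume <- function(algal_melt, area) {
  if (any(area < 0)) stop("extrapolate_volume: area must be >= 0", call. = FALSE)
  algal_melt * area * 1e6
}
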