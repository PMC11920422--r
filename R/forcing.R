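#' Convert PAR to broadband and spectral irradiance
#'
#' Field stations log photosynthetically active radiation (PAR, 400-700 nm)
#' in µmol photons m⁻² s⁻¹. Energy flux is obtained with the daylight quantum
#' conversion 4.57 µmol J⁻¹ (McCree), and — since a broadband PAR sensor
#' carries no spectral information — the energy is spread uniformly over
#' 400-700 nm to give a spectral irradiance density.
#'
#' @param par PAR in µmol m⁻² s⁻¹, `>= 0`.
#' @param conversion Quantum-to-energy conversion in µmol J⁻¹ (default 4.57).
#' @param step Wavelength step of the working grid in nm (default 1).
#' @return An object of class `spectral_irradiance` with fields `total`
#'   (W m⁻²), `wavelength` (nm, 400-700) and `density` (W m⁻² nm⁻¹). The
#'   trapezoidal integral of `density` equals `total` exactly.
#' @examples
#' par_to_irradiance(351)$total # 76.81 W m-2, field median daylight PAR
#' @export
par_to_irradiance <- function(par, conversion = 4.57, step = 1) {
  if (!is.numeric(par) || length(par) != 1 || is.na(par) || par < 0) {
    stop("par_to_irradiance: par must be a single non-negative number",
         call. = FALSE)
  }
  if (conversion <= 0) stop("par_to_irradiance: conversion must be positive", call. = FALSE)
  total <- par / conversion
  wavelength <- seq(400, 700, by = step)
  structure(list(total = total,
                 wavelength = wavelength,
                 density = rep(total / 300, length(wavelength))),
            class = "spectral_irradiance")
}

#' @export
print.spectral_irradiance <- function(x, ...) {
  cat(sprintf("<spectral_irradiance: %.4g W m-2 over 400-700 nm>\n", x$total))
  invisible(x)
}

#' Instantaneous radiative forcing of an algal patch
#'
#' The extra radiative power absorbed by an algae-laden surface relative to a
#' clean reference, per unit area:
#' \deqn{IRF = \int_{400}^{700} E_e(\lambda)\,(\rho_{clean}(\lambda) - \rho_{algae}(\lambda))\, d\lambda}
#' evaluated by trapezoidal quadrature on the irradiance grid. The result may
#' be negative when the algal patch is brighter than the reference; it is
#' returned as-is (clamping is a melt-model concern, not a spectral one).
#'
#' @param clean Reflectance spectrum of the clean snow/ice reference.
#' @param algal Reflectance spectrum of the algal patch.
#' @param irr A [par_to_irradiance()] object.
#' @return IRF in W m⁻².
#' @export
compute_irf <- function(clean, algal, irr) {
  stopifnot_spectrum(clean)
  stopifnot_spectrum(algal)
  if (!inherits(irr, "spectral_irradiance")) {
    stop("compute_irf: irr must be a spectral_irradiance", call. = FALSE)
  }
  grid <- irr$wavelength
  for (s in list(clean, algal)) {
    if (min(s$wavelength) > min(grid) || max(s$wavelength) < max(grid)) {
      stop("compute_irf: spectra must cover 400-700 nm", call. = FALSE)
    }
  }
  rc <- spectrum_at(clean, grid)
  ra <- spectrum_at(algal, grid)
  pracma::trapz(grid, irr$density * (rc - ra))
}

#' Fit the IRF vs ln(cell density) regression
#'
#' Ordinary least squares of instantaneous radiative forcing on the natural
#' log of cell density, \eqn{IRF = a\,\ln(density) + b}, fitted at a stated
#' reference PAR (the irradiance at which the IRF observations were scaled or
#' measured). The residual standard deviation (n-2 denominator) is retained
#' for uncertainty propagation in the melt model.
#'
#' @param samples A data frame with columns `cell_density_per_ml` (> 0) and
#'   `irf_w_m2`; an optional `group` column is carried along but the fit is
#'   pooled.
#' @param reference_par Reference PAR in µmol m⁻² s⁻¹ (default 351, a typical
#'   median daylight value).
#' @return An `irf_regression` object: `slope_a`, `intercept_b`, `r_squared`,
#'   `residual_sd`, `reference_par`, `n`.
#' @export
fit_irf_density <- function(samples, reference_par = 351) {
  samples <- as.data.frame(samples)
  need <- c("cell_density_per_ml", "irf_w_m2")
  if (!all(need %in% names(samples))) {
    stop("fit_irf_density: samples need columns cell_density_per_ml and irf_w_m2",
         call. = FALSE)
  }
  d <- samples$cell_density_per_ml
  y <- samples$irf_w_m2
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("fit_irf_density: cell densities must be positive (log is taken)",
         call. = FALSE)
  }
  if (length(d) < 3) {
    stop("fit_irf_density: at least 3 samples are required", call. = FALSE)
  }
  x <- log(d)
  if (length(unique(x)) < 2) {
    stop("fit_irf_density: all densities equal; slope is not identifiable",
         call. = FALSE)
  }
  if (!is.numeric(reference_par) || reference_par <= 0) {
    stop("fit_irf_density: reference_par must be positive", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope_a = unname(stats::coef(fit)[2]),
                 intercept_b = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 residual_sd = sqrt(ss_res / (length(y) - 2)),
                 reference_par = reference_par,
                 n = length(y)),
            class = "irf_regression")
}

#' Build an IRF regression from known coefficients
#'
#' Wraps published or externally fitted coefficients in the object
#' [predict_irf()] and the melt model expect.
#'
#' @param slope_a Slope in W m⁻² per unit ln(cells ml⁻¹).
#' @param intercept_b Intercept in W m⁻².
#' @param residual_sd Residual SD in W m⁻² (default 0).
#' @param r_squared Coefficient of determination (default `NA`).
#' @param reference_par Reference PAR in µmol m⁻² s⁻¹.
#' @return An `irf_regression` object.
#' @export
irf_regression <- function(slope_a, intercept_b, residual_sd = 0,
                           r_squared = NA_real_, reference_par = 351) {
  if (residual_sd < 0) stop("irf_regression: residual_sd must be >= 0", call. = FALSE)
  if (reference_par <= 0) stop("irf_regression: reference_par must be positive", call. = FALSE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("irf_regression: r_squared must lie in [0, 1]", call. = FALSE)
  }
  structure(list(slope_a = slope_a, intercept_b = intercept_b,
                 r_squared = r_squared, residual_sd = residual_sd,
                 reference_par = reference_par, n = NA_integer_),
            class = "irf_regression")
}

#' @export
print.irf_regression <- function(x, ...) {
  cat(sprintf(
    "<irf_regression: IRF = %.4g ln(density) %+.4g W m-2; R2 = %.3g, residual SD = %.3g, reference PAR = %g>\n",
    x$slope_a, x$intercept_b, x$r_squared, x$residual_sd, x$reference_par))
  invisible(x)
}

#' Predict IRF at a given cell density and irradiance
#'
#' Evaluates the fitted log-linear relationship at the reference PAR, then
#' scales linearly with instantaneous PAR (IRF is proportional to the
#' radiation actually incident on the surface) and clamps negative
#' predictions to zero — algae are not allowed to brighten the surface.
#'
#' @param density Cell density in cells ml⁻¹, `> 0`.
#' @param reg An `irf_regression`.
#' @param par Instantaneous PAR in µmol m⁻² s⁻¹ (default: the regression's
#'   reference PAR).
#' @param irf_offset Additive shift (W m⁻², applied at reference PAR) used for
#'   uncertainty propagation; default 0.
#' @return Predicted IRF in W m⁻² (vectorised over `par`).
#' @export
predict_irf <- function(density, reg, par = reg$reference_par, irf_offset = 0) {
  if (!inherits(reg, "irf_regression")) {
    stop("predict_irf: reg must be an irf_regression", call. = FALSE)
  }
  if (!is.numeric(density) || length(density) != 1 || density <= 0) {
    stop("predict_irf: density must be a single positive number", call. = FALSE)
  }
  if (any(par < 0)) stop("predict_irf: par must be >= 0", call. = FALSE)
  raw <- reg$slope_a * log(density) + reg$intercept_b + irf_offset
  pmax(raw * par / reg$reference_par, 0)
}
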