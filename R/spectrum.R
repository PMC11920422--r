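#' Construct a spectrum
#'
#' A spectrum is the basic carrier for field-spectrometer data: a strictly
#' increasing wavelength grid (nm) paired with values that are either
#' reflectance (dimensionless HDRF, may mildly exceed 1) or radiance in
#' instrument-proportional units.
#'
#' Reflectance values above 1.5 are rejected: HDRF of bright snow can exceed
#' 1 under anisotropic illumination, but not by 50%, so larger values almost
#' always indicate a unit or calibration error.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing,
#'   length >= 2.
#' @param value Numeric vector of the same length; finite and non-negative.
#' @param kind `"reflectance"` or `"radiance"`.
#' @return An object of class `bioalbedo_spectrum` with fields `wavelength`,
#'   `value` and `kind`.
#' @examples
#' s <- new_spectrum(400:700, rep(0.8, 301))
#' broadband_mean(s, 400, 700)
#' @export
new_spectrum <- function(wavelength, value, kind = c("reflectance", "radiance")) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    stop("bioalbedo_spectrum: wavelength and value must have equal length",
         call. = FALSE)
  }
  if (length(wavelength) < 2) {
    stop("bioalbedo_spectrum: at least two samples are required", call. = FALSE)
  }
  if (anyNA(wavelength) || any(!is.finite(wavelength))) {
    stop("bioalbedo_spectrum: wavelengths must be finite", call. = FALSE)
  }
  if (any(diff(wavelength) <= 0)) {
    bad <- which(diff(wavelength) <= 0)[1] + 1L
    stop(sprintf(
      "bioalbedo_spectrum: wavelengths must be strictly increasing (violated at index %d, %g nm)",
      bad, wavelength[bad]), call. = FALSE)
  }
  if (anyNA(value) || any(!is.finite(value))) {
    stop("bioalbedo_spectrum: values must be finite", call. = FALSE)
  }
  if (any(value < 0)) {
    stop("bioalbedo_spectrum: values must be non-negative", call. = FALSE)
  }
  if (kind == "reflectance" && any(value > 1.5)) {
    stop(sprintf(
      "bioalbedo_spectrum: reflectance value %.4g at %g nm exceeds the 1.5 validity cap (unit error?)",
      max(value), wavelength[which.max(value)]), call. = FALSE)
  }
  structure(list(wavelength = wavelength, value = value, kind = kind),
            class = "bioalbedo_spectrum")
}

#' @export
print.bioalbedo_spectrum <- function(x, ...) {
  cat(sprintf("<bioalbedo_spectrum: %s, %d samples, %g-%g nm>\n",
              x$kind, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @export
as.data.frame.bioalbedo_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, value = x$value)
}

#' Test for spectrum objects
#' @param x Object to test.
#' @return `TRUE` for objects created by [new_spectrum()].
#' @export
is_spectrum <- function(x) inherits(x, "bioalbedo_spectrum")

stopifnot_spectrum <- function(x, arg = deparse(substitute(x))) {
  if (!is_spectrum(x)) {
    stop(sprintf("%s must be a bioalbedo_spectrum", arg), call. = FALSE)
  }
  invisible(x)
}

#' Reference-panel calibration
#'
#' Calibrated reflectance of the Spectralon reference panel, used to correct
#' the target/panel radiance ratio in [compute_hdrf()]. A nominally 98% panel
#' is represented by the default constant 0.98; a per-wavelength calibration
#' table may be supplied instead.
#'
#' @param beta Either a single number or a numeric vector paired with
#'   `wavelength`. Must lie in (0, 1.1].
#' @param wavelength Optional wavelength grid (nm) when `beta` is a vector.
#' @return An object of class `panel_calibration`.
#' @export
panel_calibration <- function(beta = 0.98, wavelength = NULL) {
  beta <- as.numeric(beta)
  if (any(!is.finite(beta)) || any(beta <= 0) || any(beta > 1.1)) {
    stop("panel_calibration: beta must lie in (0, 1.1]", call. = FALSE)
  }
  if (length(beta) > 1) {
    if (is.null(wavelength) || length(wavelength) != length(beta)) {
      stop("panel_calibration: per-wavelength beta requires a matching wavelength grid",
           call. = FALSE)
    }
    wavelength <- as.numeric(wavelength)
    if (any(diff(wavelength) <= 0)) {
      stop("panel_calibration: wavelengths must be strictly increasing",
           call. = FALSE)
    }
  } else {
    wavelength <- NULL
  }
  structure(list(beta = beta, wavelength = wavelength),
            class = "panel_calibration")
}

beta_on_grid <- function(cal, grid) {
  if (is.null(cal)) cal <- panel_calibration()
  if (is.numeric(cal) && length(cal) == 1) cal <- panel_calibration(beta = cal)
  if (!inherits(cal, "panel_calibration")) {
    stop("cal must be a panel_calibration (or a single beta value)", call. = FALSE)
  }
  if (is.null(cal$wavelength)) {
    rep(cal$beta, length(grid))
  } else {
    if (min(grid) < min(cal$wavelength) || max(grid) > max(cal$wavelength)) {
      stop("panel_calibration does not cover the target wavelength grid",
           call. = FALSE)
    }
    stats::approx(cal$wavelength, cal$beta, xout = grid)$y
  }
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; the standard pre-processing step that places all
#' spectra on a common working grid (1 nm by default elsewhere in the
#' package) before any spectral arithmetic. Extrapolation is refused.
#'
#' @param s A [new_spectrum()] object.
#' @param grid Strictly increasing wavelengths (nm) within the range of `s`.
#' @return A spectrum of the same kind on `grid`.
#' @export
resample_spectrum <- function(s, grid) {
  stopifnot_spectrum(s)
  grid <- as.numeric(grid)
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    stop("resample_spectrum: grid must be strictly increasing with length >= 2",
         call. = FALSE)
  }
  if (min(grid) < min(s$wavelength) || max(grid) > max(s$wavelength)) {
    stop(sprintf(
      "resample_spectrum: requested grid [%g, %g] nm extends beyond the data range [%g, %g] nm (extrapolation refused)",
      min(grid), max(grid), min(s$wavelength), max(s$wavelength)),
      call. = FALSE)
  }
  v <- stats::approx(s$wavelength, s$value, xout = grid)$y
  new_spectrum(grid, v, kind = s$kind)
}

# values of s at arbitrary wavelengths inside its range (no object overhead)
spectrum_at <- function(s, x) {
  stats::approx(s$wavelength, s$value, xout = x)$y
}

#' Hemispherical directional reflectance factor from bracketed panel scans
#'
#' Field "spectral reflectance" is measured as the ratio of target radiance to
#' the radiance of a calibrated Spectralon panel scanned immediately before
#' and after the target. Per wavelength,
#' \deqn{\rho_\lambda = \frac{L_{target,\lambda}}{\bar L_{panel,\lambda}} \beta_\lambda,}
#' where the panel radiance is the arithmetic mean of the bracketing scans and
#' \eqn{\beta_\lambda} is the panel's calibrated reflectance.
#'
#' All inputs must be radiance spectra. Panel scans (and a per-wavelength
#' calibration, if given) are resampled onto the target grid; a panel that
#' does not cover the target range is a grid-mismatch error.
#'
#' @param target Radiance spectrum of the surface.
#' @param panel_before,panel_after Radiance spectra of the reference panel
#'   bracketing the target scan.
#' @param cal A [panel_calibration()], a single beta value, or `NULL` for the
#'   default 0.98 panel.
#' @return A reflectance spectrum on the target grid.
#' @export
compute_hdrf <- function(target, panel_before, panel_after, cal = NULL) {
  stopifnot_spectrum(target)
  stopifnot_spectrum(panel_before)
  stopifnot_spectrum(panel_after)
  for (s in list(target, panel_before, panel_after)) {
    if (s$kind != "radiance") {
      stop("compute_hdrf: all inputs must be radiance spectra", call. = FALSE)
    }
  }
  grid <- target$wavelength
  covers <- function(p) min(p$wavelength) <= min(grid) && max(p$wavelength) >= max(grid)
  if (!covers(panel_before) || !covers(panel_after)) {
    stop("compute_hdrf: panel scans do not cover the target wavelength grid (grid mismatch)",
         call. = FALSE)
  }
  pb <- if (identical(panel_before$wavelength, grid)) panel_before$value else
    spectrum_at(panel_before, grid)
  pa <- if (identical(panel_after$wavelength, grid)) panel_after$value else
    spectrum_at(panel_after, grid)
  panel <- (pb + pa) / 2
  if (any(panel <= 0)) {
    lam <- grid[which(panel <= 0)[1]]
    stop(sprintf("compute_hdrf: panel radiance <= 0 at %g nm (cannot divide)", lam),
         call. = FALSE)
  }
  beta <- beta_on_grid(cal, grid)
  new_spectrum(grid, target$value / panel * beta, kind = "reflectance")
}

#' Average replicate spectra
#'
#' Field protocol records each patch in triplicate; this averages replicates
#' elementwise. All spectra must share one kind; they are resampled to the
#' grid of the first.
#'
#' @param spectra A list of spectra.
#' @return A single spectrum of the common kind.
#' @export
average_spectra <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0 || !all(vapply(spectra, is_spectrum, logical(1)))) {
    stop("average_spectra: need a non-empty list of spectra", call. = FALSE)
  }
  kinds <- unique(vapply(spectra, function(s) s$kind, character(1)))
  if (length(kinds) != 1) {
    stop("average_spectra: spectra mix radiance and reflectance", call. = FALSE)
  }
  grid <- spectra[[1]]$wavelength
  vals <- vapply(spectra, function(s) {
    if (identical(s$wavelength, grid)) s$value else resample_spectrum(s, grid)$value
  }, numeric(length(grid)))
  new_spectrum(grid, rowMeans(as.matrix(vals)), kind = kinds)
}

#' HDRF of replicate scans
#'
#' Convenience wrapper expressing the two possible orders of averaging for
#' triplicate measurements: compute per-replicate HDRF and average the
#' reflectances (the default), or average the radiances first and compute a
#' single HDRF.
#'
#' @param targets List of target radiance spectra (one per replicate).
#' @param panels_before,panels_after Lists of bracketing panel scans, same
#'   length as `targets`.
#' @param cal Panel calibration, as in [compute_hdrf()].
#' @param order `"average_hdrf"` (default) or `"average_radiance"`.
#' @return A reflectance spectrum.
#' @export
hdrf_replicates <- function(targets, panels_before, panels_after, cal = NULL,
                            order = c("average_hdrf", "average_radiance")) {
  order <- match.arg(order)
  n <- length(targets)
  if (length(panels_before) != n || length(panels_after) != n || n == 0) {
    stop("hdrf_replicates: targets and panel lists must share a positive length",
         call. = FALSE)
  }
  if (order == "average_hdrf") {
    average_spectra(lapply(seq_len(n), function(i) {
      compute_hdrf(targets[[i]], panels_before[[i]], panels_after[[i]], cal)
    }))
  } else {
    compute_hdrf(average_spectra(targets),
                 average_spectra(panels_before),
                 average_spectra(panels_after), cal)
  }
}

# trapezoidal mean of a spectrum over [lo, hi], with interpolated end points
trapezoid_window_mean <- function(s, lo, hi) {
  inner <- s$wavelength[s$wavelength > lo & s$wavelength < hi]
  x <- c(lo, inner, hi)
  y <- spectrum_at(s, x)
  pracma::trapz(x, y) / (hi - lo)
}

#' Wavelength-weighted mean reflectance over a window
#'
#' Trapezoidal mean of the spectrum over `[lo, hi]` nm — e.g. broadband VNIR
#' reflectance over 350-1000 nm, used to rank surface brightness and to set
#' the melt model's albedo.
#'
#' @param s A reflectance spectrum covering the window.
#' @param lo,hi Window limits in nm, `lo < hi`.
#' @return A single dimensionless mean.
#' @export
broadband_mean <- function(s, lo, hi) {
  stopifnot_spectrum(s)
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi) {
    stop("broadband_mean: need lo < hi", call. = FALSE)
  }
  if (lo < min(s$wavelength) || hi > max(s$wavelength)) {
    stop(sprintf(
      "broadband_mean: window [%g, %g] nm not covered by the spectrum [%g, %g] nm",
      lo, hi, min(s$wavelength), max(s$wavelength)), call. = FALSE)
  }
  trapezoid_window_mean(s, lo, hi)
}

#' Band-averaged reflectance
#'
#' Boxcar (trapezoidal) mean of a spectrum across a sensor band, simulating
#' the multispectral band value a satellite would record for that surface.
#'
#' @param s A reflectance spectrum covering the band.
#' @param band A [band_def()].
#' @return The band-mean reflectance.
#' @export
band_reflectance <- function(s, band) {
  if (!inherits(band, "band_def")) {
    stop("band_reflectance: band must be a band_def", call. = FALSE)
  }
  broadband_mean(s, band$lower, band$upper)
}
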