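#' Define a sensor band
#'
#' @param name Band identifier, e.g. `"B5"`.
#' @param center Band-centre wavelength in nm.
#' @param lower,upper Band limits in nm, `lower < center < upper`.
#' @return A `band_def` object.
#' @export
band_def <- function(name, center, lower, upper) {
  if (!(lower < center && center < upper)) {
    stop("band_def: need lower < center < upper", call. = FALSE)
  }
  structure(list(name = as.character(name), center = center,
                 lower = lower, upper = upper),
            class = "band_def")
}

#' Default band set for chlorophyll band-depth mapping
#'
#' Yellow / red / red-edge bands bracketing the 680 nm chlorophyll-a
#' absorption feature, at the published WorldView-2 band centres
#' (605 / 660 / 725 nm). The red band sits inside the feature and the two
#' neighbours define the continuum.
#'
#' @return A named list of three [band_def()]s: `B4`, `B5`, `B6`.
#' @export
worldview_bands <- function() {
  list(B4 = band_def("B4", 605, 585, 625),
       B5 = band_def("B5", 660, 630, 690),
       B6 = band_def("B6", 725, 705, 745))
}

#' Construct a multiband scene
#'
#' A scene is a stack of per-band reflectance grids sharing one shape, with
#' band-centre metadata, a pixel size, and a validity mask (e.g. the manually
#' digitised ice-cap outline; pixels outside it never enter any count).
#'
#' @param bands Named list of [band_def()]s.
#' @param values Named list of numeric matrices, one per band, same names and
#'   identical dimensions; reflectances must be `>= 0` where valid.
#' @param pixel_size Pixel edge length in metres, `> 0`.
#' @param valid Logical matrix of the same shape, or `NULL` for all-valid.
#' @return An `algae_scene` object.
#' @export
scene <- function(bands, values, pixel_size, valid = NULL) {
  if (!is.list(bands) || length(bands) < 3 ||
      !all(vapply(bands, inherits, logical(1), "band_def"))) {
    stop("scene: bands must be a list of at least three band_def objects",
         call. = FALSE)
  }
  if (is.null(names(values)) || !setequal(names(values), names(bands))) {
    stop("scene: values must be a named list matching the band names", call. = FALSE)
  }
  dims <- lapply(values, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("scene: all band arrays must be matrices of one common shape", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("scene: pixel_size must be positive", call. = FALSE)
  }
  shp <- dims[[1]]
  if (is.null(valid)) {
    valid <- matrix(TRUE, shp[1], shp[2])
  }
  if (!is.logical(valid) || !identical(dim(valid), as.integer(shp))) {
    stop("scene: valid must be a logical matrix of the band shape", call. = FALSE)
  }
  for (nm in names(values)) {
    v <- values[[nm]][valid]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("scene: band %s has non-finite or negative reflectance in valid pixels", nm),
           call. = FALSE)
    }
  }
  structure(list(bands = bands, values = values,
                 pixel_size = pixel_size, valid = valid),
            class = "algae_scene")
}

#' @export
print.algae_scene <- function(x, ...) {
  d <- dim(x$values[[1]])
  cat(sprintf("<algae_scene: %d x %d pixels (%g m), bands %s>\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$bands), collapse = "/")))
  invisible(x)
}

#' Continuum-scaled band depth at the chlorophyll band
#'
#' The scaled integral of the red band: the linear continuum between the
#' flanking band centres is
#' \deqn{C = \frac{R_{B4}(\lambda_{B6}-\lambda_{B5}) + R_{B6}(\lambda_{B5}-\lambda_{B4})}{\lambda_{B6}-\lambda_{B4}},}
#' and the index is \eqn{I_{B5} = (C - R_{B5})/C}: positive exactly when the
#' red band sits below the continuum, i.e. when a chlorophyll-a absorption
#' feature is present.
#'
#' Vectorised over the band values. Pixels where the continuum is not
#' positive are undefined and returned as `NA` (excluded, not an error).
#'
#' @param r_b4,r_b5,r_b6 Band reflectances (scalars, vectors or matrices of a
#'   common shape).
#' @param centers Numeric length-3 vector of band-centre wavelengths
#'   (strictly increasing).
#' @return The scaled band depth, same shape as the inputs; `NA` marks an
#'   undefined pixel.
#' @examples
#' scaled_band_integral(0.6, 0.5, 0.6, c(605, 660, 725)) # 1/6
#' @export
scaled_band_integral <- function(r_b4, r_b5, r_b6, centers) {
  if (length(centers) != 3 || any(diff(centers) <= 0)) {
    stop("scaled_band_integral: centers must be three strictly increasing wavelengths",
         call. = FALSE)
  }
  l4 <- centers[1]; l5 <- centers[2]; l6 <- centers[3]
  cont <- (r_b4 * (l6 - l5) + r_b6 * (l5 - l4)) / (l6 - l4)
  out <- (cont - r_b5) / cont
  out[cont <= 0] <- NA_real_
  out
}

#' Classify a scene into algal presence/absence
#'
#' Computes the scaled band depth per pixel and flags a pixel as containing
#' algae when the index is strictly positive within the valid area. Pixels
#' with a non-positive continuum are undefined and excluded from both the
#' algal count and the valid-pixel denominator. Per-pixel cell densities are
#' deliberately not estimated: the index-density correlation is too weak for
#' that, so the product is a binary presence/absence map. The nominal
#' detection floor of the method (5452 cells ml⁻¹, the published
#' index-vs-density intercept) is recorded as metadata only.
#'
#' @param sc An [scene()] object.
#' @param band_names Character length-3: the flanking and central band names,
#'   in wavelength order (default `c("B4", "B5", "B6")`).
#' @return A `bloom_map`: `algae_mask` (logical matrix), `i_b5` (numeric
#'   matrix, `NA` where undefined/invalid), `extent_km2`, `fraction`,
#'   `n_algae`, `n_valid`, `pixel_size`, `detection_floor_cells_ml`.
#' @export
classify_scene <- function(sc, band_names = c("B4", "B5", "B6")) {
  if (!inherits(sc, "algae_scene")) {
    stop("classify_scene: sc must be an algae_scene", call. = FALSE)
  }
  if (!all(band_names %in% names(sc$bands))) {
    stop(sprintf("classify_scene: scene is missing band(s) %s",
                 paste(setdiff(band_names, names(sc$bands)), collapse = ", ")),
         call. = FALSE)
  }
  centers <- vapply(sc$bands[band_names], function(b) b$center, numeric(1))
  i_b5 <- scaled_band_integral(sc$values[[band_names[1]]],
                               sc$values[[band_names[2]]],
                               sc$values[[band_names[3]]],
                               centers)
  i_b5[!sc$valid] <- NA_real_
  defined <- sc$valid & !is.na(i_b5)
  algae <- defined & i_b5 > 0
  ext <- bloom_extent(algae, sc$pixel_size, sum(defined))
  structure(list(algae_mask = algae, i_b5 = i_b5,
                 extent_km2 = ext$extent_km2, fraction = ext$fraction,
                 n_algae = sum(algae), n_valid = sum(defined),
                 pixel_size = sc$pixel_size,
                 detection_floor_cells_ml = 5452),
            class = "bloom_map")
}

#' @export
print.bloom_map <- function(x, ...) {
  cat(sprintf("<bloom_map: %d / %d valid pixels algal (%.1f%%), extent %.4g km2>\n",
              x$n_algae, x$n_valid, 100 * x$fraction, x$extent_km2))
  invisible(x)
}

#' Bloom extent from an algal mask
#'
#' Extent is the summed area of algae-classified pixels; fraction is their
#' share of the valid (defined) pixels.
#'
#' @param mask Logical matrix/vector of algae-classified pixels, or a
#'   `bloom_map`.
#' @param pixel_size Pixel edge length in metres.
#' @param valid_count Number of valid pixels (denominator of the fraction).
#' @return List with `extent_km2` and `fraction`.
#' @export
bloom_extent <- function(mask, pixel_size, valid_count) {
  if (inherits(mask, "bloom_map")) {
    valid_count <- mask$n_valid
    pixel_size <- mask$pixel_size
    mask <- mask$algae_mask
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("bloom_extent: pixel_size must be positive", call. = FALSE)
  }
  n_algae <- sum(mask, na.rm = TRUE)
  if (valid_count <= 0) {
    stop("bloom_extent: no valid pixels; fraction undefined", call. = FALSE)
  }
  list(extent_km2 = n_algae * pixel_size^2 / 1e6,
       fraction = n_algae / valid_count)
}
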