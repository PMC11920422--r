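#' Write a spectrum to delimited text
#'
#' Two-column CSV with header `wavelength_nm,value`, preceded by a three-line
#' `#` comment header carrying the quantity kind. Values are written at full
#' double precision so write/read round-trips are lossless.
#'
#' @param s A spectrum.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot_spectrum(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# bioalbedo spectrum",
               sprintf("# quantity_kind: %s", s$kind),
               "# units: wavelength nm, value dimensionless or instrument radiance",
               "wavelength_nm,value"), con)
  writeLines(sprintf("%.17g,%.17g", s$wavelength, s$value), con)
  invisible(path)
}

#' Read a spectrum from delimited text
#'
#' Accepts the format written by [write_spectrum()]: optional `#` comment
#' lines (a `quantity_kind:` comment sets the kind), a `wavelength_nm,value`
#' header, then one sample per line. Parse errors report the offending line
#' number.
#'
#' @param path File path.
#' @param kind Override the quantity kind; default: taken from the comment
#'   header, falling back to `"reflectance"`.
#' @return A spectrum.
#' @export
read_spectrum <- function(path, kind = NULL) {
  if (!file.exists(path)) stop(sprintf("read_spectrum: no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  comment <- grepl("^\\s*#", lines)
  if (is.null(kind)) {
    km <- regmatches(lines[comment],
                     regexpr("quantity_kind:\\s*\\S+", lines[comment]))
    kind <- if (length(km) > 0) sub("quantity_kind:\\s*", "", km[1]) else "reflectance"
  }
  body_idx <- which(!comment)
  if (length(body_idx) < 3) {
    stop(sprintf("read_spectrum: %s: too few data lines", path), call. = FALSE)
  }
  header_line <- body_idx[1]
  if (!grepl("^\\s*wavelength_nm\\s*,\\s*value\\s*$", lines[header_line])) {
    stop(sprintf("read_spectrum: %s: line %d: malformed header (expected 'wavelength_nm,value')",
                 path, header_line), call. = FALSE)
  }
  data_idx <- body_idx[-1]
  parts <- strsplit(lines[data_idx], ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad) > 0) {
    stop(sprintf("read_spectrum: %s: line %d: expected two comma-separated values",
                 path, data_idx[bad[1]]), call. = FALSE)
  }
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1)))
  v <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  if (anyNA(w) || anyNA(v)) {
    first <- which(is.na(w) | is.na(v))[1]
    stop(sprintf("read_spectrum: %s: line %d: missing or non-numeric value",
                 path, data_idx[first]), call. = FALSE)
  }
  if (any(diff(w) <= 0)) {
    first <- which(diff(w) <= 0)[1] + 1L
    stop(sprintf("read_spectrum: %s: line %d: wavelengths not strictly increasing",
                 path, data_idx[first]), call. = FALSE)
  }
  new_spectrum(w, v, kind = kind)
}

#' Write a weather series
#'
#' CSV with header `timestamp,par_umol_m2_s,air_temp_c,wind_m_s,rh_pct` and
#' ISO-8601 UTC timestamps.
#'
#' @param weather A weather tibble (see [make_weather_series()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(weather, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("timestamp,par_umol_m2_s,air_temp_c,wind_m_s,rh_pct", con)
  writeLines(sprintf("%s,%.17g,%.17g,%.17g,%.17g",
                     format(weather$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                     weather$par, weather$air_temp, weather$wind, weather$rh),
             con)
  invisible(path)
}

#' Read and validate a weather series
#'
#' Parses the format written by [write_weather()] and enforces a regular
#' cadence (default 300 s). Gaps of at most `max_gap` consecutive missing
#' steps are filled by linear interpolation with a `bioalbedo_gapfill`
#' warning; larger gaps, or timestamps off the regular grid, are errors.
#'
#' @param path File path.
#' @param spacing Expected cadence in seconds (default 300).
#' @param max_gap Maximum number of consecutive missing records to fill
#'   (default 2).
#' @return A weather tibble with no missing steps.
#' @export
read_weather <- function(path, spacing = 300, max_gap = 2) {
  if (!file.exists(path)) stop(sprintf("read_weather: no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "par_umol_m2_s", "air_temp_c", "wind_m_s", "rh_pct")
  if (!all(need %in% names(df))) {
    stop(sprintf("read_weather: %s: header must contain %s",
                 path, paste(need, collapse = ",")), call. = FALSE)
  }
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(ts)) {
    stop(sprintf("read_weather: %s: unparseable timestamp at data row %d",
                 path, which(is.na(ts))[1]), call. = FALSE)
  }
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    stop(sprintf("read_weather: %s: timestamps must be strictly increasing", path),
         call. = FALSE)
  }
  off <- (as.numeric(ts) - as.numeric(ts[1])) %% spacing
  if (any(abs(off) > 1e-6 & abs(off - spacing) > 1e-6)) {
    stop(sprintf("read_weather: %s: timestamps are not on a regular %d-s grid",
                 path, spacing), call. = FALSE)
  }
  steps <- round((as.numeric(ts) - as.numeric(ts[1])) / spacing)
  gaps <- diff(steps) - 1
  if (any(gaps > max_gap)) {
    i <- which(gaps > max_gap)[1]
    stop(sprintf("read_weather: %s: gap of %d missing records after %s exceeds the fill limit (%d)",
                 path, gaps[i], format(ts[i], "%Y-%m-%dT%H:%M:%SZ"), max_gap),
         call. = FALSE)
  }
  full_steps <- 0:steps[length(steps)]
  n_missing <- length(full_steps) - length(steps)
  fill <- function(v) stats::approx(steps, v, xout = full_steps)$y
  out <- tibble::tibble(
    timestamp = ts[1] + spacing * full_steps,
    par = fill(df$par_umol_m2_s),
    air_temp = fill(df$air_temp_c),
    wind = fill(df$wind_m_s),
    rh = fill(df$rh_pct))
  if (n_missing > 0) {
    warning(sprintf("bioalbedo_gapfill: %s: filled %d missing record(s) by linear interpolation",
                    path, n_missing))
  }
  if (any(out$par < 0) || any(out$rh < 0 | out$rh > 100)) {
    stop(sprintf("read_weather: %s: PAR must be >= 0 and RH within [0, 100]", path),
         call. = FALSE)
  }
  out
}

#' Write a density-IRF sample table
#' @param samples Tibble with `cell_density_per_ml`, `irf_w_m2`, `group`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_density_samples <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("cell_density_per_ml,irf_w_m2,group", con)
  writeLines(sprintf("%.17g,%.17g,%s", samples$cell_density_per_ml,
                     samples$irf_w_m2, samples$group), con)
  invisible(path)
}

#' Read a density-IRF sample table
#' @param path File path.
#' @return A tibble with `cell_density_per_ml`, `irf_w_m2`, `group`.
#' @export
read_density_samples <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_density_samples: no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_density_per_ml", "irf_w_m2")
  if (!all(need %in% names(df))) {
    stop(sprintf("read_density_samples: %s: header must contain %s",
                 path, paste(need, collapse = ",")), call. = FALSE)
  }
  if (is.null(df$group)) df$group <- NA_character_
  tibble::as_tibble(df[c("cell_density_per_ml", "irf_w_m2", "group")])
}

#' Write a scene to a plain-text container
#'
#' A scene is stored as a directory: `scene.json` (band definitions, pixel
#' size, shape), one `band_<name>.csv` grid per band, and `valid.csv`
#' (0/1 validity mask). All grids are comma-separated, row-major, full
#' precision.
#'
#' @param sc An [scene()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(sc, dir) {
  if (!inherits(sc, "algae_scene")) stop("write_scene: sc must be an algae_scene", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    pixel_size_m = sc$pixel_size,
    shape = dim(sc$values[[1]]),
    bands = unname(lapply(sc$bands, function(b) {
      list(name = b$name, center_nm = b$center, lower_nm = b$lower, upper_nm = b$upper)
    })))
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  write_grid <- function(m, path) {
    writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")),
               path)
  }
  for (nm in names(sc$values)) {
    write_grid(sc$values[[nm]], file.path(dir, sprintf("band_%s.csv", nm)))
  }
  write_grid(sc$valid + 0, file.path(dir, "valid.csv"))
  invisible(dir)
}

read_grid <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

#' Read a scene from its plain-text container
#' @param dir Directory written by [write_scene()].
#' @return An [scene()] object.
#' @export
read_scene <- function(dir) {
  meta_path <- file.path(dir, "scene.json")
  if (!file.exists(meta_path)) {
    stop(sprintf("read_scene: %s does not contain scene.json", dir), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  bands <- lapply(seq_len(nrow(meta$bands)), function(i) {
    b <- meta$bands[i, ]
    band_def(b$name, b$center_nm, b$lower_nm, b$upper_nm)
  })
  names(bands) <- meta$bands$name
  values <- lapply(names(bands), function(nm) {
    read_grid(file.path(dir, sprintf("band_%s.csv", nm)))
  })
  names(values) <- names(bands)
  valid_path <- file.path(dir, "valid.csv")
  valid <- if (file.exists(valid_path)) read_grid(valid_path) > 0 else NULL
  scene(bands, values, meta$pixel_size_m, valid)
}

#' Write a bloom map
#'
#' The mask goes to `mask.csv` as byte codes (1 algae, 0 not, 255 invalid or
#' undefined) and the summary (extent, fraction, counts) to `summary.csv`.
#'
#' @param map A `bloom_map` from [classify_scene()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bloom_map <- function(map, dir) {
  if (!inherits(map, "bloom_map")) stop("write_bloom_map: map must be a bloom_map", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  code <- matrix(0L, nrow(map$algae_mask), ncol(map$algae_mask))
  code[map$algae_mask] <- 1L
  code[is.na(map$i_b5)] <- 255L
  writeLines(apply(code, 1, paste, collapse = ","), file.path(dir, "mask.csv"))
  summary <- data.frame(extent_km2 = map$extent_km2, fraction = map$fraction,
                        n_algae = map$n_algae, n_valid = map$n_valid,
                        pixel_size_m = map$pixel_size,
                        detection_floor_cells_ml = map$detection_floor_cells_ml)
  utils::write.csv(summary, file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}

#' Default run configuration
#'
#' All tunables of the pipeline in one nested list: physical constants, band
#' definitions, regression coefficients, surface parameters and seeds.
#' Serialised losslessly to JSON by [write_run_config()].
#'
#' @return A nested named list.
#' @export
default_run_config <- function() {
  list(
    constants = melt_constants(),
    bands = lapply(worldview_bands(), function(b) {
      list(name = b$name, center_nm = b$center, lower_nm = b$lower, upper_nm = b$upper)
    }),
    regression = list(slope_a = 5.52, intercept_b = -24.03,
                      residual_sd = 10.8, reference_par = 351),
    surfaces = list(
      snow = list(albedo = 0.78, density = 400),
      weathering_crust = list(albedo = 0.55, density = 550)),
    cell_density = 2.5e5,
    cell_density_sd = 2.7e5,
    panel_beta = 0.98,
    pixel_size_m = 1.6,
    seed = 1)
}

#' Write a run configuration
#' @param config Nested list (see [default_run_config()]).
#' @param path Output file path (JSON).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a run configuration
#' @param path JSON file written by [write_run_config()].
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_run_config: no such file: %s", path), call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
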