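#' Scanner configuration
#'
#' Builds a validated configuration for a cylindrical PET scanner made of
#' flat monolithic crystal slabs.  Two named presets are shipped:
#' `"design_a"` (7 rings, 36.2 cm axial FOV) and `"design_b"` (14 rings,
#' 72.6 cm), both with 40 modules of 50 x 50 x 16 mm LYSO per ring on a
#' 70 cm bore, 200 ps CTR, 3 ns coincidence window, 11.5 % energy
#' resolution with a 440-650 keV window and 300 ns paralysable dead time.
#'
#' @param preset `"design_a"`, `"design_b"`, or `NULL` for a fully custom
#'   configuration
#' @param ... overrides of individual fields (see Details)
#' @details Fields: `bore_diameter`, `modules_per_ring`, `n_rings`,
#'   `crystal_width_transaxial`, `crystal_width_axial`, `crystal_thickness`,
#'   `ring_gap` (all mm); `ctr_fwhm_ps`; `coincidence_window_ns`;
#'   `energy_resolution_frac` (at 511 keV); `energy_window` (keV pair);
#'   `dead_time_ns`; `dead_time_model` (only `"paralysable"`).
#' @return object of class `scanner_config`
#' @export
scanner_config <- function(preset = c("design_a", "design_b"), ...) {
  cfg <- list(
    bore_diameter = 700,
    modules_per_ring = 40L,
    n_rings = 7L,
    crystal_width_transaxial = 50,
    crystal_width_axial = 50,
    crystal_thickness = 16,
    ring_gap = 2,
    ctr_fwhm_ps = 200,
    coincidence_window_ns = 3,
    energy_resolution_frac = 0.115,
    energy_window = c(440, 650),
    dead_time_ns = 300,
    dead_time_model = "paralysable"
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    if (preset == "design_b") cfg$n_rings <- 14L
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, dots)
  }
  validate_scanner_config(cfg)
  structure(cfg, class = "scanner_config")
}

validate_scanner_config <- function(cfg) {
  pos <- c("bore_diameter", "modules_per_ring", "n_rings",
           "crystal_width_transaxial", "crystal_width_axial",
           "crystal_thickness", "ctr_fwhm_ps", "coincidence_window_ns",
           "energy_resolution_frac", "dead_time_ns")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a single positive number")
    }
  }
  if (cfg$ring_gap < 0) stop("ring_gap must be non-negative")
  if (length(cfg$energy_window) != 2L ||
      cfg$energy_window[1] >= cfg$energy_window[2]) {
    stop("energy_window must be an increasing (low, high) keV pair")
  }
  if (!identical(cfg$dead_time_model, "paralysable")) {
    stop("only the paralysable dead time model is supported")
  }
  if (cfg$modules_per_ring * cfg$crystal_width_transaxial >
      pi * cfg$bore_diameter) {
    stop("modules do not fit on the ring: ",
         "modules_per_ring x crystal_width_transaxial exceeds the bore ",
         "circumference")
  }
  invisible(cfg)
}

#' Build the scanner geometry from a configuration
#'
#' Places `n_rings` x `modules_per_ring` flat crystal slabs tangent to the
#' bore cylinder at equal azimuthal spacing (module k at azimuth
#' 2 pi k / modules_per_ring, k = 0 on +x), rings centred on the axial
#' origin with `ring_gap` between consecutive rings.  The axial field of
#' view is `n_rings * crystal_width_axial + (n_rings - 1) * ring_gap`.
#'
#' @param config a [scanner_config()]
#' @return object of class `scanner_geometry` with the module table
#'   (`ring`, `azimuth`, centre coordinates, inward normal), ring axial
#'   centres and the derived `afov` (mm)
#' @export
build_scanner <- function(config) {
  validate_scanner_config(config)
  n_rings <- config$n_rings
  mpr <- config$modules_per_ring
  pitch <- config$crystal_width_axial + config$ring_gap
  afov <- n_rings * config$crystal_width_axial + (n_rings - 1) * config$ring_gap
  ring_z <- (seq_len(n_rings) - (n_rings + 1) / 2) * pitch
  r_in <- config$bore_diameter / 2
  r_mid <- r_in + config$crystal_thickness / 2

  azim <- rep(seq_len(mpr) - 1L, times = n_rings)
  ring <- rep(seq_len(n_rings) - 1L, each = mpr)
  phi <- 2 * pi * azim / mpr
  modules <- data.frame(
    module = seq_len(n_rings * mpr),
    ring = ring,
    azimuth = azim,
    cx = r_mid * cos(phi),
    cy = r_mid * sin(phi),
    cz = ring_z[ring + 1L],
    nx = -cos(phi),
    ny = -sin(phi),
    nz = 0
  )
  structure(
    list(
      config = config,
      afov = afov,
      ring_z = ring_z,
      modules = modules,
      n_modules = nrow(modules)
    ),
    class = "scanner_geometry"
  )
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf(
    "PET scanner: %d rings x %d modules (%.0f x %.0f x %.0f mm slabs),\n  bore %.0f mm, aFOV %.1f mm\n",
    x$config$n_rings, x$config$modules_per_ring,
    x$config$crystal_width_transaxial, x$config$crystal_width_axial,
    x$config$crystal_thickness, x$config$bore_diameter, x$afov))
  invisible(x)
}

# compact representation handed to the C++ core
geom_list <- function(geom) {
  cfg <- geom$config
  list(
    r_inner = cfg$bore_diameter / 2,
    r_outer = cfg$bore_diameter / 2 + cfg$crystal_thickness,
    half_transaxial = cfg$crystal_width_transaxial / 2,
    half_axial = cfg$crystal_width_axial / 2,
    modules_per_ring = as.integer(cfg$modules_per_ring),
    ring_z = geom$ring_z
  )
}

#' Geometric summary of a scanner design
#'
#' Derives the axial FOV, the opening angle `atan(aFOV / bore_diameter)`
#' (reported to the nearest degree), the total detector surface
#' (modules x transaxial width x axial width) and the scintillator volume
#' (surface x crystal thickness).
#'
#' @param geom a [build_scanner()] geometry
#' @return object of class `geometry_report`: `afov_cm`,
#'   `opening_angle_deg` (nearest degree), `opening_angle_exact_deg`,
#'   `detector_surface_1e6_mm2`, `scintillator_volume_1e6_mm3`
#' @export
derived_metrics <- function(geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  cfg <- geom$config
  surface <- geom$n_modules * cfg$crystal_width_transaxial *
    cfg$crystal_width_axial
  volume <- surface * cfg$crystal_thickness
  angle <- atan(geom$afov / cfg$bore_diameter) * 180 / pi
  structure(
    list(
      afov_cm = geom$afov / 10,
      opening_angle_deg = round(angle),
      opening_angle_exact_deg = angle,
      detector_surface_1e6_mm2 = surface / 1e6,
      scintillator_volume_1e6_mm3 = volume / 1e6
    ),
    class = "geometry_report"
  )
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("aFOV %.1f cm | opening angle %d deg | surface %.2f x10^6 mm^2 | volume %.2f x10^6 mm^3\n",
              x$afov_cm, x$opening_angle_deg, x$detector_surface_1e6_mm2,
              x$scintillator_volume_1e6_mm3))
  invisible(x)
}

#' First crystal slab met by a ray
#'
#' Traces rays from inside the bore and reports, per ray, the first module
#' whose crystal slab is entered, the entry point and the chord length
#' through the slab; module 0 marks rays that escape axially or pass
#' between modules.
#'
#' @param geom scanner geometry
#' @param origin numeric length-3 point, or an n x 3 matrix of origins
#'   (inside the bore)
#' @param direction unit vector, or an n x 3 matrix of unit vectors
#' @return list with `module` (integer, 0 = none), `entry` (n x 3),
#'   `chord` and `t_entry` (mm)
#' @export
intersect_ray <- function(geom, origin, direction) {
  stopifnot(inherits(geom, "scanner_geometry"))
  o <- rbind_point(origin)
  d <- rbind_point(direction)
  if (nrow(o) != nrow(d)) stop("origin and direction row counts differ")
  nrm <- sqrt(rowSums(d^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit vectors")
  r_in <- geom$config$bore_diameter / 2
  if (any(sqrt(o[, 1]^2 + o[, 2]^2) >= r_in)) {
    stop("ray origins must lie inside the bore")
  }
  intersect_rays_cpp(geom_list(geom), o, d)
}

rbind_point <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    p
  } else {
    stopifnot(length(p) == 3L)
    matrix(as.numeric(p), 1L, 3L)
  }
}

#' Write / read scanner configurations as key-value text
#'
#' @param config a [scanner_config()]
#' @param path file path
#' @return `read_scanner_config` returns a `scanner_config`
#' @export
write_scanner_config <- function(config, path) {
  validate_scanner_config(config)
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(config[[k]], collapse = " "))
  }, character(1))
  writeLines(c("# monopet scanner configuration", lines), path)
  invisible(path)
}

#' @rdname write_scanner_config
#' @export
read_scanner_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- list()
  for (p in kv) {
    if (length(p) != 2L) stop("malformed config line: ", paste(p, collapse = "="))
    key <- trimws(p[1])
    val <- trimws(p[2])
    cfg[[key]] <- if (key == "dead_time_model") val else
      as.numeric(strsplit(val, "\\s+")[[1]])
  }
  cfg$modules_per_ring <- as.integer(cfg$modules_per_ring)
  cfg$n_rings <- as.integer(cfg$n_rings)
  cfg <- structure(cfg, class = "scanner_config")
  validate_scanner_config(cfg)
  cfg
}
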