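#' Phantom primitives
#'
#' A phantom is an ordered set of homogeneous geometric primitives; where
#' primitives overlap, the one listed *later* wins (priority order).  All
#' cylinders have their axis along z.  The torso outline is the standard
#' NEMA body cross-section: two half-circles of radius `R` centred at
#' (+-`a`, 0) joined by straight walls, giving a 2(a+R) x 2R envelope.
#'
#' @param center length-3 centre (mm)
#' @param radius radius (mm)
#' @param half_length half axial extent (mm)
#' @param material material name, see [materials_511()]
#' @param activity activity concentration in kBq/mL (numerically Bq/mm^3);
#'   0 for cold material
#' @return one-row data.frame usable in [phantom_model()]
#' @export
prim_cylinder <- function(center, radius, half_length, material,
                          activity = 0) {
  prim_row(0L, c(center, radius, half_length, 0, 0), material, activity)
}

#' @rdname prim_cylinder
#' @export
prim_sphere <- function(center, radius, material, activity = 0) {
  prim_row(1L, c(center, radius, 0, 0, 0), material, activity)
}

#' @rdname prim_cylinder
#' @param half_widths length-3 half widths of the box (mm)
#' @export
prim_box <- function(center, half_widths, material, activity = 0) {
  prim_row(2L, c(center, half_widths, 0), material, activity)
}

#' @rdname prim_cylinder
#' @param cz axial centre of the torso section (mm)
#' @param a half width of the straight section (mm)
#' @param R radius of the half-circles (mm)
#' @export
prim_torso <- function(cz, half_length, a = 35, R = 115, material = "water",
                       activity = 0) {
  prim_row(3L, c(cz, half_length, a, R, 0, 0, 0), material, activity)
}

prim_row <- function(shape, par, material, activity) {
  m <- material(material)
  stopifnot(activity >= 0)
  data.frame(shape = shape, p1 = par[1], p2 = par[2], p3 = par[3],
             p4 = par[4], p5 = par[5], p6 = par[6], p7 = par[7],
             material = m$name, mu = m$mu_511,
             compton_fraction = m$compton_fraction, activity = activity,
             stringsAsFactors = FALSE)
}

#' Assemble a phantom from primitives
#'
#' @param ... primitive rows ([prim_cylinder()] etc.) or data.frames of them,
#'   in priority order (later overrides earlier in overlaps)
#' @return object of class `phantom_model`
#' @export
phantom_model <- function(...) {
  prims <- do.call(rbind, list(...))
  structure(list(primitives = prims), class = "phantom_model")
}

#' @rdname phantom_model
#' @export
empty_phantom <- function() {
  structure(list(primitives = NULL), class = "phantom_model")
}

n_primitives <- function(phantom) {
  if (is.null(phantom$primitives)) 0L else nrow(phantom$primitives)
}

# primitive matrix handed to C++ (shape, p1..p7, mu, compton_fraction)
phantom_matrix <- function(phantom) {
  if (n_primitives(phantom) == 0L) {
    return(matrix(0, 0, 10))
  }
  p <- phantom$primitives
  as.matrix(p[, c("shape", paste0("p", 1:7), "mu", "compton_fraction")])
}

# mu_max + bounding box handed to C++
phantom_aux <- function(phantom) {
  if (n_primitives(phantom) == 0L) {
    return(c(0, 0, 0, 0, 0, 0, 0))
  }
  p <- phantom$primitives
  bb <- primitive_bboxes(phantom)
  c(max(p$mu),
    min(bb[, 1]), max(bb[, 2]), min(bb[, 3]), max(bb[, 4]),
    min(bb[, 5]), max(bb[, 6]))
}

primitive_bboxes <- function(phantom) {
  p <- phantom$primitives
  t(vapply(seq_len(nrow(p)), function(i) {
    r <- p[i, ]
    switch(as.character(r$shape),
      "0" = c(r$p1 - r$p4, r$p1 + r$p4, r$p2 - r$p4, r$p2 + r$p4,
              r$p3 - r$p5, r$p3 + r$p5),
      "1" = c(r$p1 - r$p4, r$p1 + r$p4, r$p2 - r$p4, r$p2 + r$p4,
              r$p3 - r$p4, r$p3 + r$p4),
      "2" = c(r$p1 - r$p4, r$p1 + r$p4, r$p2 - r$p5, r$p2 + r$p5,
              r$p3 - r$p6, r$p3 + r$p6),
      "3" = c(-(r$p3 + r$p4), r$p3 + r$p4, -r$p4, r$p4,
              r$p1 - r$p2, r$p1 + r$p2))
  }, numeric(6)))
}

#' Locate points in a phantom
#'
#' Vectorised point-in-phantom test honouring the priority order: the
#' returned index is the highest-priority (last listed) primitive that
#' contains each point, 0 where no primitive does.
#'
#' @param phantom a [phantom_model()]
#' @param points n x 3 matrix of points (mm)
#' @return integer vector of primitive indices (0 = outside)
#' @export
point_in_phantom <- function(phantom, points) {
  points <- rbind_point(points)
  idx <- integer(nrow(points))
  if (n_primitives(phantom) == 0L) return(idx)
  p <- phantom$primitives
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  for (i in seq_len(nrow(p))) {
    r <- p[i, ]
    inside <- switch(as.character(r$shape),
      "0" = (x - r$p1)^2 + (y - r$p2)^2 <= r$p4^2 & abs(z - r$p3) <= r$p5,
      "1" = (x - r$p1)^2 + (y - r$p2)^2 + (z - r$p3)^2 <= r$p4^2,
      "2" = abs(x - r$p1) <= r$p4 & abs(y - r$p2) <= r$p5 &
            abs(z - r$p3) <= r$p6,
      "3" = {
        xp <- pmax(abs(x) - r$p3, 0)
        xp^2 + y^2 <= r$p4^2 & abs(z - r$p1) <= r$p2
      })
    idx[inside] <- i
  }
  idx
}

#' Analytic volume of a single primitive (mm^3)
#' @param phantom a [phantom_model()]
#' @param i primitive index
#' @export
primitive_volume <- function(phantom, i) {
  r <- phantom$primitives[i, ]
  switch(as.character(r$shape),
    "0" = pi * r$p4^2 * 2 * r$p5,
    "1" = 4 / 3 * pi * r$p4^3,
    "2" = 8 * r$p4 * r$p5 * r$p6,
    "3" = (pi * r$p4^2 + 4 * r$p3 * r$p4) * 2 * r$p2)
}

#' Monte Carlo volumes of the phantom regions
#'
#' Estimates the effective volume of each primitive *as a region*, i.e. the
#' volume where that primitive has priority, by uniform sampling in the
#' phantom bounding box.
#'
#' @param phantom a [phantom_model()]
#' @param n number of sample points
#' @param seed RNG seed
#' @return numeric vector of volumes (mm^3) per primitive
#' @export
region_volumes <- function(phantom, n = 2e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aux <- phantom_aux(phantom)
  bb <- aux[2:7]
  vol_bb <- (bb[2] - bb[1]) * (bb[4] - bb[3]) * (bb[6] - bb[5])
  pts <- cbind(runif(n, bb[1], bb[2]), runif(n, bb[3], bb[4]),
               runif(n, bb[5], bb[6]))
  idx <- point_in_phantom(phantom, pts)
  vapply(seq_len(n_primitives(phantom)),
         function(i) vol_bb * mean(idx == i), numeric(1))
}

# ---------------------------------------------------------------------------
# sources

#' Emission source models
#'
#' `make_sensitivity_source` builds the 70 cm axial line source of
#' back-to-back 511 keV gammas (5 MBq by default, no surrounding material)
#' used by the NEMA sensitivity measurement, at radial offset 0 or 100 mm.
#'
#' @param radial_offset radial offset of the line from the axis (mm)
#' @param activity_bq total activity (Bq)
#' @return list: `phantom` (a [phantom_model()]) and `source` (a
#'   `source_model`)
#' @export
make_sensitivity_source <- function(radial_offset = 0, activity_bq = 5e6) {
  stopifnot(activity_bq >= 0)
  src <- structure(
    list(kind = "line", mode = "back_to_back", activity_bq = activity_bq,
         p0 = c(radial_offset, 0, -350), p1 = c(radial_offset, 0, 350)),
    class = "source_model")
  list(phantom = empty_phantom(), source = src)
}

#' @describeIn make_sensitivity_source NEMA NU-2 scatter phantom: a 700 mm
#'   long, 203 mm diameter polyethylene cylinder with an F-18 line source in
#'   a 6.4 mm channel at 45 mm radial offset.  `activity_concentration` is
#'   in kBq/mL of the whole phantom volume (the NEMA convention), so the
#'   total line activity is `concentration x 22654 mL`.
#' @param activity_concentration kBq/mL
#' @export
make_scatter_phantom <- function(activity_concentration) {
  stopifnot(activity_concentration >= 0)
  ph <- phantom_model(
    prim_cylinder(c(0, 0, 0), 101.5, 350, "polyethylene"),
    prim_cylinder(c(45, 0, 0), 3.2, 350, "air")
  )
  vol_ml <- primitive_volume(ph, 1) / 1000
  src <- structure(
    list(kind = "line", mode = "f18",
         activity_bq = activity_concentration * 1000 * vol_ml,
         p0 = c(45, 0, -350), p1 = c(45, 0, 350),
         concentration_kbq_ml = activity_concentration),
    class = "source_model")
  list(phantom = ph, source = src)
}

#' @describeIn make_sensitivity_source F-18 point source (3.7 MBq) in a
#'   0.5 mm water sphere inside a glass capillary (0.52 mm inner diameter,
#'   1.8 mm outer diameter, 0.9 mm height, taken as printed).  Set
#'   `capillary = FALSE` for an ideal point emitter in vacuum.
#' @param position length-3 source position (mm), inside the bore
#' @param capillary include the water sphere + glass capillary material
#' @export
make_point_source <- function(position, activity_bq = 3.7e6,
                              capillary = TRUE) {
  stopifnot(length(position) == 3L)
  if (sqrt(position[1]^2 + position[2]^2) >= 350) {
    stop("point source position outside the bore")
  }
  ph <- if (capillary) {
    phantom_model(
      prim_cylinder(position, 0.9, 0.45, "glass"),
      prim_cylinder(position, 0.26, 0.45, "water"),
      prim_sphere(position, 0.25, "water")
    )
  } else {
    empty_phantom()
  }
  src <- structure(
    list(kind = "point", mode = "f18", activity_bq = activity_bq,
         p0 = as.numeric(position)),
    class = "source_model")
  list(phantom = ph, source = src)
}

#' @describeIn make_sensitivity_source NEMA image-quality phantom: torso
#'   background compartment (180 mm interior length) at
#'   `background_concentration`, a cold 50 mm diameter lung insert on the
#'   axis, and six hot spheres (10, 13, 17, 22, 28, 37 mm inner diameter)
#'   centred on a 114.4 mm circle in the z = 0 plane at `sbr` times the
#'   background concentration.
#' @param sbr sphere-to-background activity ratio (4 and 8 are the NEMA
#'   values; others are allowed with a warning)
#' @param background_concentration background activity concentration,
#'   kBq/mL
#' @export
make_iq_phantom <- function(sbr, background_concentration = 5.3) {
  if (!sbr %in% c(4, 8)) {
    warning("sphere-to-background ratio ", sbr,
            " is outside the NEMA values {4, 8}")
  }
  diam <- c(10, 13, 17, 22, 28, 37)
  ang <- (seq_along(diam) - 1) * 60 * pi / 180
  centers <- cbind(57.2 * cos(ang), 57.2 * sin(ang), 0)
  spheres <- do.call(rbind, lapply(seq_along(diam), function(i) {
    prim_sphere(centers[i, ], diam[i] / 2, "water",
                activity = sbr * background_concentration)
  }))
  ph <- phantom_model(
    prim_torso(0, 90, material = "water",
               activity = background_concentration),
    prim_cylinder(c(0, 0, 0), 25, 90, "lung", activity = 0),
    spheres
  )
  src <- structure(
    list(kind = "volume", mode = "f18",
         background_concentration = background_concentration, sbr = sbr),
    class = "source_model")
  attr(ph, "spheres") <- data.frame(diameter = diam, cx = centers[, 1],
                                    cy = centers[, 2], cz = 0)
  list(phantom = ph, source = src)
}

#' Write / read a phantom as delimited text
#'
#' One primitive per row (shape code, parameters, material, activity), in
#' priority order, with a comment header.
#'
#' @param phantom a [phantom_model()]
#' @param path file path
#' @return `read_phantom` returns a `phantom_model`
#' @export
write_phantom <- function(phantom, path) {
  p <- phantom$primitives
  lines <- c("# monopet phantom: shape p1..p7 material activity",
             vapply(seq_len(n_primitives(phantom)), function(i) {
               paste(p$shape[i], p$p1[i], p$p2[i], p$p3[i], p$p4[i], p$p5[i],
                     p$p6[i], p$p7[i], p$material[i], p$activity[i])
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(empty_phantom())
  prims <- do.call(rbind, lapply(strsplit(lines, "\\s+"), function(f) {
    if (length(f) != 10L) stop("malformed phantom line")
    prim_row(as.integer(f[1]), as.numeric(f[2:8]), f[9], as.numeric(f[10]))
  }))
  structure(list(primitives = prims), class = "phantom_model")
}

#' Voxelise the 511 keV attenuation map of a phantom
#'
#' Each voxel receives the linear attenuation coefficient of the
#' highest-priority primitive containing its centre; 0 (vacuum) elsewhere.
#'
#' @param phantom a [phantom_model()]
#' @param grid a [voxel_grid()]
#' @return a `mu_map` (an [image_volume()] with units mm^-1)
#' @export
voxelise_mu_map <- function(phantom, grid) {
  ctr <- grid_centers(grid)
  pts <- as.matrix(expand.grid(ctr$x, ctr$y, ctr$z))
  idx <- point_in_phantom(phantom, pts)
  mu <- numeric(length(idx))
  sel <- idx > 0
  if (any(sel)) mu[sel] <- phantom$primitives$mu[idx[sel]]
  out <- image_volume(grid, array(mu, grid$dims), units = "mm^-1")
  class(out) <- c("mu_map", class(out))
  out
}
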