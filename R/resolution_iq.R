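#' FWHM of a point spread function along one grid axis
#'
#' NEMA profile method: the maximum voxel is located, a 1-D profile through
#' it is taken along the axis, the peak value is refined by a parabolic fit
#' through the peak bin and its two neighbours, and the half-maximum
#' crossings are found by linear interpolation between bins on each side.
#' A single-voxel delta yields about one voxel width (the crossings sit
#' half a bin away on each side).
#'
#' @param image an [image_volume()]
#' @param axis 1/2/3 or "x"/"y"/"z"
#' @return FWHM in mm
#' @export
measure_fwhm <- function(image, axis) {
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  stopifnot(axis %in% 1:3)
  v <- image$values
  pk <- arrayInd(which.max(v), dim(v))
  prof <- switch(axis,
                 v[, pk[2], pk[3]],
                 v[pk[1], , pk[3]],
                 v[pk[1], pk[2], ])
  step <- image$grid$spacing[axis]
  i0 <- pk[axis]
  n <- length(prof)
  if (i0 <= 1L || i0 >= n) stop("PSF peak lies on the image border")
  # parabolic refinement of the peak value
  y1 <- prof[i0 - 1]; y2 <- prof[i0]; y3 <- prof[i0 + 1]
  den <- y1 - 2 * y2 + y3
  peak <- if (den < 0) y2 - (y1 - y3)^2 / (8 * den) else y2
  half <- peak / 2
  cross <- function(idx) {
    # idx runs from the peak outwards; first bin below half
    for (k in idx) {
      if (prof[k] < half) {
        k_in <- k + sign(i0 - k)  # neighbour towards the peak
        frac <- (prof[k_in] - half) / (prof[k_in] - prof[k])
        return(abs(k_in - i0) + frac)
      }
    }
    stop("half-maximum crossing not found inside the image")
  }
  left <- cross(seq(i0 - 1L, 1L))
  right <- cross(seq(i0 + 1L, n))
  (left + right) * step
}

#' NEMA spatial-resolution study
#'
#' Simulates the F-18 capillary point source at the six NEMA positions
#' (radii 10, 100, 200 mm; axially at the centre and at 3/8 of the aFOV),
#' blurs the LOR endpoints with the intrinsic detector resolution,
#' reconstructs each source on a local 0.5 mm grid with MLEM (10
#' iterations, no subsets) and measures the radial, tangential and axial
#' FWHM.  Sources are placed on the +x axis, so the grid axes coincide
#' with the radial/tangential/axial directions.
#'
#' @param design `"design_a"` or `"design_b"`
#' @param seed RNG seed
#' @param n_true_target true coincidences to collect per position
#' @param voxel_mm reconstruction voxel size
#' @param subgrid voxels per axis of the local reconstruction grid
#' @param n_iterations MLEM iterations
#' @param blur_fwhm_mm intrinsic detector blur (0 disables it)
#' @param physics optional [physics_model()] override (e.g. back-to-back
#'   mode to isolate the reconstruction floor)
#' @param positions optional data.frame (`radius_mm`, `z_mm`) overriding
#'   the six NEMA positions
#' @return data.frame: position and `fwhm_radial`, `fwhm_tangential`,
#'   `fwhm_axial` in mm
#' @export
resolution_study <- function(design = "design_a", seed = NULL,
                             n_true_target = 1e5, voxel_mm = 0.5,
                             subgrid = 64L, n_iterations = 10,
                             blur_fwhm_mm = 1.15, physics = NULL,
                             positions = NULL) {
  geom <- if (is.character(design)) build_scanner(scanner_config(design)) else design
  if (is.null(positions)) {
    positions <- expand.grid(radius_mm = c(10, 100, 200),
                             z_mm = c(0, 3 / 8 * geom$afov))
  }
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(2^31 - 1, nrow(positions))
  rows <- list()
  for (k in seq_len(nrow(positions))) {
    pos <- c(positions$radius_mm[k], 0, positions$z_mm[k])
    scn <- scenario_point(geom, pos, physics = physics)
    sim <- collect_trues(scn, n_true_target, sub_seeds[k])
    trues <- sim$trues
    if (blur_fwhm_mm > 0) {
      trues <- blur_lor_endpoints(trues, geom, blur_fwhm_mm,
                                  seed = sub_seeds[k] + 7)
    }
    # align the grid so the nominal source position is a voxel centre
    # (a corner-straddling point spreads over 8 voxels and inflates the
    # measured FWHM by almost a voxel)
    grid <- voxel_grid(voxel_mm, subgrid,
                       origin = pos - voxel_mm * (subgrid / 2 - 0.5))
    img <- reconstruct_mlem(trues, grid, geom = geom,
                            n_iterations = n_iterations,
                            seed = sub_seeds[k] + 11)
    rows[[k]] <- data.frame(
      radius_mm = positions$radius_mm[k], z_mm = positions$z_mm[k],
      n_trues = nrow(trues),
      fwhm_radial = measure_fwhm(img, 1),
      fwhm_tangential = measure_fwhm(img, 2),
      fwhm_axial = measure_fwhm(img, 3))
  }
  do.call(rbind, rows)
}

# simulate until ~n_target true coincidences are collected (pilot + final)
collect_trues <- function(scn, n_target, seed, pilot_decays = 2e5,
                          max_decays = 2e7) {
  pilot <- run_simulation(scn, n_decays = pilot_decays, seed = seed,
                          max_decays = max_decays)
  pc <- process_coincidences(pilot)
  tpd <- pc$counts[["trues"]] / pilot_decays
  if (tpd <= 0) stop("no true coincidences in the pilot frame")
  n <- min(max(ceiling(n_target / tpd * 1.05), pilot_decays), max_decays)
  sim <- run_simulation(scn, n_decays = n, seed = seed + 1,
                        max_decays = max_decays)
  pc <- process_coincidences(sim)
  duration_s <- sim$duration_s
  rm(sim, pilot)
  gc(verbose = FALSE)
  list(trues = pc$coincidences[pc$coincidences$truth == "true"],
       counts = pc$counts, duration_s = duration_s)
}

#' NEMA image-quality ROIs
#'
#' One circular ROI per hot sphere (diameter equal to the sphere inner
#' diameter) on the central sphere slice, plus a fixed polar template of
#' twelve background ROI centres per slice on the central slice and the
#' slices at +-10 and +-20 mm, concentric across ROI sizes: 60 background
#' ROIs per size, 360 in total.  Template positions keep every ROI edge at
#' least 15 mm from the phantom wall and clear of the spheres and the lung
#' insert; violations raise an error.
#'
#' @param phantom the IQ phantom ([make_iq_phantom()])
#' @param slice_offsets_mm background slice offsets from the sphere plane
#' @return list with `spheres` (centres + diameters), `background`
#'   (template centres x slices) and the ROI diameters
#' @export
place_iq_rois <- function(phantom,
                          slice_offsets_mm = c(-20, -10, 0, 10, 20)) {
  spheres <- attr(phantom, "spheres")
  if (is.null(spheres)) stop("phantom carries no sphere table")
  template <- data.frame(
    angle_deg = c(30, 150, 210, 330, 90, 270, 0, 180, 45, 135, 225, 315),
    radius_mm = c(95, 95, 95, 95, 75, 75, 110, 110, 100, 100, 100, 100))
  bg <- data.frame(
    x = template$radius_mm * cos(template$angle_deg * pi / 180),
    y = template$radius_mm * sin(template$angle_deg * pi / 180))
  max_roi_r <- max(spheres$diameter) / 2
  # 15 mm edge margin to the torso wall (straight walls + half-circles)
  a <- 35; R <- 115
  xp <- pmax(abs(bg$x) - a, 0)
  wall <- R - sqrt(xp^2 + bg$y^2)
  if (any(wall < 15 + max_roi_r)) stop("background ROI too close to the wall")
  for (i in seq_len(nrow(spheres))) {
    d2 <- sqrt((bg$x - spheres$cx[i])^2 + (bg$y - spheres$cy[i])^2)
    if (any(d2 < max_roi_r + spheres$diameter[i] / 2)) {
      stop("background ROI overlaps sphere ", spheres$diameter[i], " mm")
    }
  }
  if (any(sqrt(bg$x^2 + bg$y^2) < max_roi_r + 25)) {
    stop("background ROI overlaps the lung insert")
  }
  list(spheres = spheres, background_xy = bg,
       slice_offsets_mm = slice_offsets_mm,
       diameters = spheres$diameter)
}

# mean voxel value of a circular 2-D ROI at slice z (voxel-centre-in-circle)
roi_mean <- function(image, cx, cy, z, diameter) {
  g <- image$grid
  ctr <- grid_centers(g)
  iz <- which.min(abs(ctr$z - z))
  ix <- which(abs(ctr$x - cx) <= diameter / 2 + g$spacing[1])
  iy <- which(abs(ctr$y - cy) <= diameter / 2 + g$spacing[2])
  sub <- image$values[ix, iy, iz, drop = FALSE]
  dx <- outer(ctr$x[ix] - cx, ctr$y[iy] - cy,
              function(a, b) a^2 + b^2)
  inside <- dx <= (diameter / 2)^2
  if (!any(inside)) stop("ROI contains no voxel centre")
  mean(sub[, , 1][inside])
}

#' Contrast recovery and background variability
#'
#' `CRC_j = (C_H/C_B - 1) / (A_H/A_B - 1)` per hot sphere, with `C_H` the
#' mean counts in the sphere ROI and `C_B` the mean of the 60 background
#' ROI means of the matching size; background variability
#' `N_j = SD_j / C_B` with `SD_j` the standard deviation of those 60
#' background ROI means.
#'
#' @param image reconstructed [image_volume()]
#' @param rois [place_iq_rois()] output
#' @param A_H,A_B hot-sphere and background activity concentrations
#' @return data.frame: per sphere `diameter`, `C_H`, `C_B`, `crc`, `SD`,
#'   `bv`
#' @export
crc_and_bv <- function(image, rois, A_H, A_B) {
  if (A_H == A_B) stop("A_H must differ from A_B (CRC denominator is zero)")
  sp <- rois$spheres
  out <- lapply(seq_len(nrow(sp)), function(j) {
    d <- sp$diameter[j]
    ch <- roi_mean(image, sp$cx[j], sp$cy[j], sp$cz[j], d)
    bg <- unlist(lapply(rois$slice_offsets_mm, function(dz) {
      vapply(seq_len(nrow(rois$background_xy)), function(b) {
        roi_mean(image, rois$background_xy$x[b], rois$background_xy$y[b],
                 sp$cz[j] + dz, d)
      }, numeric(1))
    }))
    cb <- mean(bg)
    data.frame(diameter = d, C_H = ch, C_B = cb,
               crc = (ch / cb - 1) / (A_H / A_B - 1),
               SD = sd(bg), bv = sd(bg) / cb, n_bg_rois = length(bg))
  })
  do.call(rbind, out)
}

#' NEMA image-quality study
#'
#' Simulates the IQ phantom, reconstructs the ground-truth trues with
#' TOF-MLEM (20 iterations, 2 mm voxels, 200 ps TOF kernel) with
#' attenuation correction from the voxelised mu-map, and evaluates CRC and
#' background variability per sphere at every iteration.
#'
#' @param design `"design_a"` or `"design_b"`
#' @param sbr sphere-to-background ratio (4 or 8)
#' @param seed RNG seed
#' @param n_true_target true coincidences to collect
#' @param n_iterations TOF-MLEM iterations
#' @param voxel_mm voxel size
#' @param blur_fwhm_mm intrinsic detector blur
#' @param axial_extent_mm axial half-extent of the reconstruction grid
#' @return list: `reports` (one CRC/BV table per iteration), `final`
#'   (iteration `n_iterations` table), `image`, `n_trues`
#' @export
iq_study <- function(design = "design_a", sbr = 4, seed = NULL,
                     n_true_target = 3e5, n_iterations = 20, voxel_mm = 2,
                     blur_fwhm_mm = 1.15, axial_extent_mm = 50) {
  geom <- if (is.character(design)) build_scanner(scanner_config(design)) else design
  scn <- scenario_iq(geom, sbr)
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(2^31 - 1, 3)
  sim <- collect_trues(scn, n_true_target, sub[1], pilot_decays = 3e5,
                       max_decays = 5e7)
  trues <- blur_lor_endpoints(sim$trues, geom, blur_fwhm_mm, seed = sub[2])
  nxy <- 2L * ceiling(160 / voxel_mm)
  nz <- 2L * ceiling(axial_extent_mm / voxel_mm)
  grid <- voxel_grid(voxel_mm, c(nxy, nxy, nz), center = c(0, 0, 0))
  mu <- voxelise_mu_map(scn$phantom, grid)
  img <- reconstruct_mlem(trues, grid, geom = geom,
                          n_iterations = n_iterations,
                          tof_ctr_ps = geom$config$ctr_fwhm_ps,
                          mu_map = mu, snapshots = seq_len(n_iterations),
                          seed = sub[3])
  rois <- place_iq_rois(scn$phantom)
  bgc <- scn$source$background_concentration
  reports <- lapply(attr(img, "snapshots"), function(snap) {
    crc_and_bv(image_volume(grid, snap), rois, A_H = sbr * bgc, A_B = bgc)
  })
  n_trues <- nrow(trues)
  rm(trues, sim, mu)
  gc(verbose = FALSE)
  list(reports = reports, final = reports[[length(reports)]], image = img,
       n_trues = n_trues, grid = grid)
}
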