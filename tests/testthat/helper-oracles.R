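# Independent oracles and small builders shared across the test files.

# Exhaustive first-module finder: per ray, clip the line against *every*
# module slab with an independent R slab-clipping routine and take the
# smallest positive entry.  No candidate pruning, so it cross-checks the
# fast path's pruning logic.
brute_force_first_module <- function(geom, origins, dirs) {
  cfg <- geom$config
  r_in <- cfg$bore_diameter / 2
  r_out <- r_in + cfg$crystal_thickness
  mpr <- cfg$modules_per_ring
  ht <- cfg$crystal_width_transaxial / 2
  ha <- cfg$crystal_width_axial / 2
  mods <- geom$modules
  phis <- 2 * pi * mods$azimuth / mpr
  cphi <- cos(phis); sphi <- sin(phis)
  zc <- mods$cz
  n <- nrow(origins)
  module <- integer(n)
  entry <- matrix(NA_real_, n, 3)
  clip <- function(o, d, lo, hi, t0, t1) {
    # vectorised over modules; returns updated (t0, t1), NA pair = miss
    still <- abs(d) < 1e-12
    ta <- (lo - o) / d
    tb <- (hi - o) / d
    swap <- ta > tb & !still
    tmp <- ta[swap]; ta[swap] <- tb[swap]; tb[swap] <- tmp
    ta[still] <- -Inf; tb[still] <- Inf
    miss_still <- still & (o < lo | o > hi)
    t0 <- pmax(t0, ta); t1 <- pmin(t1, tb)
    t0[miss_still] <- Inf
    list(t0 = t0, t1 = t1)
  }
  for (i in seq_len(n)) {
    o <- origins[i, ]; d <- dirs[i, ]
    ou <- o[1] * cphi + o[2] * sphi;  du <- d[1] * cphi + d[2] * sphi
    ov <- -o[1] * sphi + o[2] * cphi; dv <- -d[1] * sphi + d[2] * cphi
    ow <- o[3] - zc;                  dw <- rep(d[3], length(zc))
    r1 <- clip(ou, du, r_in, r_out, rep(-Inf, length(zc)), rep(Inf, length(zc)))
    r2 <- clip(ov, dv, -ht, ht, r1$t0, r1$t1)
    r3 <- clip(ow, dw, -ha, ha, r2$t0, r2$t1)
    hit <- which(r3$t1 > pmax(r3$t0, 0) & r3$t0 > -1e-9 & is.finite(r3$t0))
    if (length(hit)) {
      j <- hit[which.min(r3$t0[hit])]
      module[i] <- mods$module[j]
      entry[i, ] <- o + max(r3$t0[j], 0) * d
    }
  }
  list(module = module, entry = entry)
}

# closed-form fraction of isotropic directions from an on-axis point z0 that
# cross the cylinder radius R within the axial band [z1, z2]
band_coverage <- function(z0, R, z1, z2) {
  u <- function(h) h / sqrt(h^2 + R^2)
  pmax(0.5 * (u(z2 - z0) - u(z1 - z0)), 0)
}

# random isotropic unit vectors
iso_dirs <- function(n) {
  z <- runif(n, -1, 1)
  ph <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(ph), s * sin(ph), z)
}

design_a <- function() build_scanner(scanner_config("design_a"))
design_b <- function() build_scanner(scanner_config("design_b"))

# analytic 3-D Gaussian image for FWHM estimator tests
gaussian_image <- function(sigma_mm, voxel_mm = 0.5, n = 41L,
                           center = c(0, 0, 0)) {
  g <- voxel_grid(voxel_mm, n, center = center)
  ctr <- grid_centers(g)
  vals <- outer(outer(exp(-(ctr$x - center[1])^2 / (2 * sigma_mm^2)),
                      exp(-(ctr$y - center[2])^2 / (2 * sigma_mm^2))),
                exp(-(ctr$z - center[3])^2 / (2 * sigma_mm^2)))
  image_volume(g, array(vals, g$dims))
}

# synthetic singles table builder for the coincidence-processing tests
singles_table <- function(t_ns, module, energy = 511,
                          decay_id = seq_along(t_ns), n_scatters = 0L) {
  data.table::data.table(
    decay_id = as.numeric(decay_id), module = as.integer(module),
    x = 350, y = 0, z = 0,
    energy_dep = as.numeric(energy), energy = as.numeric(energy),
    t_ns = as.numeric(t_ns), n_scatters = as.integer(n_scatters))
}
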