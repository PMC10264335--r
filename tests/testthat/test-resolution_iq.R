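test_that("FWHM estimator is unbiased on analytic Gaussians", {
  k <- 2 * sqrt(2 * log(2))
  # adequately sampled profiles (~7 bins across the FWHM): within 3 %
  for (sigma in c(0.4, 0.6, 1.0, 1.8, 3.0)) {
    img <- gaussian_image(sigma, voxel_mm = sigma / 3, n = 61L)
    for (ax in 1:3) {
      expect_equal(measure_fwhm(img, ax), k * sigma,
                   tolerance = 0.03, label = sprintf("sigma %.1f", sigma))
    }
  }
  # sigma = 0.6 mm on the 0.5 mm study grid: 1.413 mm within the
  # half-voxel linear-interpolation error
  expect_lt(abs(measure_fwhm(gaussian_image(0.6), 1) - 1.4131), 0.25)
})

test_that("FWHM estimator degenerate cases", {
  g <- voxel_grid(0.5, 21, center = c(0, 0, 0))
  delta <- array(0, g$dims)
  delta[11, 11, 11] <- 1
  img <- image_volume(g, delta)
  # single-voxel delta: about one voxel width by convention
  expect_equal(measure_fwhm(img, 1), 0.5, tolerance = 0.1)
  border <- array(0, g$dims)
  border[1, 11, 11] <- 1
  expect_error(measure_fwhm(image_volume(g, border), 1), "border")
})

test_that("IQ ROI template: counts, sizes, clearances", {
  iq <- make_iq_phantom(4)
  rois <- place_iq_rois(iq$phantom)
  expect_equal(nrow(rois$background_xy), 12L)
  expect_equal(length(rois$slice_offsets_mm), 5L)
  # 60 background ROIs per size, six sizes -> 360
  expect_equal(nrow(rois$background_xy) * length(rois$slice_offsets_mm), 60L)
  expect_equal(rois$diameters, c(10, 13, 17, 22, 28, 37))
  # clearances: >= 15 mm from the wall, clear of spheres and lung for the
  # largest ROI size
  bg <- rois$background_xy
  xp <- pmax(abs(bg$x) - 35, 0)
  expect_true(all(115 - sqrt(xp^2 + bg$y^2) >= 15 + 37 / 2))
  sp <- rois$spheres
  for (i in seq_len(nrow(sp))) {
    d <- sqrt((bg$x - sp$cx[i])^2 + (bg$y - sp$cy[i])^2)
    expect_true(all(d >= 37 / 2 + sp$diameter[i] / 2))
  }
  expect_true(all(sqrt(bg$x^2 + bg$y^2) >= 37 / 2 + 25))
})

test_that("CRC and background-variability identities", {
  iq <- make_iq_phantom(4)
  rois <- place_iq_rois(iq$phantom)
  g <- voxel_grid(2, c(160, 160, 50), center = c(0, 0, 0))
  vals <- array(1, g$dims)
  ctr <- grid_centers(g)
  # paint every sphere ROI region at 3.7 on all slices
  sp <- rois$spheres
  for (i in seq_len(nrow(sp))) {
    inside <- outer((ctr$x - sp$cx[i])^2, (ctr$y - sp$cy[i])^2, "+") <=
      (sp$diameter[i] / 2)^2
    vals[array(inside, g$dims)] <- 3.7
  }
  img <- image_volume(g, vals)
  rep <- crc_and_bv(img, rois, A_H = 4 * 5.3, A_B = 5.3)
  # C_H/C_B = 3.7 at 4:1 -> CRC = 2.7/3 = 0.90
  expect_equal(rep$crc, rep(0.9, 6), tolerance = 1e-12)
  # constant background: SD = 0 -> N_j = 0
  expect_equal(rep$SD, rep(0, 6))
  expect_equal(rep$bv, rep(0, 6))
  expect_equal(rep$n_bg_rois, rep(60L, 6))
  # identities on the stored statistics
  expect_equal(rep$crc, (rep$C_H / rep$C_B - 1) / (4 - 1))
  expect_equal(rep$bv, rep$SD / rep$C_B)
  # C_H = C_B -> CRC = 0
  flat <- crc_and_bv(image_volume(g, array(2, g$dims)), rois, 4 * 5.3, 5.3)
  expect_equal(flat$crc, rep(0, 6))
  # degenerate ratio trapped
  expect_error(crc_and_bv(img, rois, 5.3, 5.3), "denominator")
})

test_that("a projector-consistent hot sphere reconstructs with CRC near 1", {
  # uniform air-like cylinder with a 4:1 hot sphere: negligible attenuation
  # and scatter, back-to-back emission, no endpoint blur -> the data match
  # the reconstruction model and contrast must be recovered
  ph <- phantom_model(
    prim_cylinder(c(0, 0, 0), 70, 60, "air", activity = 1),
    prim_sphere(c(25, 0, 0), 16, "air", activity = 4))
  src <- structure(list(kind = "volume", mode = "back_to_back"),
                   class = "source_model")
  scn <- scenario(design_a(), ph, src,
                  physics = physics_model("back_to_back"))
  sim <- run_simulation(scn, n_decays = 6e5, seed = 87)
  pc <- process_coincidences(sim)
  tr <- pc$coincidences[pc$coincidences$truth == "true"]
  g <- voxel_grid(4, c(40, 40, 24), center = c(0, 0, 0))
  img <- reconstruct_mlem(tr, g, geom = design_a(), n_iterations = 25,
                          seed = 88)
  ch <- monopet:::roi_mean(img, 25, 0, 0, 32)
  cb <- mean(c(monopet:::roi_mean(img, -35, 0, 0, 32),
               monopet:::roi_mean(img, 0, -40, 0, 32),
               monopet:::roi_mean(img, -20, 40, 0, 32)))
  crc <- (ch / cb - 1) / 3
  expect_equal(crc, 1, tolerance = 0.12)
})

test_that("resolution study: sub-voxel grid recon resolves the point source", {
  res <- resolution_study("design_a", seed = 89, n_true_target = 2e4,
                          positions = data.frame(radius_mm = 10, z_mm = 0))
  expect_equal(nrow(res), 1L)
  expect_true(all(res[, c("fwhm_radial", "fwhm_tangential",
                          "fwhm_axial")] < 2))
  expect_true(all(res[, c("fwhm_radial", "fwhm_tangential",
                          "fwhm_axial")] > 0.5))
  # near-isotropy at 1 cm radius
  expect_lt(abs(res$fwhm_radial - res$fwhm_tangential), 0.25)
})
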