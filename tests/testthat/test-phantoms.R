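test_that("NEMA source and phantom presets match their defining geometry", {
  s <- make_sensitivity_source()
  expect_equal(s$source$p0, c(0, 0, -350))
  expect_equal(s$source$p1, c(0, 0, 350))
  expect_equal(s$source$activity_bq, 5e6)
  expect_equal(n_primitives(s$phantom), 0L)
  off <- make_sensitivity_source(radial_offset = 100)
  expect_equal(off$source$p0[1], 100)
  zero <- make_sensitivity_source(activity_bq = 0)
  expect_equal(zero$source$activity_bq, 0)

  sc <- make_scatter_phantom(34)
  # polyethylene cylinder volume pi * 101.5^2 * 700
  expect_equal(primitive_volume(sc$phantom, 1), pi * 101.5^2 * 700)
  expect_equal(sc$source$activity_bq, 34 * 1000 * pi * 101.5^2 * 700 / 1000)
  expect_equal(sc$source$p0[1], 45)
  low <- make_scatter_phantom(0.045)
  expect_equal(low$source$concentration_kbq_ml, 0.045)

  expect_error(make_point_source(c(400, 0, 0)), "bore")
  ps <- make_point_source(c(10, 0, 0))
  expect_equal(n_primitives(ps$phantom), 3L)
  bare <- make_point_source(c(0, 0, 0), capillary = FALSE)
  expect_equal(n_primitives(bare$phantom), 0L)
})

test_that("IQ phantom has the NEMA spheres, cold lung and torso", {
  iq <- make_iq_phantom(8)
  sp <- attr(iq$phantom, "spheres")
  expect_equal(sp$diameter, c(10, 13, 17, 22, 28, 37))
  expect_equal(sqrt(sp$cx^2 + sp$cy^2), rep(57.2, 6))
  p <- iq$phantom$primitives
  expect_equal(p$activity[p$material == "lung"], 0)
  # sphere concentration = sbr x background
  expect_equal(unique(p$activity[p$shape == 1]), 8 * 5.3)
  expect_warning(make_iq_phantom(2), "NEMA")
})

test_that("point location respects priority order and plain geometry", {
  ph <- phantom_model(
    prim_cylinder(c(0, 0, 0), 50, 100, "water"),
    prim_sphere(c(20, 0, 0), 10, "glass")
  )
  pts <- rbind(c(20, 0, 0),    # inside sphere (overrides cylinder)
               c(-20, 0, 0),   # cylinder only
               c(0, 0, 150),   # outside axially
               c(60, 0, 0))    # outside radially
  expect_equal(point_in_phantom(ph, pts), c(2L, 1L, 0L, 0L))

  # independent per-shape predicates on random points
  set.seed(5)
  q <- cbind(runif(3000, -60, 60), runif(3000, -60, 60),
             runif(3000, -120, 120))
  idx <- point_in_phantom(ph, q)
  in_sph <- (q[, 1] - 20)^2 + q[, 2]^2 + q[, 3]^2 <= 100
  in_cyl <- q[, 1]^2 + q[, 2]^2 <= 2500 & abs(q[, 3]) <= 100
  expect_equal(idx == 2L, in_sph)
  expect_equal(idx >= 1L, in_cyl | in_sph)
})

test_that("Monte Carlo region volumes match the analytic geometry", {
  iq <- make_iq_phantom(4)
  set.seed(6)
  pts <- cbind(runif(2000, -150, 150), runif(2000, -115, 115),
               runif(2000, -90, 90))
  idx <- point_in_phantom(iq$phantom, pts)
  vols_mc <- region_volumes(iq$phantom, n = 2e5, seed = 7)
  # torso region effective volume: analytic minus lung minus spheres
  a_torso <- primitive_volume(iq$phantom, 1) -
    primitive_volume(iq$phantom, 2) -
    sum(vapply(3:8, function(i) primitive_volume(iq$phantom, i), numeric(1)))
  expect_lt(abs(vols_mc[1] - a_torso) / a_torso, 0.02)
  expect_gt(mean(idx == 1L), 0.3)
})

test_that("volume-source activity matches concentration x region volume", {
  iq <- make_iq_phantom(4, background_concentration = 5.3)
  scn <- scenario_iq("design_a", 4)
  act <- monopet:::source_activity_bq(scn)
  vols_mc <- region_volumes(iq$phantom, n = 4e5, seed = 8)
  p <- iq$phantom$primitives
  act_mc <- sum(p$activity * vols_mc)
  expect_lt(abs(act - act_mc) / act_mc, 0.005)
})

test_that("phantoms round-trip through the text format", {
  ph <- make_iq_phantom(4)$phantom
  path <- tempfile(fileext = ".phantom")
  write_phantom(ph, path)
  back <- read_phantom(path)
  expect_equal(back$primitives, ph$primitives)
  expect_equal(read_phantom(write_phantom(empty_phantom(), path)),
               empty_phantom())
})

test_that("mu-map voxelisation assigns the priority material", {
  ph <- phantom_model(
    prim_cylinder(c(0, 0, 0), 40, 40, "water"),
    prim_cylinder(c(0, 0, 0), 10, 40, "lung")
  )
  g <- voxel_grid(4, c(30, 30, 10), center = c(0, 0, 0))
  mu <- voxelise_mu_map(ph, g)
  ctr <- grid_centers(g)
  # a voxel well inside the water annulus
  ix <- which.min(abs(ctr$x - 25)); iy <- which.min(abs(ctr$y)); iz <- 5L
  expect_equal(mu$values[ix, iy, iz], 0.0096)
  # a voxel in the lung insert: 0.3 x water
  ix0 <- which.min(abs(ctr$x))
  expect_equal(mu$values[ix0, iy, iz], 0.00288)
  expect_equal(mu$values[ix0, iy, iz] / 0.0096, 0.3)
  # vacuum outside
  expect_equal(mu$values[30, 30, 1], 0)
})
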