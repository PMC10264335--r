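test_that("endpoint blurring: identity at zero, correct spread, slab clamp", {
  scn <- scenario_point("design_a", c(0, 0, 0), capillary = FALSE,
                        physics = physics_model("back_to_back"))
  sim <- run_simulation(scn, n_decays = 2e5, seed = 81)
  pc <- process_coincidences(sim)
  tr <- pc$coincidences[pc$coincidences$truth == "true"]
  g <- design_a()
  expect_identical(blur_lor_endpoints(tr, g, 0), tr)
  bl <- blur_lor_endpoints(tr, g, 1.15, seed = 82)
  # displacement spread along z for points well inside the slab (no clamp)
  zr <- g$ring_z[(tr$module1 - 1L) %/% 40L + 1L]
  free <- abs(tr$z1 - zr) < 25 - 4
  dz <- (bl$z1 - tr$z1)[free]
  expect_equal(sd(dz) * 2 * sqrt(2 * log(2)), 1.15, tolerance = 0.03)
  # every blurred endpoint stays inside its 16 mm slab
  for (side in 1:2) {
    mod <- bl[[paste0("module", side)]]
    phi <- 2 * pi * ((mod - 1L) %% 40L) / 40L
    u <- bl[[paste0("x", side)]] * cos(phi) + bl[[paste0("y", side)]] * sin(phi)
    v <- -bl[[paste0("x", side)]] * sin(phi) + bl[[paste0("y", side)]] * cos(phi)
    w <- bl[[paste0("z", side)]] - g$ring_z[(mod - 1L) %/% 40L + 1L]
    expect_true(all(u >= 350 - 1e-9 & u <= 366 + 1e-9))
    expect_true(all(abs(v) <= 25 + 1e-9))
    expect_true(all(abs(w) <= 25 + 1e-9))
  }
})

test_that("sensitivity map: central maximum, axial symmetry, zero-map guard", {
  g1 <- build_scanner(scanner_config(NULL, n_rings = 1L))
  grid <- voxel_grid(10, c(11, 11, 5), center = c(0, 0, 0))
  sm <- compute_sensitivity_map(g1, grid, n_dirs = 4000, seed = 83)
  v <- sm$values
  expect_equal(which.max(apply(v, 3, max)), 3L)       # axial centre slice
  pk <- arrayInd(which.max(v), dim(v))
  expect_lte(sqrt(sum((pk[1:2] - 6)^2)), sqrt(2) + 1e-9)  # transverse centre
  expect_equal(apply(v, 3, mean)[1], apply(v, 3, mean)[5], tolerance = 0.05)
  # empty geometry -> zero map -> reconstruction refuses
  g0 <- g1
  g0$n_modules <- 0L
  zm <- compute_sensitivity_map(g0, grid)
  expect_true(all(zm$values == 0))
  fake <- list(p1 = matrix(c(0, 0, 0), 1), p2 = matrix(c(1, 1, 1), 1))
  expect_error(reconstruct_mlem(fake, grid, sens_map = zm), "zero")
})

test_that("attenuation factors: vacuum, analytic water path, reversal symmetry", {
  ph <- phantom_model(prim_cylinder(c(0, 0, 0), 100, 200, "water"))
  grid <- voxel_grid(2, c(110, 110, 10), center = c(0, 0, 0))
  mu <- voxelise_mu_map(ph, grid)
  lors <- list(p1 = rbind(c(-300, 0, 0), c(-300, 150, 0), c(300, 0, 0)),
               p2 = rbind(c(300, 0, 0), c(300, 150, 0), c(-300, 0, 0)))
  a <- attenuation_factors(lors, mu)
  expect_equal(a[1], exp(-0.0096 * 200), tolerance = 0.02)  # 200 mm of water
  expect_equal(a[2], 1)                                     # misses the phantom
  expect_equal(a[1], a[3])                                  # direction reversal
})

test_that("projector adjointness with and without TOF", {
  set.seed(84)
  grid <- voxel_grid(c(3, 4, 5), c(8, 7, 6), origin = c(-12, -14, -15))
  nv <- prod(grid$dims)
  x <- runif(nv)
  n <- 40
  p1 <- cbind(runif(n, -60, 60), runif(n, -60, 60), runif(n, -60, 60))
  p2 <- cbind(runif(n, -60, 60), runif(n, -60, 60), runif(n, -60, 60))
  y <- runif(n)
  for (tof in c(0, 12)) {
    dt <- if (tof > 0) runif(n, -0.2, 0.2) else numeric(0)
    fx <- monopet:::forward_project_cpp(x, grid$origin, grid$spacing,
                                        grid$dims, p1, p2, dt, tof)
    bty <- monopet:::backproject_cpp(y, grid$origin, grid$spacing,
                                     grid$dims, p1, p2, dt, tof)
    expect_equal(sum(fx * y), sum(x * bty), tolerance = 1e-10)
  }
})

test_that("MLEM: point recovery, count conservation, non-negativity, likelihood ascent", {
  set.seed(85)
  pt <- c(3.2, -2.1, 1.4)
  n <- 4000
  d <- iso_dirs(n)
  lors <- list(p1 = sweep(d * 400, 2, pt, "+"),
               p2 = sweep(-d * 400, 2, pt, "+"))
  grid <- voxel_grid(2, c(16, 16, 16), center = c(0, 0, 0))
  sens <- image_volume(grid, array(1, grid$dims))
  img <- reconstruct_mlem(lors, grid, n_iterations = 10, sens_map = sens,
                          snapshots = c(1, 5, 10))
  v <- img$values
  expect_true(all(v >= 0))
  # count conservation: sum x_j s_j = number of events at every snapshot
  for (snap in attr(img, "snapshots")) expect_equal(sum(snap), n)
  # mass concentrates at the source voxel neighbourhood
  pk <- arrayInd(which.max(v), dim(v))
  ctr <- grid_centers(grid)
  expect_lt(max(abs(c(ctr$x[pk[1]], ctr$y[pk[2]], ctr$z[pk[3]]) - pt)), 2.1)
  nb <- v[pk[1] + (-1:1), pk[2] + (-1:1), pk[3] + (-1:1)]
  expect_gt(sum(nb) / sum(v), 0.9)
  # log-likelihood is non-decreasing
  ll <- attr(img, "loglik")
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-1])))
})

test_that("TOF-MLEM with a huge CTR reduces to plain MLEM", {
  set.seed(86)
  pt <- c(5, 0, 0)
  n <- 1500
  d <- iso_dirs(n)
  lors <- list(p1 = sweep(d * 300, 2, pt, "+"),
               p2 = sweep(-d * 300, 2, pt, "+"),
               dt_ns = rnorm(n, 0, 0.05))
  grid <- voxel_grid(2.5, c(12, 12, 12), center = c(0, 0, 0))
  sens <- image_volume(grid, array(1, grid$dims))
  plain <- reconstruct_mlem(lors, grid, n_iterations = 5, sens_map = sens)
  tofinf <- reconstruct_mlem(lors, grid, n_iterations = 5, sens_map = sens,
                             tof_ctr_ps = 1e9)
  expect_equal(tofinf$values, plain$values, tolerance = 1e-6)
  # and the 200 ps kernel is ~30 mm FWHM
  expect_equal(tof_kernel_fwhm_mm(200), 29.98, tolerance = 1e-3)
  # a sharp kernel concentrates the image more than plain MLEM
  tof <- reconstruct_mlem(lors, grid, n_iterations = 5, sens_map = sens,
                          tof_ctr_ps = 100)
  expect_gt(max(tof$values) / max(plain$values), 1)
})
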