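# Volumetry, surface extraction, area, shape parameter, paired rates.

test_that("voxel-count volume matches its definition and an analytic sphere", {
  arr <- array(0L, c(20, 10, 10))
  arr[seq_len(1000)] <- 1L
  vol <- label_volume(arr, spacing = rep(0.8, 3))
  expect_equal(volume_from_labels(vol, "unmyelinated_wm"), 1000 * 0.8^3)
  expect_equal(volume_from_labels(vol, "ventricles"), 0)
  expect_error(volume_from_labels(vol, "cortex"), "unknown structure")

  sph <- voxel_sphere(r = 10, spacing = 0.5)
  expect_rel_equal(volume_from_labels(sph, "unmyelinated_wm"),
                   4 / 3 * pi * 1000, 0.02)
})

test_that("extracted meshes are closed, oriented, and volume-accurate", {
  sph <- voxel_sphere(r = 10, spacing = 0.5)
  mesh <- extract_mesh(sph, "unmyelinated_wm", smoothing_iters = 10)
  rep_ <- validate_closed_oriented(mesh)
  expect_true(rep_$closed)
  expect_true(rep_$oriented)
  expect_rel_equal(mesh_signed_volume(mesh), 4 / 3 * pi * 1000, 0.02)

  # mesh volume vs voxel volume agreement
  expect_rel_equal(mesh_signed_volume(mesh),
                   volume_from_labels(sph, "unmyelinated_wm"), 0.03)

  # single voxel: closed, tiny positive volume
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  vol1 <- label_volume(one, spacing = rep(1, 3))
  m1 <- extract_mesh(vol1, "unmyelinated_wm", smoothing_iters = 0)
  expect_true(validate_closed_oriented(m1)$closed)
  expect_gt(mesh_signed_volume(m1), 0)
  expect_lt(mesh_signed_volume(m1), 1.5)

  expect_error(extract_mesh(vol1, "cerebellum"), "no voxels")
})

test_that("smoothing keeps connectivity and does not grow the area", {
  sph <- voxel_sphere(r = 6, spacing = 0.6)
  raw <- extract_mesh(sph, "unmyelinated_wm", smoothing_iters = 0)
  smoothed <- extract_mesh(sph, "unmyelinated_wm", smoothing_iters = 20)
  expect_identical(nrow(raw$vertices), nrow(smoothed$vertices))
  expect_lte(surface_area(smoothed), surface_area(raw))
})

test_that("largest-component filter drops speckle labels", {
  arr <- array(0L, c(20, 20, 20))
  arr[5:15, 5:15, 5:15] <- 1L
  arr[2, 2, 2] <- 1L  # speckle
  vol <- label_volume(arr, spacing = rep(1, 3))
  mesh <- extract_mesh(vol, "unmyelinated_wm", smoothing_iters = 0)
  expect_true(validate_closed_oriented(mesh)$closed)
  expect_rel_equal(mesh_signed_volume(mesh), 11^3, 0.15)
})

test_that("surface area matches exact and analytic references", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)))
  expect_equal(surface_area(tri), 0.5)

  cube <- voxel_sphere(r = 1, spacing = 1)  # not used; build cube directly
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 2
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  cube <- surface_mesh(v, f)
  expect_equal(surface_area(cube), 24)
  expect_gt(mesh_signed_volume(cube), 0)

  ico <- icosphere(4, radius = 10)
  expect_rel_equal(surface_area(ico), 4 * pi * 100, 0.01)
})

test_that("shape parameter is area/volume with scale covariance", {
  expect_equal(shape_parameter(300, 1000), 0.3)
  expect_equal(shape_parameter(24, 8), 3)
  expect_error(shape_parameter(10, 0), "positive")

  ico <- icosphere(3, radius = 10)
  sp1 <- shape_parameter(surface_area(ico), mesh_signed_volume(ico))
  expect_rel_equal(sp1, 3 / 10, 0.03)
  big <- apply_rigid(ico, s = 2.5)
  sp2 <- shape_parameter(surface_area(big), mesh_signed_volume(big))
  expect_rel_equal(sp2, sp1 / 2.5, 1e-10)
})

test_that("area and volume are invariant under rigid motion", {
  ico <- icosphere(3, radius = 7)
  moved <- apply_rigid(ico, fetalmorph:::rotation_about(c(2, 1, 3), 1.1),
                       c(12, -4, 9))
  expect_rel_equal(surface_area(moved), surface_area(ico), 1e-9)
  expect_rel_equal(mesh_signed_volume(moved), mesh_signed_volume(ico), 1e-9)
})

test_that("gestational ages parse and paired rates follow the linear model", {
  expect_equal(parse_ga("23+6"), 23 + 6 / 7, tolerance = 1e-9)
  expect_equal(parse_ga(c("22+0", "25")), c(22, 25))
  expect_error(parse_ga("23+9"), "parse")

  pr <- paired_rate(100, 150, 24, 26, metric = "volume")
  expect_equal(pr$rate, 25)
  expect_equal(paired_rate(7, 7, "23+0", "25+0")$rate, 0)
  expect_error(paired_rate(1, 2, 25, 24), "strictly greater")
})
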