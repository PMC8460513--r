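# Volume and mesh IO: round-trips, format errors, mesh validation.

test_that("label volumes round-trip through NIfTI with sidecar label maps", {
  arr <- array(0L, c(10, 10, 10))
  arr[4:6, 4:6, 4:6] <- 1L
  vol <- label_volume(arr, spacing = c(0.8, 0.8, 0.8))
  expect_true(vol$isotropic)
  expect_equal(sum(vol$data == 0L), 1000L - 27L)

  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_label_volume(vol, path)
  back <- read_label_volume(path)
  expect_identical(back$data, vol$data)
  expect_lt(max(abs(back$spacing - vol$spacing)), 1e-6)
  expect_lt(max(abs(back$affine - vol$affine)), 1e-5)
  expect_identical(back$label_map, vol$label_map)

  # empty volume reads back with zero foreground
  empty <- label_volume(array(0L, c(10, 10, 10)), spacing = rep(1, 3))
  p2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_label_volume(empty, p2)
  expect_equal(sum(read_label_volume(p2)$data != 0L), 0L)
})

test_that("non-integer NIfTI data and invalid geometry are rejected", {
  img <- RNifti::asNifti(array(0.5, c(4, 4, 4)))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  expect_error(read_label_volume(path), "integer")
  expect_error(label_volume(array(0L, c(4, 4, 4)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(label_volume(array(0L, c(4, 4, 4)), spacing = rep(1, 3),
                            affine = matrix(0, 4, 4)), "invertible")
  expect_error(label_volume(array(5L, c(2, 2, 2)), spacing = rep(1, 3)),
               "label_map")
})

test_that("meshes round-trip through PLY (ascii and binary) and VTK", {
  m <- icosphere(2, radius = 10)
  m$fields$shape_index <- seq_len(nrow(m$vertices)) / nrow(m$vertices)
  for (spec in list(c("ply", "ascii"), c("ply", "binary_little_endian"),
                    c("vtk", "ascii"))) {
    path <- withr::local_tempfile(fileext = paste0(".", spec[1]))
    write_mesh(m, path, format = spec[2])
    back <- read_mesh(path)
    expect_lt(max(abs(back$vertices - m$vertices)), 1e-5)
    expect_identical(back$faces, m$faces)
    expect_lt(max(abs(back$fields$shape_index - m$fields$shape_index)), 1e-6)
  }
})

test_that("unit tetrahedron connectivity survives a write/read cycle", {
  tet <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                      rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(tet, path, format = "ascii")
  back <- read_mesh(path)
  expect_identical(back$faces, tet$faces)
  expect_equal(back$vertices, tet$vertices, tolerance = 1e-6)
})

test_that("quad-faced files are a format error unless triangulation is allowed", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0", "4 0 1 2 3"), path)
  expect_error(read_mesh(path), "triangulate")
  tri <- read_mesh(path, triangulate = TRUE)
  expect_equal(nrow(tri$faces), 2L)
})

test_that("closedness/orientation validation reports and repairs meshes", {
  ico <- icosphere(2, radius = 5)
  rep1 <- validate_closed_oriented(ico)
  expect_true(rep1$closed)
  expect_true(rep1$oriented)
  expect_gt(rep1$signed_volume, 0)

  open <- surface_mesh(ico$vertices, ico$faces[-1, ])
  rep2 <- validate_closed_oriented(open)
  expect_false(rep2$closed)
  expect_equal(rep2$n_boundary_edges, 3L)

  inward <- surface_mesh(ico$vertices, ico$faces[, c(1, 3, 2)])
  rep3 <- validate_closed_oriented(inward, fix = TRUE)
  expect_true(rep3$oriented)
  expect_gt(mesh_signed_volume(rep3$mesh), 0)
})

test_that("degenerate faces and out-of-range indices are constructor errors", {
  v <- diag(3)
  expect_error(surface_mesh(v, rbind(c(1, 1, 2))), "degenerate")
  expect_error(surface_mesh(v, rbind(c(1, 2, 4))), "out of range")
})
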