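# Shared analytic fixtures, built in code at test time.

# voxelized sphere of radius r (mm) at isotropic spacing, centred on the grid
voxel_sphere <- function(r = 10, spacing = 0.5, label = 1L) {
  n <- ceiling(2 * (r + 2 * spacing) / spacing)
  cc <- (seq_len(n) - 1) * spacing - (n - 1) * spacing / 2
  d2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  arr <- array(0L, c(n, n, n))
  arr[d2 <= r^2] <- label
  origin <- -(n - 1) * spacing / 2
  label_volume(arr, spacing = rep(spacing, 3),
               affine = rbind(cbind(diag(spacing, 3), rep(origin, 3)),
                              c(0, 0, 0, 1)))
}

# open cylinder mesh (radius r, height h), consistently outward-wound
cylinder_mesh <- function(r = 5, h = 30, n_theta = 60, n_z = 31) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  z <- seq(0, h, length.out = n_z)
  g <- expand.grid(t = th, z = z)
  v <- cbind(r * cos(g$t), r * sin(g$t), g$z)
  f <- list()
  for (iz in seq_len(n_z - 1)) for (it in seq_len(n_theta)) {
    a <- (iz - 1) * n_theta + it
    b <- (iz - 1) * n_theta + (it %% n_theta) + 1
    cc <- iz * n_theta + it
    d <- iz * n_theta + (it %% n_theta) + 1
    f[[length(f) + 1]] <- c(a, b, d)
    f[[length(f) + 1]] <- c(a, d, cc)
  }
  list(mesh = surface_mesh(v, do.call(rbind, f)),
       interior = g$z > h / 10 & g$z < h * 9 / 10)
}

# default folded phantom pair under the study conditions: ~10% brain volume
# growth over 2 weeks plus the default folding-rate increase
study_pair <- function(seed, subdivisions = 3) {
  sp <- phantom_spec(fold_amplitude = 2, ventricle_scale = 0.25, seed = seed)
  generate_longitudinal_pair(
    sp,
    growth_per_week = c(unmyelinated_wm = 3100, ventricles = 50,
                        cerebellum = 180),
    fold_increase_per_week = 0.5, delta_ga = 2,
    subdivisions = subdivisions)
}

# correspondence error (mm) of a match against the identity ground truth,
# measured on the post surface
match_errors <- function(corr, pair) {
  v <- pair$post$mesh$vertices
  sqrt(rowSums((v[corr$target_vertex, , drop = FALSE] - v)^2))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
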