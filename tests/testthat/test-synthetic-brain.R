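# Phantom generator: truth volumes, determinism, longitudinal growth,
# landmarks, cohorts.

test_that("phantom truth volumes are recovered from the voxel grid", {
  # unfolded phantom: closed-form ellipsoid oracle
  sp0 <- phantom_spec(fold_amplitude = 0, ventricle_scale = 0, spacing = 0.8)
  ph0 <- generate_phantom(sp0)
  expect_rel_equal(volume_from_labels(ph0$volume, "unmyelinated_wm"),
                   4 / 3 * pi * 30 * 25 * 20, 0.02)
  expect_equal(volume_from_labels(ph0$volume, "ventricles"), 0)

  # folded phantom with ventricle: quadrature truth at 0.8 mm spacing
  sp <- phantom_spec(fold_amplitude = 3, ventricle_scale = 0.25, seed = 7)
  ph <- generate_phantom(sp)
  expect_rel_equal(volume_from_labels(ph$volume, "unmyelinated_wm"),
                   ph$truth$wm_volume, 0.02)
  expect_rel_equal(volume_from_labels(ph$volume, "ventricles"),
                   ph$truth$ventricle_volume, 0.02)
  expect_rel_equal(volume_from_labels(ph$volume, "cerebellum"),
                   ph$truth$cerebellum_volume, 0.02)
})

test_that("volume recovery holds within 2% across random specs", {
  set.seed(42)
  for (i in 1:4) {
    sp <- phantom_spec(semi_axes = c(30, 25, 20) * runif(1, 0.9, 1.15),
                       fold_amplitude = runif(1, 0, 4),
                       ventricle_scale = runif(1, 0.2, 0.3),
                       seed = 100 + i)
    ph <- generate_phantom(sp)
    expect_rel_equal(volume_from_labels(ph$volume, "unmyelinated_wm"),
                     ph$truth$wm_volume, 0.02)
    expect_rel_equal(volume_from_labels(ph$volume, "ventricles"),
                     ph$truth$ventricle_volume, 0.02)
    expect_rel_equal(volume_from_labels(ph$volume, "cerebellum"),
                     ph$truth$cerebellum_volume, 0.02)
  }
})

test_that("generation is deterministic under a fixed seed", {
  sp <- phantom_spec(fold_amplitude = 2, seed = 11)
  expect_identical(generate_phantom(sp)$volume$data,
                   generate_phantom(sp)$volume$data)
  co1 <- generate_cohort(3, 3, 3, seed = 9)
  co2 <- generate_cohort(3, 3, 3, seed = 9)
  expect_identical(co1$table, co2$table)
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(fold_amplitude = 15), "self-intersection")
  expect_error(phantom_spec(ventricle_scale = 0.9, fold_amplitude = 4),
               "inside")
  # overlapping cerebellum is caught at generation time
  sp <- phantom_spec(cerebellum_offset = c(0, -10, -5))
  expect_error(generate_phantom(sp), "overlaps")
})

test_that("longitudinal pairs grow structures at the requested rates", {
  sp <- phantom_spec(fold_amplitude = 2, ventricle_scale = 0.25, seed = 3)
  pr <- generate_longitudinal_pair(
    sp, growth_per_week = c(unmyelinated_wm = 0, ventricles = 648,
                            cerebellum = 0),
    fold_increase_per_week = 0, delta_ga = 2, voxelize = TRUE)
  dv <- volume_from_labels(pr$post$volume, "ventricles") -
    volume_from_labels(pr$pre$volume, "ventricles")
  expect_rel_equal(dv, 1296, 0.05)
  dwm <- volume_from_labels(pr$post$volume, "unmyelinated_wm") -
    volume_from_labels(pr$pre$volume, "unmyelinated_wm")
  expect_lt(abs(dwm) / volume_from_labels(pr$pre$volume, "unmyelinated_wm"),
            0.01)
  expect_equal(pr$correspondence, seq_len(nrow(pr$pre$mesh$vertices)))

  # zero growth: volumes unchanged within voxelization error
  pr0 <- generate_longitudinal_pair(
    sp, growth_per_week = c(unmyelinated_wm = 0, ventricles = 0,
                            cerebellum = 0),
    fold_increase_per_week = 0, delta_ga = 2, voxelize = TRUE)
  expect_rel_equal(volume_from_labels(pr0$post$volume, "unmyelinated_wm"),
                   volume_from_labels(pr0$pre$volume, "unmyelinated_wm"),
                   0.01)
  expect_error(generate_longitudinal_pair(sp, delta_ga = 0), "positive")
})

test_that("the default folding rate raises post-surface curvedness", {
  pr <- study_pair(seed = 21)
  expect_gt(curvature_field(pr$post$mesh)$summary$mean_curvedness,
            curvature_field(pr$pre$mesh)$summary$mean_curvedness)
})

test_that("gyrification grows monotonically with fold amplitude", {
  grid <- 0:4
  stats <- lapply(grid, function(A) {
    cf <- curvature_field(phantom_surface_mesh(
      phantom_spec(fold_amplitude = A, seed = 3), 3))$summary
    c(curv = cf$mean_curvedness, sulcal = 1 - cf$gyral_area_fraction)
  })
  curv <- vapply(stats, `[[`, numeric(1), "curv")
  sulcal <- vapply(stats, `[[`, numeric(1), "sulcal")
  expect_true(all(diff(curv) > 0))
  expect_equal(stats::cor(grid, curv, method = "spearman"), 1)
  # folding carves sulci: concave area appears and grows once folds are
  # deep enough to overcome the convex base surface
  expect_true(all(diff(sulcal[2:5]) > 0))
  expect_gt(sulcal[5], 0.1)
})

test_that("phantom landmarks are constructed on the labeled anatomy", {
  sp <- phantom_spec(fold_amplitude = 2, ventricle_scale = 0.25, seed = 7)
  lm <- phantom_landmarks(sp)
  expect_equal(tcd(lm), 2 * sp$cerebellum_semi_axes[1])
  expect_equal(vw(lm), 2 * sp$semi_axes[1] * sp$ventricle_scale)
  expect_equal(chl(lm), sp$cerebellum_semi_axes[3])
  expect_equal(cso(lm), sp$cso_angle_deg, tolerance = 1e-9)
  # mirror symmetry of the TCD endpoints about the midsagittal plane
  expect_equal(lm$tcd_left * c(-1, 1, 1), lm$tcd_right)
  # VW endpoints sit on the ventricle boundary, TCD on the cerebellum
  vax <- sp$semi_axes * sp$ventricle_scale
  expect_equal(sum((lm$vw_lateral / vax)^2), 1, tolerance = 1e-9)
  rel <- (lm$tcd_right - sp$cerebellum_offset) / sp$cerebellum_semi_axes
  expect_equal(sum(rel^2), 1, tolerance = 1e-9)
  # no ventricle -> VW landmarks absent and vw() errors
  lm0 <- phantom_landmarks(phantom_spec(ventricle_scale = 0))
  expect_error(vw(lm0), "missing landmarks")
})

test_that("cohort tables have the study structure and linked phantom specs", {
  co <- generate_cohort(12, 12, 12, seed = 5, phantom_specs = TRUE)
  tab <- co$table
  # 12 paired subjects (2 scans) + 24 single-scan controls, 6 metrics each
  expect_equal(nrow(tab), (12 * 2 + 24) * 6)
  expect_setequal(unique(tab$group), c("mmc", "control_early", "control_late"))
  expect_true(all(tab$ga_weeks > 0))
  expect_false(anyDuplicated(tab[, c("subject_id", "timepoint", "metric")]) > 0)
  # a subject phantom spec reproduces the table volume it was built for
  sj <- co$subjects[["mmc01"]]
  ph <- generate_phantom(sj$phantoms[[1]])
  truth_vent <- ph$truth$ventricle_volume
  want <- sj$base[["ventricles"]] +
    sj$rates[["ventricles"]] * (sj$scans$ga[1] - 22)
  expect_rel_equal(truth_vent, want, 0.01)
  expect_rel_equal(volume_from_labels(ph$volume, "ventricles"), want, 0.03)
  expect_error(generate_cohort(1, 12, 12), ">= 2")
})
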