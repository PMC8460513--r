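# Synthetic gyrified brain phantoms with analytic ground truth.
#
# The phantom brain is a star-shaped surface around the origin: an ellipsoid
# radius modulated by a band-limited sum of real spherical harmonics of one
# degree (the fold frequency) with seeded random coefficients, scaled so the
# perturbation peaks at exactly `fold_amplitude` mm. Ventricles are an
# interior co-centred ellipsoid; the cerebellum a disjoint posterior-inferior
# ellipsoid. Longitudinal pairs share the harmonic coefficients and the
# icosphere parameterisation, so the ground-truth vertex correspondence is
# the identity.

#' Phantom specification
#'
#' @param semi_axes length-3 ellipsoid semi-axes (a, b, c) of the brain
#'   surface, mm (lateral, anterior-posterior, inferior-superior).
#' @param fold_amplitude peak radial folding amplitude, mm (>= 0, must be
#'   below `min(semi_axes)/2`).
#' @param fold_frequency spherical-harmonic degree of the folding pattern.
#' @param ventricle_scale ventricle ellipsoid semi-axes as a fraction of the
#'   brain semi-axes (0 disables the ventricle).
#' @param cerebellum_offset length-3 centre of the cerebellum ellipsoid, mm
#'   (posterior-inferior of the brain by default).
#' @param cerebellum_semi_axes length-3 cerebellum semi-axes, mm.
#' @param spacing isotropic voxel spacing of emitted volumes, mm.
#' @param cso_angle_deg clivus-supraocciput angle built into the landmark
#'   set, degrees.
#' @param seed RNG seed fixing the folding pattern.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes = c(30, 25, 20), fold_amplitude = 2,
                         fold_frequency = 6, ventricle_scale = 0.25,
                         cerebellum_offset = c(0, -30, -22),
                         cerebellum_semi_axes = c(12, 9, 8),
                         spacing = 0.8, cso_angle_deg = 75, seed = 1) {
  if (fold_amplitude < 0) stop("fold_amplitude must be >= 0")
  if (fold_amplitude >= min(semi_axes) / 2)
    stop("fold_amplitude must be below min(semi_axes)/2 (self-intersection)")
  if (ventricle_scale < 0 || ventricle_scale >= 1)
    stop("ventricle_scale must be in [0, 1)")
  if (ventricle_scale > 0) {
    # the ventricle is a concentric scaled copy of the brain ellipsoid, so
    # it stays strictly inside the folded surface iff the scale leaves room
    # for the deepest inward fold along the shortest axis
    if (ventricle_scale >= 1 - fold_amplitude / min(semi_axes))
      stop("ventricle ellipsoid is not strictly inside the brain surface")
  }
  structure(list(semi_axes = as.numeric(semi_axes),
                 fold_amplitude = fold_amplitude,
                 fold_frequency = as.integer(fold_frequency),
                 ventricle_scale = ventricle_scale,
                 cerebellum_offset = as.numeric(cerebellum_offset),
                 cerebellum_semi_axes = as.numeric(cerebellum_semi_axes),
                 spacing = spacing, cso_angle_deg = cso_angle_deg,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Real spherical harmonics of one degree at unit directions u (N x 3).
# Returns N x (2l+1) basis matrix with orthonormal scaling.
.sph_basis <- function(u, l) {
  ct <- pmin(pmax(u[, 3], -1), 1)
  phi <- atan2(u[, 2], u[, 1])
  if (l == 0) return(matrix(sqrt(1 / (4 * pi)), nrow(u), 1))
  P <- t(pracma::legendre(l, ct))  # N x (l+1), columns m = 0..l
  out <- matrix(0, nrow(u), 2 * l + 1)
  out[, 1] <- sqrt((2 * l + 1) / (4 * pi)) * P[, 1]
  col <- 2L
  for (m in seq_len(l)) {
    nrm <- sqrt((2 * l + 1) / (2 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    out[, col] <- nrm * P[, m + 1] * cos(m * phi); col <- col + 1L
    out[, col] <- nrm * P[, m + 1] * sin(m * phi); col <- col + 1L
  }
  out
}

# Seeded unit-peak folding function f(u) in [-1, 1]; closure over coefs.
.fold_function <- function(l, seed) {
  old <- .Random.seed_save()
  set.seed(seed)
  coefs <- stats::rnorm(2 * l + 1)
  .Random.seed_restore(old)
  probe <- icosphere(4)$vertices
  peak <- max(abs(.sph_basis(probe, l) %*% coefs))
  function(u) as.vector(.sph_basis(u, l) %*% coefs) / peak
}

# save/restore .Random.seed so generators are seed-local
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Radius of the brain surface along unit directions u for a spec.
.brain_radius <- function(spec, u, foldfn = NULL) {
  re <- 1 / sqrt((u[, 1] / spec$semi_axes[1])^2 +
                 (u[, 2] / spec$semi_axes[2])^2 +
                 (u[, 3] / spec$semi_axes[3])^2)
  if (spec$fold_amplitude > 0) {
    if (is.null(foldfn)) foldfn <- .fold_function(spec$fold_frequency, spec$seed)
    re <- re + spec$fold_amplitude * foldfn(u)
  }
  re
}

# Angular quadrature nodes/weights on the unit sphere (weights sum to 4*pi).
.sphere_quadrature <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- icosphere(5)
      w <- vertex_areas(s)
      cache <<- list(u = s$vertices, w = w * (4 * pi / sum(w)))
    }
    cache
  }
})

# Volume enclosed by the star-shaped brain surface: V = 1/3 * sum w r(u)^3.
.brain_interior_volume <- function(spec, foldfn = NULL) {
  q <- .sphere_quadrature()
  sum(q$w * .brain_radius(spec, q$u, foldfn)^3) / 3
}

.ellipsoid_volume <- function(axes) 4 / 3 * pi * prod(axes)

#' Analytic truth surface mesh of a phantom
#'
#' The brain surface sampled on an icosphere parameterisation: vertex i sits
#' at `r(u_i) * u_i`. Two phantoms sharing `fold_frequency` and `seed`
#' produce meshes in vertex-wise correspondence.
#'
#' @param spec a `phantom_spec`.
#' @param subdivisions icosphere subdivision level (default 4, 2562
#'   vertices).
#' @return a closed outward-oriented `surface_mesh`.
#' @export
phantom_surface_mesh <- function(spec, subdivisions = 4) {
  s <- icosphere(subdivisions)
  u <- s$vertices
  r <- .brain_radius(spec, u)
  surface_mesh(u * r, s$faces)
}

#' Generate a labeled phantom volume with ground truth
#'
#' Voxelises the phantom at the spec's spacing into a `label_volume`
#' (white matter = 1, ventricles = 2, cerebellum = 3, background = 0) and
#' returns reference truth computed independently of the voxel grid:
#' structure volumes by high-order angular quadrature / closed forms, a
#' reference surface area from a fine analytic mesh, the folding function,
#' and constructed landmarks.
#'
#' @param spec a `phantom_spec`.
#' @return list with elements `volume` (a `label_volume`) and `truth`
#'   (list: `wm_volume`, `ventricle_volume`, `cerebellum_volume`,
#'   `surface_area`, `fold_function`, `landmarks`, ...).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  foldfn <- if (spec$fold_amplitude > 0)
    .fold_function(spec$fold_frequency, spec$seed) else NULL
  h <- spec$spacing
  rmax <- max(spec$semi_axes) + spec$fold_amplitude
  lo <- pmin(-rmax, spec$cerebellum_offset - spec$cerebellum_semi_axes) - 2 * h
  hi <- pmax(rmax, spec$cerebellum_offset + spec$cerebellum_semi_axes) + 2 * h
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  origin <- lo
  affine <- rbind(cbind(diag(h, 3), origin), c(0, 0, 0, 1))
  xs <- origin[1] + (seq_len(dims[1]) - 1L) * h
  ys <- origin[2] + (seq_len(dims[2]) - 1L) * h
  zs <- origin[3] + (seq_len(dims[3]) - 1L) * h
  lab <- array(0L, dims)
  vax <- spec$semi_axes * spec$ventricle_scale
  # slice-wise evaluation keeps memory modest
  xy <- cbind(rep(xs, times = dims[2]), rep(ys, each = dims[1]))
  for (k in seq_len(dims[3])) {
    z <- zs[k]
    p <- cbind(xy, z)
    r <- sqrt(rowSums(p^2))
    u <- p / pmax(r, 1e-12)
    inside_brain <- r <= .brain_radius(spec, u, foldfn)
    sl <- integer(nrow(p))
    sl[inside_brain] <- 1L
    if (spec$ventricle_scale > 0) {
      inv <- (p[, 1] / vax[1])^2 + (p[, 2] / vax[2])^2 + (p[, 3] / vax[3])^2 <= 1
      sl[inv] <- 2L
    }
    pc <- sweep(p, 2, spec$cerebellum_offset, "-")
    inc <- (pc[, 1] / spec$cerebellum_semi_axes[1])^2 +
      (pc[, 2] / spec$cerebellum_semi_axes[2])^2 +
      (pc[, 3] / spec$cerebellum_semi_axes[3])^2 <= 1
    if (any(inc & inside_brain))
      stop("cerebellum ellipsoid overlaps the brain surface; adjust the spec")
    sl[inc] <- 3L
    lab[, , k] <- sl
  }
  vol <- label_volume(lab, spacing = rep(h, 3), affine = affine)
  interior <- .brain_interior_volume(spec, foldfn)
  vent_vol <- if (spec$ventricle_scale > 0) .ellipsoid_volume(vax) else 0
  ref <- phantom_surface_mesh(spec, subdivisions = 5)
  truth <- list(
    wm_volume = interior - vent_vol,
    ventricle_volume = vent_vol,
    cerebellum_volume = .ellipsoid_volume(spec$cerebellum_semi_axes),
    surface_area = surface_area(ref),
    fold_function = foldfn,
    landmarks = phantom_landmarks(spec),
    spec = spec)
  list(volume = vol, truth = truth)
}

#' Constructed landmark set of a phantom
#'
#' Landmarks are emitted by construction from the spec geometry (the study
#' equivalents are placed manually): transverse-cerebellar-diameter
#' endpoints at the cerebellar lateral extremes, ventricle-width endpoints
#' at the atrial mid-height, a foramen-magnum plane through the cerebellum
#' centre (caudal normal -z), the lowest cerebellar point, and clivus /
#' supraocciput line segments meeting at `cso_angle_deg` in the midsagittal
#' plane.
#'
#' @param spec a `phantom_spec`.
#' @return a `landmark_set` (see [landmark_set()]).
#' @export
phantom_landmarks <- function(spec) {
  cb <- spec$cerebellum_offset
  ca <- spec$cerebellum_semi_axes
  vax <- spec$semi_axes * spec$ventricle_scale
  z_fm <- cb[3]
  half <- spec$cso_angle_deg / 2 * pi / 180
  p0 <- c(0, cb[2] + ca[2], z_fm)
  d_cliv <- c(0, sin(half), cos(half))
  d_socc <- c(0, -sin(half), cos(half))
  pts <- list(
    tcd_left = cb + c(-ca[1], 0, 0),
    tcd_right = cb + c(ca[1], 0, 0),
    # ventricular width endpoints exist only when the ventricle does;
    # vw() then raises a missing-landmark error, as it should
    vw_medial = if (spec$ventricle_scale > 0) c(-vax[1], 0, 0),
    vw_lateral = if (spec$ventricle_scale > 0) c(vax[1], 0, 0),
    fm_plane_a = c(10, 0, z_fm),
    fm_plane_b = c(-10, 5, z_fm),
    fm_plane_c = c(0, -10, z_fm),
    cereb_lowest = cb + c(0, 0, -ca[3]),
    clivus_a = p0, clivus_b = p0 + 20 * d_cliv,
    supraocciput_a = p0, supraocciput_b = p0 + 20 * d_socc)
  landmark_set(pts[!vapply(pts, is.null, logical(1))])
}

#' Generate a longitudinal phantom pair with known correspondence
#'
#' The post phantom keeps the folding pattern (same harmonic coefficients)
#' and the icosphere parameterisation of the pre phantom; structure volumes
#' grow linearly at the given per-week rates and the folding amplitude by
#' `fold_increase_per_week`, so the ground-truth vertex correspondence
#' between the two truth meshes is the identity.
#'
#' @param spec pre-timepoint `phantom_spec`.
#' @param growth_per_week named vector of volume growth rates (mm^3/week)
#'   for `unmyelinated_wm`, `ventricles`, `cerebellum`.
#' @param fold_increase_per_week folding amplitude increase, mm/week.
#' @param delta_ga scan interval, decimal weeks (> 0).
#' @param ga_pre gestational age at the pre scan, decimal weeks.
#' @param voxelize also voxelise both phantoms (slower); otherwise only
#'   truth meshes and truth volumes are returned.
#' @param subdivisions icosphere level for the truth meshes.
#' @return list with `pre`, `post` (each: `spec`, `mesh`, truth volumes,
#'   optionally `volume`), `correspondence` (identity), `rates`, `ga_pre`,
#'   `ga_post`.
#' @export
generate_longitudinal_pair <- function(spec,
                                       growth_per_week = c(unmyelinated_wm = 8000,
                                                           ventricles = 648,
                                                           cerebellum = 770),
                                       fold_increase_per_week = 0.5,
                                       delta_ga = 2, ga_pre = 23.857,
                                       voxelize = FALSE, subdivisions = 4) {
  if (delta_ga <= 0) stop("delta_ga must be positive")
  foldfn <- if (spec$fold_amplitude > 0 || fold_increase_per_week > 0)
    .fold_function(spec$fold_frequency, spec$seed) else NULL
  g <- function(nm) if (nm %in% names(growth_per_week)) growth_per_week[[nm]] else 0
  interior_pre <- .brain_interior_volume(spec, foldfn)
  vax <- spec$semi_axes * spec$ventricle_scale
  vent_pre <- if (spec$ventricle_scale > 0) .ellipsoid_volume(vax) else 0
  wm_pre <- interior_pre - vent_pre
  cb_pre <- .ellipsoid_volume(spec$cerebellum_semi_axes)
  vent_post <- vent_pre + g("ventricles") * delta_ga
  wm_post <- wm_pre + g("unmyelinated_wm") * delta_ga
  cb_post <- cb_pre + g("cerebellum") * delta_ga
  if (vent_post < 0 || wm_post <= 0 || cb_post <= 0)
    stop("growth rates drive a structure volume non-positive")
  A_post <- spec$fold_amplitude + fold_increase_per_week * delta_ga
  # post brain semi-axes: uniform scale s so interior volume hits target
  target_interior <- wm_post + vent_post
  post <- spec
  post$fold_amplitude <- A_post
  f_int <- function(s) {
    p <- post; p$semi_axes <- spec$semi_axes * s
    .brain_interior_volume(p, foldfn) - target_interior
  }
  s_b <- stats::uniroot(f_int, c(0.5, 2), tol = 1e-8)$root
  post$semi_axes <- spec$semi_axes * s_b
  s_v <- if (vent_pre > 0) (vent_post / vent_pre)^(1 / 3) else 0
  post$ventricle_scale <- spec$ventricle_scale * s_v / s_b
  post$cerebellum_semi_axes <- spec$cerebellum_semi_axes * (cb_post / cb_pre)^(1 / 3)
  post <- do.call(phantom_spec, post[setdiff(names(post), character(0))])
  mesh_pre <- phantom_surface_mesh(spec, subdivisions)
  mesh_post <- phantom_surface_mesh(post, subdivisions)
  out <- list(
    pre = list(spec = spec, mesh = mesh_pre, wm_volume = wm_pre,
               ventricle_volume = vent_pre, cerebellum_volume = cb_pre),
    post = list(spec = post, mesh = mesh_post, wm_volume = wm_post,
                ventricle_volume = vent_post, cerebellum_volume = cb_post),
    correspondence = seq_len(nrow(mesh_pre$vertices)),
    rates = c(unmyelinated_wm = g("unmyelinated_wm"),
              ventricles = g("ventricles"), cerebellum = g("cerebellum"),
              fold = fold_increase_per_week),
    ga_pre = ga_pre, ga_post = ga_pre + delta_ga)
  if (voxelize) {
    out$pre$volume <- generate_phantom(spec)$volume
    out$post$volume <- generate_phantom(post)$volume
  }
  out
}

# ------------------------------------------------------------------ cohort --

#' Effect configuration for synthetic cohorts
#'
#' Group-level distributions of per-week growth rates. Control defaults
#' take their location and spread from the scale of mid-gestation control
#' growth (ventricles ~650 mm^3/week); the affected (MMC) group defaults to
#' strongly elevated ventricular growth and an elevated folding rate, the
#' condition the pipeline is built to detect. `zero_effect = TRUE` makes
#' the affected group identical to controls (null calibration);
#' `ventricle_shift_sd` instead shifts the affected ventricular-rate mean
#' by that many control SDs (power studies).
#'
#' @param zero_effect if TRUE all group differences are removed.
#' @param ventricle_shift_sd optional affected-group ventricular-rate shift
#'   in control-SD units (overrides the default affected mean).
#' @return nested list of per-structure `(mean, sd)` rate parameters.
#' @export
cohort_effects <- function(zero_effect = FALSE, ventricle_shift_sd = NULL) {
  ctrl <- list(ventricles = c(mean = 648, sd = 389),
               unmyelinated_wm = c(mean = 8000, sd = 1500),
               cerebellum = c(mean = 770, sd = 200),
               mean_si = c(mean = 0.012, sd = 0.004))
  mmc <- list(ventricles = c(mean = 3699, sd = 2775),
              unmyelinated_wm = c(mean = 6500, sd = 1500),
              cerebellum = c(mean = 440, sd = 250),
              mean_si = c(mean = 0.033, sd = 0.010))
  if (zero_effect) mmc <- ctrl
  if (!is.null(ventricle_shift_sd)) {
    mmc <- ctrl
    mmc$ventricles["mean"] <- ctrl$ventricles["mean"] +
      ventricle_shift_sd * ctrl$ventricles["sd"]
  }
  list(control = ctrl, mmc = mmc)
}

# baseline structure volumes (mm^3) and SI at the 22-week reference
.cohort_baselines <- list(
  ventricles = c(mean = 900, sd = 120),
  unmyelinated_wm = c(mean = 50000, sd = 4000),
  cerebellum = c(mean = 2500, sd = 250),
  mean_si = c(mean = 0.05, sd = 0.01))

#' Generate a synthetic cohort table (plus per-subject phantom specs)
#'
#' Emulates the study design: `n_mmc` affected fetuses scanned before and
#' after surgery, and two control groups scanned once each at early / late
#' gestational ages. Per-subject growth rates are drawn from
#' `effect_config`; absolute structure volumes follow linear growth from a
#' 22-week baseline; biometrics (TCD, VW) are cube-root functions of the
#' cerebellar / ventricular volumes with multiplicative noise, inducing the
#' moderate volume-biometry correlations the analysis stage looks for.
#'
#' @param n_mmc,n_early,n_late group sizes (each >= 2).
#' @param effect_config from [cohort_effects()].
#' @param seed RNG seed.
#' @param measurement_cv multiplicative measurement noise (coefficient of
#'   variation) applied to every emitted volume.
#' @param phantom_specs also attach a per-subject-scan `phantom_spec` whose
#'   analytic truth volumes match the emitted table values.
#' @return list with `table` (long-format data.frame: subject_id, group,
#'   timepoint, ga_weeks, metric, value) and `subjects` (per-scan
#'   generative parameters, incl. phantom specs when requested).
#' @export
generate_cohort <- function(n_mmc = 12, n_early = 12, n_late = 12,
                            effect_config = cohort_effects(), seed = 1,
                            measurement_cv = 0.02, phantom_specs = FALSE) {
  if (min(n_mmc, n_early, n_late) < 2) stop("group sizes must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- function(p, n) stats::rnorm(n, p["mean"], p["sd"])
  tdraw <- function(p, n, lo = 0) pmax(draw(p, n), lo)
  structures <- c("ventricles", "unmyelinated_wm", "cerebellum")
  rows <- list(); subjects <- list()
  emit <- function(sid, group, timepoint, ga, vols, si) {
    noisy <- vols * (1 + stats::rnorm(length(vols), 0, measurement_cv))
    tcd <- 2 * (3 * noisy["cerebellum"] / (4 * pi))^(1 / 3) * 0.85 *
      (1 + stats::rnorm(1, 0, 0.05))
    vw <- (3 * noisy["ventricles"] / (4 * pi))^(1 / 3) * 1.6 *
      (1 + stats::rnorm(1, 0, 0.08))
    vals <- c(noisy, mean_si = unname(si), tcd_mm = unname(tcd),
              vw_mm = unname(vw))
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = sid, group = group, timepoint = timepoint, ga_weeks = ga,
      metric = c(paste0(structures, "_volume_mm3"), "mean_si", "tcd_mm", "vw_mm"),
      value = unname(vals), stringsAsFactors = FALSE)
  }
  gen_subject <- function(sid, group, cfg, scans) {
    base <- vapply(structures, function(s) tdraw(.cohort_baselines[[s]], 1,
                                                 .cohort_baselines[[s]]["mean"] / 4),
                   numeric(1))
    si0 <- tdraw(.cohort_baselines$mean_si, 1, 0)
    rates <- vapply(structures, function(s) tdraw(cfg[[s]], 1, -Inf), numeric(1))
    si_rate <- draw(cfg$mean_si, 1)
    for (sc in seq_len(nrow(scans))) {
      ga <- scans$ga[sc]
      vols <- base + rates * (ga - 22)
      vols <- pmax(vols, base / 10)
      emit(sid, group, scans$tp[sc], ga, vols, si0 + si_rate * (ga - 22))
    }
    subjects[[sid]] <<- list(group = group, base = base, rates = rates,
                             si0 = si0, si_rate = si_rate, scans = scans)
  }
  for (i in seq_len(n_mmc)) {
    ga1 <- stats::rnorm(1, 23.86, 1.0)
    dga <- pmax(stats::rnorm(1, 2.3, 0.4), 0.8)
    gen_subject(sprintf("mmc%02d", i), "mmc",
                effect_config$mmc,
                data.frame(tp = c("pre", "post"), ga = c(ga1, ga1 + dga)))
  }
  for (i in seq_len(n_early))
    gen_subject(sprintf("ce%02d", i), "control_early", effect_config$control,
                data.frame(tp = "single", ga = stats::rnorm(1, 23.3, 1.2)))
  for (i in seq_len(n_late))
    gen_subject(sprintf("cl%02d", i), "control_late", effect_config$control,
                data.frame(tp = "single", ga = stats::rnorm(1, 28.86, 1.43)))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (phantom_specs) {
    for (si in seq_along(subjects)) {
      sj <- subjects[[si]]
      subjects[[si]]$phantoms <- lapply(seq_len(nrow(sj$scans)), function(sc) {
        ga <- sj$scans$ga[sc]
        vols <- pmax(sj$base + sj$rates * (ga - 22), sj$base / 10)
        .spec_for_volumes(vols, seed = seed + 1000L * si + sc)
      })
    }
  }
  list(table = tab, subjects = subjects)
}

# phantom spec whose analytic truth volumes equal the given structure volumes
.spec_for_volumes <- function(vols, fold_amplitude = 2, seed = 1) {
  base <- c(30, 25, 20)
  interior <- vols[["unmyelinated_wm"]] + vols[["ventricles"]]
  s <- (interior / .ellipsoid_volume(base))^(1 / 3)
  semi <- base * s
  vsc <- ((vols[["ventricles"]] / .ellipsoid_volume(semi)))^(1 / 3)
  cb <- c(12, 9, 8) * (vols[["cerebellum"]] / .ellipsoid_volume(c(12, 9, 8)))^(1 / 3)
  sp <- phantom_spec(semi_axes = semi, fold_amplitude = 0,
                     ventricle_scale = vsc,
                     cerebellum_offset = c(0, -(semi[2] + max(cb) + 2), -semi[3]),
                     cerebellum_semi_axes = cb, seed = seed)
  if (fold_amplitude > 0) {
    # folding is volume-neutral only on average; rescale to restore interior
    sp$fold_amplitude <- fold_amplitude
    f <- function(sc) { p <- sp; p$semi_axes <- semi * sc
      .brain_interior_volume(p) - interior }
    sp$semi_axes <- semi * stats::uniroot(f, c(0.7, 1.4), tol = 1e-8)$root
  }
  sp
}
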