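# Landmark-based posterior fossa and ventricular biometry: TCD, VW, CHL,
# CSO. The measurement planes/axes live in the landmark placement (manual
# in clinical practice, constructed for phantoms); the geometry here is
# plain Euclidean.

.landmark_names <- c("tcd_left", "tcd_right", "vw_medial", "vw_lateral",
                     "fm_plane_a", "fm_plane_b", "fm_plane_c",
                     "cereb_lowest", "clivus_a", "clivus_b",
                     "supraocciput_a", "supraocciput_b")

#' Named landmark set
#'
#' A named list of 3D world-mm points. Recognised names: `tcd_left`,
#' `tcd_right` (cerebellar lateral extremes), `vw_medial`, `vw_lateral`
#' (ventricular width endpoints at the atria), `fm_plane_a/b/c` (three
#' non-collinear points spanning the foramen magnum plane), `cereb_lowest`,
#' `clivus_a/b` and `supraocciput_a/b` (two line segments in the
#' midsagittal plane).
#'
#' @param points named list of length-3 numeric vectors.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points) {
  if (is.null(names(points)) || any(names(points) == ""))
    stop("landmarks must be named")
  points <- lapply(points, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || anyNA(p)) stop("each landmark must be a finite 3-vector")
    p
  })
  structure(points, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set:", length(x), "points:",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

.lm_get <- function(lm, names) {
  miss <- setdiff(names, names(lm))
  if (length(miss)) stop("missing landmarks: ", paste(miss, collapse = ", "))
  lm[names]
}

#' Transverse cerebellar diameter (TCD)
#'
#' Euclidean distance between the cerebellar lateral extreme landmarks
#' (placed on the coronal plane at the level of the atria).
#'
#' @param lm a `landmark_set` with `tcd_left`, `tcd_right`.
#' @return TCD in mm.
#' @export
tcd <- function(lm) {
  p <- .lm_get(lm, c("tcd_left", "tcd_right"))
  d <- sqrt(sum((p[[1]] - p[[2]])^2))
  if (d == 0) warning("TCD landmarks coincide")
  d
}

#' Ventricular width (VW)
#'
#' Euclidean distance between the ventricular width endpoints (placed on an
#' axis perpendicular to the ventricle at the mid-height of the atria).
#'
#' @param lm a `landmark_set` with `vw_medial`, `vw_lateral`.
#' @return VW in mm.
#' @export
vw <- function(lm) {
  p <- .lm_get(lm, c("vw_medial", "vw_lateral"))
  d <- sqrt(sum((p[[1]] - p[[2]])^2))
  if (d == 0) warning("VW landmarks coincide")
  d
}

#' Cerebellar herniation level (CHL, signed)
#'
#' Signed perpendicular distance of the lowest cerebellar point from the
#' foramen magnum plane, measured along the caudally oriented plane normal:
#' positive values mean the cerebellum lies below the foramen magnum
#' (herniated), so surgical reversal is a decrease.
#'
#' @param lm a `landmark_set` with `fm_plane_a/b/c` and `cereb_lowest`.
#' @param caudal length-3 vector indicating the caudal direction used to
#'   orient the plane normal (default -z).
#' @return signed CHL in mm.
#' @export
chl <- function(lm, caudal = c(0, 0, -1)) {
  p <- .lm_get(lm, c("fm_plane_a", "fm_plane_b", "fm_plane_c", "cereb_lowest"))
  u <- p[[2]] - p[[1]]; v <- p[[3]] - p[[1]]
  n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12 * max(sqrt(sum(u^2)), sqrt(sum(v^2)), 1))
    stop("foramen magnum plane points are collinear")
  n <- n / nn
  if (sum(n * caudal) < 0) n <- -n
  sum(n * (p[[4]] - p[[1]]))
}

#' Clivus-supraocciput angle (CSO)
#'
#' Angle between the clivus and supraocciput line directions, reported in
#' (0, 180] degrees without folding to <= 90 (the anatomical angle can be
#' obtuse). Independent of the point order within each line.
#'
#' @param lm a `landmark_set` with `clivus_a/b`, `supraocciput_a/b`.
#' @return angle in degrees.
#' @export
cso <- function(lm) {
  p <- .lm_get(lm, c("clivus_a", "clivus_b", "supraocciput_a", "supraocciput_b"))
  d1 <- p[[2]] - p[[1]]; d2 <- p[[4]] - p[[3]]
  n1 <- sqrt(sum(d1^2)); n2 <- sqrt(sum(d2^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero-length biometry line")
  u1 <- d1 / n1; u2 <- d2 / n2
  cross_n2 <- 1 - sum(u1 * u2)^2
  if (cross_n2 < 1e-12) return(0)  # parallel lines: minimal angle 0
  # rays emanate from the mutual closest points of the two lines, so the
  # angle is independent of the point order within each segment and is not
  # folded to <= 90 degrees
  w <- p[[1]] - p[[3]]
  b <- sum(u1 * u2)
  t1 <- (b * sum(u2 * w) - sum(u1 * w)) / (1 - b^2)
  t2 <- (sum(u2 * w) - b * sum(u1 * w)) / (1 - b^2)
  c1 <- p[[1]] + t1 * u1
  c2 <- p[[3]] + t2 * u2
  pick_dir <- function(a, bpt, cp) {
    # direction from the closest point towards the farther segment endpoint
    if (sum((a - cp)^2) >= sum((bpt - cp)^2)) (a - cp) else (bpt - cp)
  }
  r1 <- pick_dir(p[[1]], p[[2]], c1)
  r2 <- pick_dir(p[[3]], p[[4]], c2)
  ct <- sum(r1 * r2) / sqrt(sum(r1^2) * sum(r2^2))
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

#' All four biometric measures of a landmark set
#'
#' @param lm a `landmark_set`.
#' @return data.frame with one row: `tcd_mm`, `vw_mm`, `chl_mm`,
#'   `cso_deg`.
#' @export
biometry_panel <- function(lm) {
  data.frame(tcd_mm = tcd(lm), vw_mm = vw(lm), chl_mm = chl(lm),
             cso_deg = cso(lm))
}

#' Read / write landmark CSV files
#'
#' CSV columns: `subject_id`, `name`, `x`, `y`, `z` (mm).
#'
#' @param path CSV path.
#' @return named list of `landmark_set` objects, one per subject.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "name", "x", "y", "z")
  if (!all(need %in% names(df))) stop("landmark CSV needs columns: ",
                                      paste(need, collapse = ", "))
  out <- lapply(split(df, df$subject_id), function(s) {
    landmark_set(stats::setNames(lapply(seq_len(nrow(s)), function(i)
      c(s$x[i], s$y[i], s$z[i])), s$name))
  })
  out
}

#' @rdname read_landmarks
#' @param landmarks named list of `landmark_set` (names = subject ids).
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- do.call(rbind, lapply(names(landmarks), function(sid) {
    lm <- landmarks[[sid]]
    data.frame(subject_id = sid, name = names(lm),
               x = vapply(lm, `[`, numeric(1), 1),
               y = vapply(lm, `[`, numeric(1), 2),
               z = vapply(lm, `[`, numeric(1), 3),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
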