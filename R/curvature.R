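# Per-vertex principal curvatures, curvedness and shape index.
#
# Curvatures come from a local osculating-quadric fit over an n-ring vertex
# neighbourhood expressed in the tangent frame of the (outward) vertex
# normal, which is robust on the irregular triangles produced by
# iso-surfacing. Sign convention: a convex-outward sphere of radius R has
# k1 = k2 = +1/R, so gyri carry positive shape index and sulci negative.

#' Principal curvatures by local quadric fitting
#'
#' For every vertex, neighbours within `neighborhood_rings` edge hops are
#' projected into the tangent frame and a quadric height function
#' `h(x, y) = a x^2 + b xy + c y^2 + d x + e y` is fit by least squares.
#' The shape operator assembled from the first/second fundamental forms at
#' the origin yields the principal curvatures, ordered `k1 >= k2`.
#' Vertices with fewer than 5 usable neighbours are marked invalid.
#'
#' @param mesh closed, outward-oriented `surface_mesh`.
#' @param neighborhood_rings neighbourhood radius in edge hops (default 2).
#' @return list with numeric vectors `k1`, `k2` (mm^-1) and logical `valid`.
#' @export
principal_curvatures <- function(mesh, neighborhood_rings = 2) {
  v <- mesh$vertices
  n <- nrow(v)
  nrm <- vertex_normals(mesh)
  A <- vertex_adjacency(mesh)
  R <- A
  if (neighborhood_rings > 1) {
    P <- A
    for (r in seq_len(neighborhood_rings - 1L)) {
      P <- P %*% A
      R <- R + P
    }
  }
  R <- methods::as(R, "CsparseMatrix")
  k1 <- rep(NA_real_, n); k2 <- rep(NA_real_, n)
  valid <- logical(n)
  # column slices of the symmetric reach matrix give the neighbour sets
  ptr <- R@p; idx <- R@i
  for (i in seq_len(n)) {
    nb <- idx[(ptr[i] + 1L):ptr[i + 1L]] + 1L
    nb <- nb[nb != i]
    if (length(nb) < 5L) next
    ni <- nrm[i, ]
    if (all(ni == 0)) next
    # tangent basis
    t1 <- if (abs(ni[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- t1 - sum(t1 * ni) * ni
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(ni[2] * t1[3] - ni[3] * t1[2],
            ni[3] * t1[1] - ni[1] * t1[3],
            ni[1] * t1[2] - ni[2] * t1[1])
    off <- sweep(v[nb, , drop = FALSE], 2, v[i, ], "-")
    x <- off %*% t1; y <- off %*% t2; h <- off %*% ni
    X <- cbind(x^2, x * y, y^2, x, y)
    cf <- tryCatch(qr.coef(qr(X), h), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    hx <- cf[4]; hy <- cf[5]
    E <- 1 + hx^2; F_ <- hx * hy; G <- 1 + hy^2
    den <- sqrt(1 + hx^2 + hy^2)
    L <- 2 * cf[1] / den; M <- cf[2] / den; N <- 2 * cf[3] / den
    # shape operator S = I^-1 II ; eigenvalues of the (generalized) 2x2
    detI <- E * G - F_^2
    S <- matrix(c(G * L - F_ * M, G * M - F_ * N,
                  E * M - F_ * L, E * N - F_ * M), 2, 2) / detI
    tr <- S[1, 1] + S[2, 2]
    dt <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    disc <- max(tr^2 / 4 - dt, 0)
    # height measured along the outward normal: convex surface dips below
    # the tangent plane, so negate to make convex-outward positive
    ks <- -c(tr / 2 + sqrt(disc), tr / 2 - sqrt(disc))
    k1[i] <- max(ks); k2[i] <- min(ks)
    valid[i] <- TRUE
  }
  list(k1 = k1, k2 = k2, valid = valid)
}

#' Curvedness
#'
#' `sqrt((k1^2 + k2^2) / 2)`, the magnitude of surface bending in mm^-1
#' (0 for a plane, 1/R for a sphere of radius R).
#'
#' @param k1,k2 principal curvatures with `k1 >= k2` where both are finite.
#' @return curvedness, same length as the inputs.
#' @export
curvedness <- function(k1, k2) {
  ok <- is.finite(k1) & is.finite(k2)
  if (any(k1[ok] < k2[ok]))
    stop("principal curvatures must be ordered k1 >= k2")
  sqrt((k1^2 + k2^2) / 2)
}

#' Shape index
#'
#' `SI = (2/pi) * atan((k1 + k2) / (k1 - k2))`, a dimensionless descriptor
#' in [-1, 1]: +1 convex dome (gyrus), +0.5 convex ridge, 0 saddle, -1
#' concave cup (sulcus). At umbilic points (k1 = k2) the continuity limit
#' `sign(k1)` is used; vertices with curvedness below `tol` are flat and
#' returned as `NA` (undefined).
#'
#' @param k1,k2 principal curvatures with `k1 >= k2`.
#' @param tol curvedness threshold below which SI is undefined
#'   (default 1e-4 mm^-1).
#' @return shape index values in [-1, 1] (NA where flat/invalid).
#' @export
shape_index <- function(k1, k2, tol = 1e-4) {
  ok <- is.finite(k1) & is.finite(k2)
  if (any(k1[ok] < k2[ok]))
    stop("principal curvatures must be ordered k1 >= k2")
  si <- rep(NA_real_, length(k1))
  cv <- curvedness(k1, k2)
  umb <- ok & (k1 - k2) <= .Machine$double.eps^0.5 * pmax(abs(k1), 1)
  gen <- ok & !umb
  si[gen] <- (2 / pi) * atan((k1[gen] + k2[gen]) / (k1[gen] - k2[gen]))
  si[umb] <- sign(k1[umb])
  si[!is.na(cv) & cv < tol] <- NA_real_
  si
}

#' Full per-vertex curvature field with summaries
#'
#' Composes [principal_curvatures()], [curvedness()] and [shape_index()]
#' and attaches area-weighted summary statistics.
#'
#' @param mesh closed, outward-oriented `surface_mesh`.
#' @param neighborhood_rings neighbourhood radius for the quadric fit.
#' @param flat_tol curvedness threshold for the shape-index validity mask.
#' @return a `curvature_field`: list with `k1`, `k2`, `curvedness`,
#'   `shape_index`, `valid`, and `summary` (area-weighted mean/median of
#'   curvedness and SI, plus the gyral area fraction SI > 0).
#' @export
curvature_field <- function(mesh, neighborhood_rings = 2, flat_tol = 1e-4) {
  pc <- principal_curvatures(mesh, neighborhood_rings)
  cv <- curvedness(pc$k1, pc$k2)
  si <- shape_index(pc$k1, pc$k2, tol = flat_tol)
  va <- vertex_areas(mesh)
  okc <- pc$valid & is.finite(cv)
  oks <- pc$valid & is.finite(si)
  wmean <- function(x, w) sum(x * w) / sum(w)
  wmedian <- function(x, w) {
    o <- order(x)
    cw <- cumsum(w[o]) / sum(w)
    x[o][which(cw >= 0.5)[1]]
  }
  summary <- list(
    mean_curvedness = wmean(cv[okc], va[okc]),
    median_curvedness = wmedian(cv[okc], va[okc]),
    mean_shape_index = wmean(si[oks], va[oks]),
    median_shape_index = wmedian(si[oks], va[oks]),
    gyral_area_fraction = sum(va[oks][si[oks] > 0]) / sum(va[oks]),
    valid_fraction = mean(pc$valid))
  structure(list(k1 = pc$k1, k2 = pc$k2, curvedness = cv, shape_index = si,
                 valid = pc$valid, summary = summary),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("curvature_field: %d vertices (%.1f%% valid)\n",
                     "  curvedness mean %.4g mm^-1, SI mean %.3f, ",
                     "gyral area fraction %.3f\n"),
              length(x$k1), 100 * s$valid_fraction,
              s$mean_curvedness, s$mean_shape_index, s$gyral_area_fraction))
  invisible(x)
}
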