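# Structure volumetry, surface extraction, surface area, the global shape
# parameter (area/volume), and paired per-week rates of change.

#' Structure volume from a labeled volume
#'
#' Volume is the count of voxels carrying the structure's label multiplied
#' by the voxel volume (product of the three spacings), in mm^3.
#'
#' @param vol a `label_volume`.
#' @param structure structure name present in `vol$label_map`.
#' @return volume in mm^3.
#' @export
volume_from_labels <- function(vol, structure) {
  code <- unname(vol$label_map[structure])
  if (is.na(code)) stop("unknown structure: ", structure)
  sum(vol$data == code) * prod(vol$spacing)
}

#' Total surface area of a mesh
#'
#' Sum of the per-triangle areas (cross-product formula). Degenerate faces
#' contribute zero area with a warning.
#'
#' @param mesh a `surface_mesh`.
#' @return area in mm^2.
#' @export
surface_area <- function(mesh) {
  ta <- triangle_areas(mesh)
  if (any(ta == 0) && nrow(mesh$faces) > 0)
    warning(sum(ta == 0), " zero-area faces contribute no area")
  sum(ta)
}

#' Global shape parameter
#'
#' Surface area divided by enclosed volume (mm^-1), a global compactness
#' measure: a sphere of radius R has shape parameter 3/R, and folding at
#' constant volume raises it.
#'
#' @param area surface area in mm^2.
#' @param volume enclosed volume in mm^3 (must be positive).
#' @return shape parameter in mm^-1.
#' @export
shape_parameter <- function(area, volume) {
  if (!is.finite(volume) || volume <= 0)
    stop("shape parameter requires a strictly positive volume")
  area / volume
}

#' Parse gestational age in weeks+days notation
#'
#' `"23+6"` means 23 weeks 6 days = 23 + 6/7 decimal weeks. Plain numerics
#' pass through.
#'
#' @param ga character vector like `"23+6"` (or numeric decimal weeks).
#' @return decimal weeks (numeric).
#' @export
parse_ga <- function(ga) {
  if (is.numeric(ga)) return(as.numeric(ga))
  out <- vapply(as.character(ga), function(g) {
    parts <- strsplit(trimws(g), "+", fixed = TRUE)[[1]]
    w <- as.numeric(parts[1])
    d <- if (length(parts) > 1L) as.numeric(parts[2]) else 0
    if (is.na(w) || is.na(d) || d < 0 || d >= 7)
      stop("cannot parse gestational age: ", g)
    w + d / 7
  }, numeric(1))
  unname(out)
}

#' Paired per-week rate of change
#'
#' Under a linear-growth assumption between the two scans, the rate is
#' (post - pre) / (ga_post - ga_pre) in metric-units per week.
#'
#' @param pre,post metric value at the earlier/later timepoint.
#' @param ga_pre,ga_post gestational ages, decimal weeks or `"W+D"` strings.
#' @param metric metric name recorded alongside the rate.
#' @return a `paired_rate` list with `pre`, `post`, `ga_pre`, `ga_post`,
#'   `rate`.
#' @export
paired_rate <- function(pre, post, ga_pre, ga_post, metric = "metric") {
  ga_pre <- parse_ga(ga_pre); ga_post <- parse_ga(ga_post)
  if (ga_post <= ga_pre)
    stop("ga_post must be strictly greater than ga_pre")
  structure(list(metric = metric, pre = pre, post = post,
                 ga_pre = ga_pre, ga_post = ga_post,
                 rate = (post - pre) / (ga_post - ga_pre)),
            class = "paired_rate")
}

#' @export
print.paired_rate <- function(x, ...) {
  cat(sprintf("%s: %.4g -> %.4g over %.3f wk = %.4g /week\n",
              x$metric, x$pre, x$post, x$ga_post - x$ga_pre, x$rate))
  invisible(x)
}

# ---------------------------------------------------------- iso-surfacing --

# 6-tetrahedron decomposition of the unit cube sharing the 0-6 diagonal.
.cube_corners <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                       c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
.cube_tets <- rbind(c(0,5,1,6), c(0,1,2,6), c(0,2,3,6),
                    c(0,3,7,6), c(0,7,4,6), c(0,4,5,6)) + 1L

#' Extract the surface mesh of a labeled structure
#'
#' Iso-surfaces the binary structure mask at level 0.5 by marching
#' tetrahedra (each grid cube split into six tetrahedra; crossing edges cut
#' at their midpoint), yielding a watertight, consistently outward-oriented
#' triangle mesh in world mm. Optional non-shrinking Taubin smoothing is
#' applied afterwards; by default only the largest 6-connected voxel
#' component is meshed.
#'
#' @param vol a `label_volume`.
#' @param structure structure name in `vol$label_map`.
#' @param smoothing_iters Taubin smoothing passes (0 = raw mesh).
#' @param largest_component mesh only the largest connected voxel component.
#' @return a closed `surface_mesh` with attribute `"provenance"` recording
#'   the smoothing used.
#' @export
extract_mesh <- function(vol, structure, smoothing_iters = 10,
                         largest_component = TRUE) {
  code <- unname(vol$label_map[structure])
  if (is.na(code)) stop("unknown structure: ", structure)
  mask <- vol$data == code
  if (!any(mask)) stop("structure '", structure, "' has no voxels")
  if (largest_component) mask <- .largest_component3d(mask)
  mesh <- .marching_tets(mask, vol$affine)
  if (smoothing_iters > 0) mesh <- taubin_smooth(mesh, smoothing_iters)
  rep_ <- validate_closed_oriented(mesh, fix = TRUE)
  mesh <- rep_$mesh
  attr(mesh, "provenance") <- sprintf("marching_tets+taubin%d", smoothing_iters)
  mesh
}

# Largest 6-connected component of a logical 3D mask.
.largest_component3d <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(mask)
  d <- dim(mask)
  pos <- arrayInd(idx, d)
  id <- integer(prod(d)); id[idx] <- seq_along(idx)
  edges <- NULL
  for (ax in 1:3) {
    ok <- pos[, ax] < d[ax]
    nb <- pos[ok, , drop = FALSE]
    nb[, ax] <- nb[, ax] + 1L
    nb_lin <- nb[, 1L] + (nb[, 2L] - 1L) * d[1L] + (nb[, 3L] - 1L) * d[1L] * d[2L]
    keep <- mask[nb_lin]
    edges <- rbind(edges, cbind(id[idx[ok]][keep], id[nb_lin[keep]]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- comp$membership == which.max(comp$csize)
  out <- array(FALSE, d)
  out[idx[keep]] <- TRUE
  out
}

# Marching tetrahedra on a binary mask (TRUE = inside), iso level 0.5.
# Returns a surface_mesh in the world frame given by the 0-based affine.
.marching_tets <- function(mask, affine) {
  d <- dim(mask)
  v <- array(0L, d + 2L)
  v[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask  # zero-padded
  pd <- dim(v)
  # occupancy sum over the 8 corners of every cell
  s <- array(0L, pd - 1L)
  for (k in seq_len(8L)) {
    o <- .cube_corners[k, ]
    s <- s + v[(1L + o[1]):(pd[1] - 1L + o[1]),
               (1L + o[2]):(pd[2] - 1L + o[2]),
               (1L + o[3]):(pd[3] - 1L + o[3])]
  }
  cells <- which(s > 0L & s < 8L)
  if (!length(cells)) stop("mask has no iso-surface")
  cpos <- arrayInd(cells, pd - 1L)  # base corner (1-based in padded grid)
  ncell <- nrow(cpos)
  # grid linear id of the 8 corners of every mixed cell
  gid <- matrix(0L, ncell, 8L)
  for (k in seq_len(8L)) {
    o <- .cube_corners[k, ]
    gid[, k] <- (cpos[, 1L] + o[1]) +
      (cpos[, 2L] + o[2] - 1L) * pd[1L] +
      (cpos[, 3L] + o[3] - 1L) * pd[1L] * pd[2L]
  }
  inside <- matrix(v[gid], ncell, 8L) > 0L
  # expand to tets: (ncell*6) x 4 corner grid ids / inside flags
  tg <- matrix(0L, ncell * 6L, 4L)
  tin <- matrix(FALSE, ncell * 6L, 4L)
  for (t in 1:6) {
    rows <- (t - 1L) * ncell + seq_len(ncell)
    tg[rows, ] <- gid[, .cube_tets[t, ], drop = FALSE]
    tin[rows, ] <- inside[, .cube_tets[t, ], drop = FALSE]
  }
  pat <- tin %*% c(1L, 2L, 4L, 8L)
  tri_e1 <- NULL; tri_e2 <- NULL; tri_e3 <- NULL; tri_ref <- NULL
  add_tris <- function(e1a, e1b, e2a, e2b, e3a, e3b, refpt) {
    tri_e1 <<- rbind(tri_e1, cbind(e1a, e1b))
    tri_e2 <<- rbind(tri_e2, cbind(e2a, e2b))
    tri_e3 <<- rbind(tri_e3, cbind(e3a, e3b))
    tri_ref <<- rbind(tri_ref, refpt)
  }
  singles <- list(`1` = c(1L, 2L, 3L, 4L), `2` = c(2L, 1L, 3L, 4L),
                  `4` = c(3L, 1L, 2L, 4L), `8` = c(4L, 1L, 2L, 3L))
  triples <- list(`14` = c(1L, 2L, 3L, 4L), `13` = c(2L, 1L, 3L, 4L),
                  `11` = c(3L, 1L, 2L, 4L), `7` = c(4L, 1L, 2L, 3L))
  pairs <- list(`3` = c(1L, 2L, 3L, 4L), `5` = c(1L, 3L, 2L, 4L),
                `9` = c(1L, 4L, 2L, 3L), `6` = c(2L, 3L, 1L, 4L),
                `10` = c(2L, 4L, 1L, 3L), `12` = c(3L, 4L, 1L, 2L))
  for (p in names(singles)) {  # one corner inside: single triangle
    rows <- which(pat == as.integer(p))
    if (!length(rows)) next
    cc <- singles[[p]]
    a <- tg[rows, cc[1]]; b <- tg[rows, cc[2]]
    c3 <- tg[rows, cc[3]]; dd <- tg[rows, cc[4]]
    add_tris(a, b, a, c3, a, dd, cbind(a, a))
  }
  for (p in names(triples)) {  # one corner outside: single triangle
    rows <- which(pat == as.integer(p))
    if (!length(rows)) next
    cc <- triples[[p]]
    a <- tg[rows, cc[1]]  # the outside corner
    b <- tg[rows, cc[2]]; c3 <- tg[rows, cc[3]]; dd <- tg[rows, cc[4]]
    add_tris(a, b, a, c3, a, dd, cbind(b, c3))  # ref inside: midpoint(b,c)
  }
  for (p in names(pairs)) {  # two in, two out: quad as two triangles
    rows <- which(pat == as.integer(p))
    if (!length(rows)) next
    cc <- pairs[[p]]
    a <- tg[rows, cc[1]]; b <- tg[rows, cc[2]]   # inside
    c3 <- tg[rows, cc[3]]; dd <- tg[rows, cc[4]] # outside
    ref <- cbind(a, b)
    add_tris(a, c3, a, dd, b, dd, ref)           # e_ac, e_ad, e_bd
    add_tris(a, c3, b, dd, b, c3, ref)           # e_ac, e_bd, e_bc
  }
  # unique cut-edge vertices (midpoints, since corner values are 0/1)
  alle <- rbind(tri_e1, tri_e2, tri_e3)
  ekey <- paste(pmin(alle[, 1L], alle[, 2L]), pmax(alle[, 1L], alle[, 2L]))
  fe <- factor(ekey)
  ntri <- nrow(tri_e1)
  faces <- matrix(as.integer(fe), ntri, 3L)
  first <- match(levels(fe), ekey)
  epts <- alle[first, , drop = FALSE]
  gp <- function(g) {  # padded grid id -> world coords (0-based orig index)
    i <- (g - 1L) %% pd[1L]
    j <- ((g - 1L) %/% pd[1L]) %% pd[2L]
    k <- (g - 1L) %/% (pd[1L] * pd[2L])
    ijk <- cbind(i - 1L, j - 1L, k - 1L)  # padded(1-based) -> orig 0-based
    h <- cbind(ijk, 1)
    (h %*% t(affine))[, 1:3, drop = FALSE]
  }
  verts <- (gp(epts[, 1L]) + gp(epts[, 2L])) / 2
  # orient every triangle away from its inside reference point
  refw <- (gp(tri_ref[, 1L]) + gp(tri_ref[, 2L])) / 2
  q1 <- verts[faces[, 1L], , drop = FALSE]
  q2 <- verts[faces[, 2L], , drop = FALSE]
  q3 <- verts[faces[, 3L], , drop = FALSE]
  u <- q2 - q1; w <- q3 - q1
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  cent <- (q1 + q2 + q3) / 3
  flip <- rowSums(nrm * (cent - refw)) < 0
  faces[flip, c(2L, 3L)] <- faces[flip, c(3L, 2L)]
  surface_mesh(verts, faces)
}

#' Taubin (non-shrinking) mesh smoothing
#'
#' Alternating lambda/mu uniform-Laplacian steps; unlike plain Laplacian
#' smoothing the pass-band keeps global size, so volumetry stays consistent.
#'
#' @param mesh a `surface_mesh`.
#' @param iterations number of lambda+mu passes.
#' @param lambda,mu Taubin coefficients (defaults 0.5 / -0.53).
#' @return smoothed `surface_mesh` (same connectivity).
#' @export
taubin_smooth <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53) {
  A <- vertex_adjacency(mesh)
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  W <- A / deg
  X <- mesh$vertices
  for (i in seq_len(iterations)) {
    X <- X + lambda * (as.matrix(W %*% X) - X)
    X <- X + mu * (as.matrix(W %*% X) - X)
  }
  mesh$vertices <- X
  mesh
}

#' Volumetry, area and shape parameter for the standard structures
#'
#' Convenience wrapper computing, per structure, the voxel volume, the
#' extracted-mesh surface area and the shape parameter.
#'
#' @param vol a `label_volume`.
#' @param structures structure names (default: all non-background labels
#'   present).
#' @param smoothing_iters passed to [extract_mesh()].
#' @return data.frame with columns `structure`, `volume_mm3`, `area_mm2`,
#'   `shape_param_mm_1`, `mesh_source`.
#' @export
structure_metrics <- function(vol, structures = NULL, smoothing_iters = 10) {
  if (is.null(structures)) {
    present <- unique(as.vector(vol$data))
    structures <- names(vol$label_map)[vol$label_map %in% setdiff(present, 0L)]
  }
  rows <- lapply(structures, function(s) {
    volu <- volume_from_labels(vol, s)
    if (volu > 0) {
      mesh <- extract_mesh(vol, s, smoothing_iters = smoothing_iters)
      area <- surface_area(mesh)
      sp <- shape_parameter(area, volu)
      src <- attr(mesh, "provenance")
    } else {
      area <- 0; sp <- NA_real_; src <- "empty"
    }
    data.frame(structure = s, volume_mm3 = volu, area_mm2 = area,
               shape_param_mm_1 = sp, mesh_source = src,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
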