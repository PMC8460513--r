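# Core triangle-mesh container and geometry helpers shared by every
# surface-based stage (area, volume, normals, adjacency, icospheres).

#' Triangle surface mesh
#'
#' Constructs a triangle mesh in world millimetres. Vertices are an `N x 3`
#' numeric matrix, faces an `M x 3` integer matrix of 1-based vertex indices,
#' and `fields` an optional named list of length-`N` per-vertex scalar arrays
#' (e.g. `shape_index`).
#'
#' @param vertices N x 3 numeric matrix of vertex coordinates (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param fields named list of length-N numeric vectors attached to vertices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, fields = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an M x 3 matrix")
  n <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > n)
      stop("face indices out of range [1, N]")
    degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
      faces[, 1L] == faces[, 3L]
    if (any(degen)) stop("degenerate faces (repeated vertex index)")
  }
  if (length(fields)) {
    if (is.null(names(fields)) || any(names(fields) == ""))
      stop("fields must be a named list")
    bad <- vapply(fields, function(f) length(f) != n, logical(1))
    if (any(bad)) stop("every field must have one value per vertex")
    fields <- lapply(fields, as.numeric)
  }
  structure(list(vertices = vertices, faces = faces, fields = fields),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (length(x$fields))
    cat(sprintf(", fields: %s", paste(names(x$fields), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Per-triangle areas of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector of length `M`, area of each face in mm^2.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Signed volume enclosed by a closed mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for a
#' closed mesh with consistent outward winding.
#'
#' @param mesh a `surface_mesh`.
#' @return signed enclosed volume in mm^3.
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  sum(p1[, 1L] * (p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]) -
      p1[, 2L] * (p2[, 1L] * p3[, 3L] - p2[, 3L] * p3[, 1L]) +
      p1[, 3L] * (p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])) / 6
}

# Area-weighted outward vertex normals (unit length; zero where undefined).
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  fn <- cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
              a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
              a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])  # 2*area-weighted
  n <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    n[, 1L] <- n[, 1L] + unname(tapply2(fn[, 1L], f[, k], nrow(v)))
    n[, 2L] <- n[, 2L] + unname(tapply2(fn[, 2L], f[, k], nrow(v)))
    n[, 3L] <- n[, 3L] + unname(tapply2(fn[, 3L], f[, k], nrow(v)))
  }
  len <- sqrt(rowSums(n^2))
  ok <- len > 0
  n[ok, ] <- n[ok, ] / len[ok]
  n
}

# Fast grouped sum onto 1..n (rowsum-based; returns dense length-n vector).
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# Lumped per-vertex areas: one third of the incident triangle areas.
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh)
  n <- nrow(mesh$vertices)
  va <- numeric(n)
  for (k in 1:3) va <- va + tapply2(ta / 3, mesh$faces[, k], n)
  va
}

# Unique undirected edges as a 2-column matrix, plus per-edge face counts.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  es <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  key <- paste(es[, 1L], es[, 2L])
  cnt <- table(key)
  uk <- names(cnt)
  parts <- matrix(as.integer(unlist(strsplit(uk, " ", fixed = TRUE))),
                  ncol = 2L, byrow = TRUE)
  list(edges = parts, counts = as.integer(cnt))
}

# Sparse symmetric vertex adjacency (1-ring), pattern only.
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)$edges
  n <- nrow(mesh$vertices)
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                       x = 1, dims = c(n, n))
}

#' Mean length of the unique mesh edges (mm)
#'
#' @param mesh a `surface_mesh`.
#' @return mean edge length in mm.
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)$edges
  d <- mesh$vertices[e[, 1L], , drop = FALSE] - mesh$vertices[e[, 2L], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Icosphere mesh
#'
#' Recursively subdivided icosahedron projected to a sphere: a near-uniform
#' triangulation used for analytic test surfaces and as the angular
#' parameterisation of the brain phantoms.
#'
#' @param subdivisions number of 4-to-1 subdivision passes (0 = icosahedron).
#' @param radius sphere radius in mm.
#' @param center length-3 center.
#' @return a closed, outward-oriented `surface_mesh`.
#' @export
icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    midkey <- new.env(hash = TRUE, parent = emptyenv())
    verts <- v
    getmid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- midkey[[key]]
      if (!is.null(id)) return(id)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      id <- nrow(verts)
      midkey[[key]] <- id
      id
    }
    newf <- matrix(0L, nf * 4L, 3L)
    for (t in seq_len(nf)) {
      i <- f[t, 1L]; j <- f[t, 2L]; k <- f[t, 3L]
      a <- getmid(i, j); b <- getmid(j, k); c3 <- getmid(k, i)
      newf[(t - 1L) * 4L + 1:4, ] <- rbind(c(i, a, c3), c(j, b, a),
                                           c(k, c3, b), c(a, b, c3))
    }
    v <- verts; f <- newf
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, f)
}

#' Apply a similarity (rigid + scale) transform to points or a mesh
#'
#' @param x an `N x 3` point matrix or a `surface_mesh`.
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation (mm).
#' @param s scalar scale factor.
#' @return object of the same type with coordinates `s * R %*% x + t`.
#' @export
apply_rigid <- function(x, R = diag(3), t = c(0, 0, 0), s = 1) {
  if (inherits(x, "surface_mesh")) {
    x$vertices <- apply_rigid(x$vertices, R, t, s)
    return(x)
  }
  sweep(s * (as.matrix(x) %*% t(R)), 2, t, "+")
}

# Brute-force nearest-neighbour indices of each query row in ref (chunked).
nn_index <- function(query, ref, chunk = 2000L) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  nq <- nrow(query)
  ref2 <- rowSums(ref^2)
  out <- integer(nq)
  for (st in seq(1L, nq, by = chunk)) {
    en <- min(st + chunk - 1L, nq)
    q <- query[st:en, , drop = FALSE]
    d2 <- outer(rowSums(q^2), ref2, "+") - 2 * tcrossprod(q, ref)
    out[st:en] <- max.col(-d2, ties.method = "first")
  }
  out
}

# A random 3D rotation matrix (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Rotation about an axis by angle (radians).
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(u)
}
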