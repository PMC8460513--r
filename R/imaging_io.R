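# Volume / mesh input-output and the shared geometric conventions.
#
# Conventions: 0-based voxel indices; world frame is the NIfTI affine (RAS);
# closed meshes carry outward normals (signed volume > 0) so that convex
# structures have positive principal curvatures.

.default_label_map <- c(background = 0L, unmyelinated_wm = 1L,
                        ventricles = 2L, cerebellum = 3L)

#' Labeled segmentation volume
#'
#' A 3D grid of non-negative integer labels with voxel spacing (mm), a 4x4
#' voxel-index-to-world affine, and a name-to-code label map. The default
#' codes are background = 0, unmyelinated white matter = 1, ventricles = 2,
#' cerebellum = 3.
#'
#' @param data 3D array of non-negative integer labels.
#' @param spacing length-3 positive voxel spacing (mm per axis).
#' @param affine 4 x 4 voxel-index (0-based) to world-mm map; default built
#'   from `spacing` with the origin at voxel (0,0,0).
#' @param label_map named integer vector mapping structure names to codes.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing, affine = NULL,
                         label_map = .default_label_map) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (any(data < 0) || any(data != round(data)))
    stop("labels must be non-negative integers")
  storage.mode(data) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4 x 4 matrix")
  lm <- as.integer(label_map); names(lm) <- names(label_map)
  present <- unique(as.vector(data))
  unknown <- setdiff(present, c(0L, lm))
  if (length(unknown))
    stop("labels present in data but absent from label_map: ",
         paste(unknown, collapse = ", "))
  structure(list(data = data, spacing = spacing, affine = affine,
                 label_map = lm,
                 isotropic = (max(spacing) - min(spacing)) < 1e-6),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: %s voxels, spacing %s mm%s\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 6), collapse = " x "),
              if (x$isotropic) " (isotropic)" else ""))
  tab <- table(factor(x$data, levels = x$label_map))
  names(tab) <- names(x$label_map)
  print(tab)
  invisible(x)
}

#' Read a labeled NIfTI volume
#'
#' Spacing and affine are taken from the NIfTI header. The label map comes
#' from a JSON sidecar (`<stem>.labels.json`, a name-to-code object) when
#' present, otherwise the package defaults.
#'
#' @param path path to a `.nii` / `.nii.gz` file with integer-valued data.
#' @param label_map optional explicit label map overriding sidecar/defaults.
#' @return a `label_volume`.
#' @export
read_label_volume <- function(path, label_map = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) dim(arr) <- dim(arr)[1:3]
  if (any(arr != round(arr)))
    stop("NIfTI data are not integer labels (non-integer values found)")
  arr <- array(as.integer(round(arr)), dim(arr))
  spacing <- RNifti::pixdim(img)[1:3]
  affine <- structure(RNifti::xform(img), class = NULL)
  if (is.null(label_map)) {
    sidecar <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
    if (file.exists(sidecar)) {
      lm <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      label_map <- stats::setNames(as.integer(lm), names(lm))
    } else {
      label_map <- .default_label_map
    }
  }
  label_volume(arr, spacing = spacing, affine = affine, label_map = label_map)
}

#' Write a labeled volume as NIfTI (plus JSON label-map sidecar)
#'
#' @param vol a `label_volume`.
#' @param path output `.nii` or `.nii.gz` path.
#' @param sidecar write the `<stem>.labels.json` label map (default TRUE).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path, sidecar = TRUE) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int16")
  if (sidecar) {
    jsonlite::write_json(as.list(vol$label_map),
                         sub("\\.nii(\\.gz)?$", ".labels.json", path),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' World coordinates of voxel indices
#'
#' @param vol a `label_volume`.
#' @param ijk `N x 3` matrix of 0-based voxel indices.
#' @return `N x 3` world coordinates in mm (`affine %*% (i,j,k,1)`).
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- as.matrix(ijk)
  h <- cbind(ijk, 1)
  out <- h %*% t(vol$affine)
  out[, 1:3, drop = FALSE]
}

# ---------------------------------------------------------------- mesh IO --

#' Read a triangle mesh (PLY or VTK legacy polydata)
#'
#' Supports ASCII and binary-little-endian PLY and ASCII VTK legacy
#' PolyData. Per-vertex scalar arrays are preserved as mesh fields.
#'
#' @param path file path; format chosen by extension (`.ply` / `.vtk`).
#' @param triangulate if TRUE, fan-triangulate polygonal faces; if FALSE a
#'   non-triangular face is a format error.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path, triangulate = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = .read_ply(path, triangulate),
         vtk = .read_vtk(path, triangulate),
         stop("unsupported mesh format: .", ext))
}

#' Write a triangle mesh (PLY or VTK legacy polydata)
#'
#' @param mesh a `surface_mesh`; its `fields` are written as per-vertex
#'   scalars.
#' @param path output path (`.ply` or `.vtk`).
#' @param format `"ascii"` or `"binary_little_endian"` (PLY only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = .write_ply(mesh, path, format),
         vtk = .write_vtk(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(con, type, n) {
  sz <- .ply_type_size[[type]]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  readBin(con, what = what, n = n, size = sz, endian = "little",
          signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
}

.read_ply <- function(path, triangulate) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; elements <- list(); cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("unexpected end of PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        elements[[cur]]$props[[tok[5]]] <- list(list = TRUE,
                                                count_type = tok[3],
                                                item_type = tok[4])
      } else {
        elements[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") break
  }
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  ascii <- fmt == "ascii"
  if (ascii) {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    pos <- 0L
  }
  verts <- NULL; fields <- list(); faces <- NULL
  for (ename in names(elements)) {
    el <- elements[[ename]]
    pn <- names(el$props)
    if (ascii) {
      lines <- txt[pos + seq_len(el$count)]
      pos <- pos + el$count
      if (ename == "vertex") {
        m <- matrix(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))),
                    nrow = el$count, byrow = TRUE)
        colnames(m) <- pn
        verts <- m[, c("x", "y", "z"), drop = FALSE]
        for (p in setdiff(pn, c("x", "y", "z"))) fields[[p]] <- m[, p]
      } else if (ename == "face") {
        fl <- lapply(strsplit(trimws(lines), "\\s+"), as.integer)
        faces <- .assemble_faces(fl, triangulate)
      }
    } else {
      if (ename == "vertex") {
        if (any(vapply(el$props, function(p) p$list, logical(1))))
          stop("list-typed vertex properties are not supported")
        types <- vapply(el$props, function(p) p$type, character(1))
        m <- matrix(0, el$count, length(pn), dimnames = list(NULL, pn))
        # interleaved record read: pull raw block, then slice per property
        sizes <- .ply_type_size[types]
        rec <- sum(sizes)
        raw <- readBin(con, "raw", n = rec * el$count)
        off <- c(0L, cumsum(sizes))
        for (j in seq_along(pn)) {
          idx <- as.vector(outer(seq_len(sizes[j]) + off[j],
                                 (seq_len(el$count) - 1L) * rec, "+"))
          m[, j] <- .raw_to_num(raw[idx], types[j], el$count)
        }
        verts <- m[, c("x", "y", "z"), drop = FALSE]
        for (p in setdiff(pn, c("x", "y", "z"))) fields[[p]] <- m[, p]
      } else if (ename == "face") {
        p <- el$props[[1]]
        fl <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          cnt <- .ply_read_scalar(con, p$count_type, 1L)
          fl[[i]] <- c(cnt, .ply_read_scalar(con, p$item_type, cnt))
        }
        faces <- .assemble_faces(fl, triangulate)
      }
    }
  }
  if (is.null(verts)) stop("PLY file has no vertex element")
  if (is.null(faces)) faces <- matrix(integer(0), 0L, 3L)
  surface_mesh(verts, faces + 1L, fields)
}

.raw_to_num <- function(raw, type, n) {
  sz <- .ply_type_size[[type]]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  readBin(raw, what = what, n = n, size = sz, endian = "little",
          signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
}

# face lines as integer vectors c(count, i0, i1, ...), 0-based -> M x 3 0-based
.assemble_faces <- function(fl, triangulate) {
  counts <- vapply(fl, function(x) x[1], numeric(1))
  if (any(counts != 3)) {
    if (!triangulate)
      stop("non-triangular faces present (set triangulate = TRUE to fan-triangulate)")
    fl <- unlist(lapply(fl, function(x) {
      k <- x[1]; idx <- x[-1]
      lapply(seq_len(k - 2L), function(t) c(3L, idx[1], idx[t + 1L], idx[t + 2L]))
    }), recursive = FALSE)
  }
  matrix(as.integer(unlist(lapply(fl, function(x) x[2:4]))),
         ncol = 3L, byrow = TRUE)
}

.write_ply <- function(mesh, path, format) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  fn <- names(mesh$fields)
  if (is.null(fn)) fn <- character(0)
  hdr <- c("ply",
           paste("format", format, "1.0"),
           paste("element vertex", n),
           "property float x", "property float y", "property float z",
           if (length(fn)) paste("property float", fn),
           paste("element face", m),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  vm <- mesh$vertices
  if (length(fn)) vm <- cbind(vm, do.call(cbind, mesh$fields))
  f0 <- mesh$faces - 1L
  if (format == "ascii") {
    writeLines(apply(vm, 1L, function(r)
      paste(formatC(r, format = "g", digits = 9), collapse = " ")), con)
    writeLines(paste(3L, f0[, 1L], f0[, 2L], f0[, 3L]), con)
  } else {
    writeBin(as.vector(t(vm)), con, size = 4L, endian = "little")
    if (m > 0L) {
      # per-face record: uchar 3 + three int32, packed via raw
      ints <- writeBin(as.integer(t(f0)), raw(), size = 4L, endian = "little")
      dim(ints) <- c(12L, m)
      rec <- rbind(matrix(as.raw(3L), 1L, m), ints)
      writeBin(as.vector(rec), con)
    }
  }
}

.read_vtk <- function(path, triangulate) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  if (!grepl("^# vtk", txt[1])) stop("not a VTK legacy file: ", path)
  if (!grepl("ASCII", txt[3], ignore.case = TRUE))
    stop("only ASCII VTK legacy files are supported")
  toks <- strsplit(trimws(txt), "\\s+")
  i <- which(vapply(toks, function(t) identical(toupper(t[1]), "POINTS"), logical(1)))[1]
  if (is.na(i)) stop("VTK file has no POINTS section")
  np <- as.integer(toks[[i]][2])
  nums <- numeric(0); j <- i + 1L
  while (length(nums) < 3L * np) {
    nums <- c(nums, as.numeric(toks[[j]])); j <- j + 1L
  }
  verts <- matrix(nums[seq_len(3L * np)], ncol = 3L, byrow = TRUE)
  ip <- which(vapply(toks, function(t) toupper(t[1]) %in% c("POLYGONS", "CELLS"), logical(1)))[1]
  faces <- matrix(integer(0), 0L, 3L)
  if (!is.na(ip)) {
    total <- as.integer(toks[[ip]][3])
    nums <- integer(0); j <- ip + 1L
    while (length(nums) < total) {
      nums <- c(nums, as.integer(toks[[j]])); j <- j + 1L
    }
    fl <- list(); k <- 1L
    while (k <= total) {
      cnt <- nums[k]
      fl[[length(fl) + 1L]] <- nums[k:(k + cnt)]
      k <- k + cnt + 1L
    }
    faces <- .assemble_faces(fl, triangulate)
  }
  fields <- list()
  ipd <- which(vapply(toks, function(t) identical(toupper(t[1]), "POINT_DATA"), logical(1)))[1]
  if (!is.na(ipd)) {
    j <- ipd + 1L
    while (j <= length(toks)) {
      t <- toks[[j]]
      if (identical(toupper(t[1]), "SCALARS")) {
        nm <- t[2]
        j <- j + 1L  # LOOKUP_TABLE line
        if (!identical(toupper(toks[[j]][1]), "LOOKUP_TABLE")) j <- j - 1L
        vals <- numeric(0); j <- j + 1L
        while (length(vals) < np && j <= length(toks)) {
          vals <- c(vals, as.numeric(toks[[j]])); j <- j + 1L
        }
        fields[[nm]] <- vals
      } else j <- j + 1L
    }
  }
  surface_mesh(verts, faces + 1L, fields)
}

.write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  writeLines(c("# vtk DataFile Version 3.0", "surface mesh", "ASCII",
               "DATASET POLYDATA", paste("POINTS", n, "float")), con)
  writeLines(apply(mesh$vertices, 1L, function(r)
    paste(formatC(r, format = "g", digits = 9), collapse = " ")), con)
  writeLines(paste("POLYGONS", m, 4L * m), con)
  f0 <- mesh$faces - 1L
  writeLines(paste(3L, f0[, 1L], f0[, 2L], f0[, 3L]), con)
  if (length(mesh$fields)) {
    writeLines(paste("POINT_DATA", n), con)
    for (nm in names(mesh$fields)) {
      writeLines(c(paste("SCALARS", nm, "float 1"), "LOOKUP_TABLE default"), con)
      writeLines(formatC(mesh$fields[[nm]], format = "g", digits = 9), con)
    }
  }
}

# ------------------------------------------------------------- validation --

#' Validate (and optionally repair) mesh closedness and orientation
#'
#' Reports edge-manifoldness (every edge on exactly <= 2 faces), closedness
#' (exactly 2), winding consistency, and outward orientation (signed volume
#' positive). With `fix = TRUE` an inward-wound closed mesh is re-oriented
#' outward by swapping the face winding.
#'
#' @param mesh a `surface_mesh`.
#' @param fix flip winding to outward when the signed volume is negative.
#' @return a list with elements `manifold`, `closed`, `oriented`,
#'   `signed_volume`, `n_boundary_edges`, and `mesh` (possibly re-oriented).
#' @export
validate_closed_oriented <- function(mesh, fix = FALSE) {
  ec <- mesh_edges(mesh)
  manifold <- all(ec$counts <= 2L)
  n_boundary <- sum(ec$counts == 1L)
  closed <- manifold && n_boundary == 0L
  # winding consistency: each directed edge appears at most once
  f <- mesh$faces
  de <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  consistent <- !anyDuplicated(paste(de[, 1L], de[, 2L]))
  sv <- mesh_signed_volume(mesh)
  oriented <- closed && consistent && sv > 0
  if (fix && closed && consistent && sv < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
    sv <- -sv
    oriented <- TRUE
  }
  list(manifold = manifold, closed = closed, oriented = oriented,
       signed_volume = sv, n_boundary_edges = n_boundary, mesh = mesh)
}
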