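#' Triangulated surface meshes
#'
#' Vertices in world mm, faces as 1-based vertex index triples. Used for the
#' scalp surface, the canonical inner-skull template and its warped
#' subject-space versions.
#'
#' @param vertices V x 3 numeric matrix (mm).
#' @param faces F x 3 integer matrix of vertex indices (1-based).
#' @return An object of class `ng_mesh`.
#' @export
ng_mesh <- function(vertices, faces) {
  vertices <- rbind_pts(vertices)
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("faces must be F x 3")
  storage.mode(faces) <- "integer"
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "ng_mesh")
}

#' @export
print.ng_mesh <- function(x, ...) {
  cat(sprintf("<ng_mesh> %d vertices, %d faces, Euler characteristic %d\n",
              nrow(x$vertices), nrow(x$faces), euler_characteristic(x)))
  invisible(x)
}

#' Euler characteristic V - E + F of a mesh
#'
#' Equals 2 for a closed genus-0 surface.
#' @param mesh An `ng_mesh`.
#' @return Integer.
#' @export
euler_characteristic <- function(mesh) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
             mesh$faces[, c(1, 3)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh$vertices) - nrow(e) + nrow(mesh$faces)
}

# Per-face areas (mm^2).
face_areas <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Subdivided icosahedral sphere
#'
#' Unit icosahedron subdivided `level` times with all vertices projected to
#' the unit sphere; `10 * 4^level + 2` vertices. Level 4 gives the 2562-vertex
#' canonical surface used for inner-skull templates.
#'
#' @param level Non-negative integer subdivision level.
#' @return An `ng_mesh` on the unit sphere.
#' @export
make_icosphere <- function(level = 4L) {
  if (length(level) != 1L || level < 0 || level != round(level))
    stop("level must be a non-negative integer")
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    nv <- nrow(V)
    mid <- new.env(hash = TRUE)
    verts <- V
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      p <- (verts[a, ] + verts[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      verts <<- rbind(verts, p)
      id <- nrow(verts)
      mid[[key]] <- id
      id
    }
    newF <- matrix(0L, 4 * nrow(F), 3)
    for (i in seq_len(nrow(F))) {
      a <- F[i, 1]; b <- F[i, 2]; c <- F[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF[4 * i - 3, ] <- c(a, ab, ca)
      newF[4 * i - 2, ] <- c(b, bc, ab)
      newF[4 * i - 1, ] <- c(c, ca, bc)
      newF[4 * i, ] <- c(ab, bc, ca)
    }
    V <- verts
    F <- newF
  }
  ng_mesh(V, F)
}

# Taubin lambda/mu smoothing: low shrinkage compared to plain Laplacian.
# Uses the uniform umbrella operator over the vertex 1-ring.
taubin_smooth <- function(mesh, iterations = 10L, lambda = 0.5, mu = -0.53) {
  if (iterations <= 0) return(mesh)
  V <- mesh$vertices
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
             mesh$faces[, c(1, 3)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  n <- nrow(V)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  W <- A / deg
  for (k in seq_len(iterations)) {
    V <- V + lambda * (as.matrix(W %*% V) - V)
    V <- V + mu * (as.matrix(W %*% V) - V)
  }
  ng_mesh(V, mesh$faces)
}

#' Extract the scalp surface from an MRI volume
#'
#' Binarizes the volume at `intensity_threshold`, keeps the largest connected
#' component, applies morphological closing, extracts the iso-0.5 surface of
#' the lightly smoothed mask by marching tetrahedra, and applies low-shrinkage
#' Taubin smoothing. Vertices are in world mm.
#'
#' @param volume An `ng_volume`.
#' @param intensity_threshold Binarization threshold.
#' @param closing_radius_vox Radius (voxels) of the morphological closing ball.
#' @param presmooth_sigma_vox Gaussian sigma (voxels) applied to the binary
#'   mask before isosurfacing (sub-voxel smoothness of the surface).
#' @param smooth_iterations Taubin smoothing iterations.
#' @return An `ng_mesh`.
#' @export
extract_scalp <- function(volume, intensity_threshold = 0.35,
                          closing_radius_vox = 1.5,
                          presmooth_sigma_vox = 0.8,
                          smooth_iterations = 10L) {
  mask <- volume$data > intensity_threshold
  if (!any(mask)) stop("empty mask: no voxels above threshold")
  dim(mask) <- dim(volume$data)
  mask <- cpp_largest_component(mask)
  if (closing_radius_vox > 0) {
    dil <- cpp_dilate(mask, closing_radius_vox)
    ero <- !cpp_dilate(!dil, closing_radius_vox)
    dim(ero) <- dim(mask)
    mask <- ero
  }
  f <- array(as.numeric(mask), dim(mask))
  f <- smooth3d(f, presmooth_sigma_vox)
  iso <- cpp_marching_tets(f, 0.5)
  if (nrow(iso$vertices) == 0L) stop("no isosurface found")
  mesh <- ng_mesh(voxel_to_world(volume, iso$vertices), iso$faces)
  taubin_smooth(mesh, smooth_iterations)
}

#' Write / read meshes as ASCII STL or OBJ
#'
#' Minimal text-format mesh I/O (format chosen by file extension).
#'
#' @param mesh An `ng_mesh`.
#' @param path Output path ending in `.stl` or `.obj`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  } else if (ext == "stl") {
    a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
    c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
    u <- b - a; v <- c - a
    n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
    len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
    n <- n / len
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(mesh$faces))) {
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
                   sprintf("    vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
                   sprintf("    vertex %.9g %.9g %.9g", c[i, 1], c[i, 2], c[i, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    V <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                               function(x) as.numeric(x[2:4])))
    F <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
    ng_mesh(V, F)
  } else if (ext == "stl") {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.numeric(x[2:4])))
    # weld duplicate corner vertices back into a shared-vertex mesh
    key <- apply(round(V, 6), 1, paste, collapse = ",")
    uid <- !duplicated(key)
    idx <- match(key, key[uid])
    F <- matrix(idx, ncol = 3, byrow = TRUE)
    ng_mesh(V[uid, , drop = FALSE], F)
  } else stop("unsupported mesh format: .", ext)
}
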