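#' Rigid-body transforms
#'
#' A proper rigid transform (rotation + translation, mm) stored as a 4x4
#' homogeneous matrix, optionally tagged with the coordinate frames it maps
#' between (`device`, `head`, `mri_world`). Frame tags, when present on both
#' a transform and a point set, are checked on application.
#'
#' @param matrix 4x4 homogeneous matrix with a proper rotation block.
#' @param from,to Optional frame tags.
#' @return An object of class `ng_transform`.
#' @export
rigid_transform <- function(matrix = diag(4), from = NULL, to = NULL) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(4L, 4L))) stop("matrix must be 4x4")
  R <- m[1:3, 1:3]
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6)
    stop("rotation block is not orthonormal")
  if (abs(det(R) - 1) > 1e-6)
    stop("rotation block must be proper (det = +1)")
  if (any(abs(m[4, ] - c(0, 0, 0, 1)) > 1e-9))
    stop("last row must be (0,0,0,1)")
  structure(list(matrix = m, from = from, to = to), class = "ng_transform")
}

#' @rdname rigid_transform
#' @param R 3x3 proper rotation matrix.
#' @param t Length-3 translation (mm).
#' @export
rigid_from_parts <- function(R, t = c(0, 0, 0), from = NULL, to = NULL) {
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  rigid_transform(m, from = from, to = to)
}

#' @export
print.ng_transform <- function(x, ...) {
  cat("<ng_transform>",
      if (!is.null(x$from) || !is.null(x$to))
        sprintf(" %s -> %s", x$from %||% "?", x$to %||% "?") else "", "\n",
      sep = "")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Invert and compose rigid transforms
#' @param T,T1,T2 `ng_transform` objects.
#' @return An `ng_transform`.
#' @export
invert_transform <- function(T) {
  R <- T$matrix[1:3, 1:3]
  t <- T$matrix[1:3, 4]
  rigid_from_parts(t(R), -t(R) %*% t, from = T$to, to = T$from)
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(T2, T1) {
  # returns T2 o T1 (apply T1 first)
  if (!is.null(T2$from) && !is.null(T1$to) && !identical(T2$from, T1$to))
    stop("frame mismatch in composition: ", T1$to, " vs ", T2$from)
  rigid_transform(T2$matrix %*% T1$matrix, from = T1$from, to = T2$to)
}

# Rotation angle (degrees) of the relative rotation between two transforms;
# used as a ground-truth registration error measure.
#' Rotation/translation discrepancy between two rigid transforms
#' @param Ta,Tb `ng_transform` objects.
#' @return List with `rotation_deg` and `translation_mm`.
#' @export
transform_discrepancy <- function(Ta, Tb) {
  Rrel <- t(Ta$matrix[1:3, 1:3]) %*% Tb$matrix[1:3, 1:3]
  ang <- acos(pmin(1, pmax(-1, (sum(diag(Rrel)) - 1) / 2))) * 180 / pi
  list(rotation_deg = ang,
       translation_mm = sqrt(sum((Ta$matrix[1:3, 4] - Tb$matrix[1:3, 4])^2)))
}

#' Labeled head point sets
#'
#' Digitized 3-D points (mm) with per-point labels (`nasion`, `lpa`, `rpa`,
#' `scalp`, `nose`) and a frame tag (`device`, `head` or `mri_world`). When
#' fiducial labels are present, each must occur exactly once.
#'
#' @param points N x 3 numeric matrix (mm).
#' @param labels Character vector of length N.
#' @param frame Frame tag.
#' @return An object of class `ng_points`.
#' @export
head_points <- function(points, labels, frame = c("device", "head", "mri_world")) {
  points <- rbind_pts(points)
  frame <- match.arg(frame)
  labels <- as.character(labels)
  if (length(labels) != nrow(points)) stop("one label per point required")
  ok <- labels %in% c("nasion", "lpa", "rpa", "scalp", "nose")
  if (!all(ok)) stop("unknown labels: ", paste(unique(labels[!ok]), collapse = ", "))
  for (fid in c("nasion", "lpa", "rpa")) {
    k <- sum(labels == fid)
    if (k > 1L) stop("fiducial '", fid, "' present ", k, " times")
  }
  stopifnot_finite(points, "point coordinates")
  structure(list(points = points, labels = labels, frame = frame),
            class = "ng_points")
}

#' @export
print.ng_points <- function(x, ...) {
  cat(sprintf("<ng_points> %d points in '%s' frame (%s)\n",
              nrow(x$points), x$frame,
              paste(sprintf("%s: %d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' @export
length.ng_points <- function(x) nrow(x$points)

#' Subset a head point set
#'
#' @param pts An `ng_points` object.
#' @param idx Logical or integer index over points.
#' @return An `ng_points` with the selected points, frame preserved.
#' @export
subset_points <- function(pts, idx) {
  head_points(pts$points[idx, , drop = FALSE], pts$labels[idx], pts$frame)
}

#' Extract the three fiducials as a named matrix
#'
#' @param pts An `ng_points` containing `nasion`, `lpa` and `rpa`.
#' @return 3 x 3 matrix with rows `nasion`, `lpa`, `rpa`.
#' @export
fiducial_matrix <- function(pts) {
  out <- matrix(NA_real_, 3, 3,
                dimnames = list(c("nasion", "lpa", "rpa"), c("x", "y", "z")))
  for (fid in rownames(out)) {
    i <- which(pts$labels == fid)
    if (length(i) != 1L) stop("missing fiducial '", fid, "'")
    out[fid, ] <- pts$points[i, ]
  }
  out
}

#' Apply a rigid transform to points
#'
#' @param T An `ng_transform`.
#' @param pts An `ng_points` object or a bare N x 3 matrix.
#' @param new_frame Frame tag for the result; defaults to `T$to` when set,
#'   otherwise the input frame is kept.
#' @return Same type as `pts`, with the frame tag updated.
#' @export
apply_transform <- function(T, pts, new_frame = NULL) {
  if (inherits(pts, "ng_points")) {
    if (!is.null(T$from) && !identical(T$from, pts$frame))
      stop("frame mismatch: transform expects '", T$from,
           "', points are in '", pts$frame, "'")
    out_frame <- new_frame %||% T$to %||% pts$frame
    head_points(apply_transform(T, pts$points), pts$labels, out_frame)
  } else {
    p <- rbind_pts(pts)
    t(T$matrix[1:3, 1:3] %*% t(p)) +
      matrix(T$matrix[1:3, 4], nrow(p), 3, byrow = TRUE)
  }
}

#' Build the MEG head coordinate frame from the three fiducials
#'
#' Neuromag-style convention: the x-axis runs from LPA toward RPA; the origin
#' is the foot of the perpendicular dropped from the nasion onto the LPA-RPA
#' line; the y-axis points toward the nasion; the z-axis (x cross y) points
#' up. Returns the device-to-head transform.
#'
#' @param nasion,lpa,rpa Length-3 coordinates (mm) in the device frame.
#' @return `ng_transform` mapping device coordinates to head coordinates.
#' @export
build_head_frame <- function(nasion, lpa, rpa) {
  nasion <- as.numeric(nasion); lpa <- as.numeric(lpa); rpa <- as.numeric(rpa)
  ex <- rpa - lpa
  nx <- sqrt(sum(ex^2))
  if (nx < 1e-9) stop("degenerate fiducials: LPA and RPA coincide")
  ex <- ex / nx
  # foot of the perpendicular from nasion to the LPA-RPA line
  origin <- lpa + sum((nasion - lpa) * ex) * ex
  ey <- nasion - origin
  ny <- sqrt(sum(ey^2))
  if (ny < 1e-9) stop("degenerate fiducials: collinear configuration")
  ey <- ey / ny
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- rbind(ex, ey, ez)  # rows are head axes in device coordinates
  rigid_from_parts(R, -R %*% origin, from = "device", to = "head")
}

#' Least-squares rigid alignment of matched landmarks
#'
#' Closed-form proper rigid transform minimizing `sum ||T src_i - dst_i||^2`
#' over matched point pairs (Kabsch: centroid alignment followed by SVD of
#' the cross-covariance with reflection correction), as used for the
#' fiducial-based first step of MEG-MRI coregistration.
#'
#' @param src,dst N x 3 matrices of corresponding points (N >= 3).
#' @param from,to Optional frame tags for the result.
#' @return An `ng_transform`.
#' @export
fit_rigid_landmarks <- function(src, dst, from = NULL, to = NULL) {
  src <- rbind_pts(src)
  dst <- rbind_pts(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst must have matching rows")
  if (nrow(src) < 3L) stop("at least 3 matched points required")
  stopifnot_finite(src); stopifnot_finite(dst)
  cs <- colMeans(src)
  cd <- colMeans(dst)
  A <- sweep(src, 2, cs)
  B <- sweep(dst, 2, cd)
  H <- t(A) %*% B
  s <- svd(H)
  if (s$d[2] < 1e-12 * max(s$d[1], 1))
    stop("rank-deficient landmark configuration")
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  rigid_from_parts(R, cd - R %*% cs, from = from, to = to)
}

#' Serialize transforms as JSON
#' @param T An `ng_transform`.
#' @param path Output file.
#' @export
write_transform <- function(T, path) {
  jsonlite::write_json(
    list(matrix = T$matrix, from = T$from, to = T$to),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(unlist(x$matrix), 4, 4),
                  from = x$from, to = x$to)
}

#' Read / write head point sets as TSV
#'
#' Plain TSV with columns `label`, `x`, `y`, `z` (mm).
#'
#' @param pts An `ng_points` object.
#' @param path File path.
#' @export
write_headpoints <- function(pts, path) {
  df <- data.frame(label = pts$labels, x = pts$points[, 1],
                   y = pts$points[, 2], z = pts$points[, 3])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_headpoints
#' @param frame Frame tag to attach on read.
#' @export
read_headpoints <- function(path, frame = "device") {
  df <- read.delim(path)
  head_points(as.matrix(df[, c("x", "y", "z")]), df$label, frame)
}
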