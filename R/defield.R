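#' Dense deformation fields
#'
#' Per-voxel displacement vectors (mm, world axes) on a reference grid,
#' mapping template world coordinates to subject world coordinates as
#' `phi(x) = x + d(x)`, together with a numerically inverted displacement for
#' the subject-to-template direction. The grid is described by an `ng_volume`
#' affine and shape (normally the template grid).
#'
#' @param disp 4-D array `(nx, ny, nz, 3)` of displacements in mm.
#' @param affine 4x4 voxel-to-world matrix of the reference grid.
#' @param inv_disp Optional precomputed inverse displacement on the same
#'   grid; computed by fixed-point iteration when omitted.
#' @return An object of class `ng_defield`.
#' @export
deformation_field <- function(disp, affine, inv_disp = NULL) {
  d <- dim(disp)
  if (length(d) != 4L || d[4] != 3L) stop("disp must be (nx,ny,nz,3)")
  obj <- structure(list(disp = disp, affine = as.matrix(affine),
                        shape = d[1:3], inv_disp = inv_disp),
                   class = "ng_defield")
  if (is.null(inv_disp)) obj$inv_disp <- invert_displacement(obj)
  obj
}

#' @export
print.ng_defield <- function(x, ...) {
  mag <- sqrt(x$disp[, , , 1]^2 + x$disp[, , , 2]^2 + x$disp[, , , 3]^2)
  cat(sprintf("<ng_defield> grid %s, |displacement| mean %.3g mm, max %.3g mm\n",
              paste(x$shape, collapse = " x "), mean(mag), max(mag)))
  invisible(x)
}

ref_volume <- function(field) {
  ng_volume(array(0, field$shape), field$affine)
}

# Interpolate the (inverse) displacement at world points; points outside the
# grid get zero displacement unless strict = TRUE (then error).
interp_displacement <- function(field, xyz, inverse = FALSE, strict = FALSE) {
  xyz <- rbind_pts(xyz)
  ref <- ref_volume(field)
  v <- world_to_voxel(ref, xyz)
  d <- field$shape
  if (strict) {
    bad <- v[, 1] < 0 | v[, 2] < 0 | v[, 3] < 0 |
      v[, 1] > d[1] - 1 | v[, 2] > d[2] - 1 | v[, 3] > d[3] - 1
    if (any(bad)) stop(sum(bad), " point(s) outside the deformation domain")
  }
  src <- if (inverse) field$inv_disp else field$disp
  out <- matrix(0, nrow(xyz), 3)
  for (k in 1:3) {
    comp <- src[, , , k]
    dim(comp) <- d
    out[, k] <- cpp_sample_trilinear(comp, v, 0)
  }
  out
}

#' Apply a deformation field to points
#'
#' Forward direction maps template-space points into subject space
#' (`x + d(x)`); `inverse = TRUE` maps subject-space points back.
#'
#' @param field An `ng_defield`.
#' @param xyz N x 3 world coordinates (mm).
#' @param inverse Use the stored inverse displacement.
#' @param strict Error if a point falls outside the field's grid (otherwise
#'   zero displacement is assumed there).
#' @return N x 3 matrix of mapped coordinates.
#' @export
apply_deformation <- function(field, xyz, inverse = FALSE, strict = FALSE) {
  rbind_pts(xyz) + interp_displacement(field, xyz, inverse, strict)
}

# Fixed-point inversion of the displacement field on its own grid:
# d_inv(y) = -d(y + d_inv(y)).
invert_displacement <- function(field, n_iter = 30L) {
  ref <- ref_volume(field)
  gw <- grid_world(ref)
  dinv <- matrix(0, nrow(gw), 3)
  for (it in seq_len(n_iter)) {
    dinv <- -interp_displacement(field, gw + dinv, inverse = FALSE)
  }
  array(dinv, c(field$shape, 3L))
}

#' Residual of composing a field with its inverse
#'
#' Mean over grid voxels of `|phi^{-1}(phi(x)) - x|` in mm; should be well
#' below one voxel for a valid field.
#'
#' @param field An `ng_defield`.
#' @return Mean residual in mm.
#' @export
inverse_consistency_mm <- function(field) {
  gw <- grid_world(ref_volume(field))
  fwd <- apply_deformation(field, gw)
  back <- apply_deformation(field, fwd, inverse = TRUE)
  mean(sqrt(rowSums((back - gw)^2)))
}

#' Jacobian determinant of a deformation field
#'
#' Determinant of `d phi / d x` at every voxel (central differences);
#' positive everywhere for an invertible, orientation-preserving field.
#'
#' @param field An `ng_defield`.
#' @return 3-D array of determinants.
#' @export
jacobian_determinant <- function(field) {
  vox <- sqrt(colSums(field$affine[1:3, 1:3]^2))
  J <- vector("list", 9L)
  for (k in 1:3) {
    comp <- field$disp[, , , k]
    dim(comp) <- field$shape
    g <- gradient3d(comp, vox)
    for (ax in 1:3) J[[(k - 1) * 3 + ax]] <- g[[ax]]
  }
  # d(phi_k)/d(x_ax) = delta_{k,ax} + d(d_k)/d(x_ax)
  a11 <- 1 + J[[1]]; a12 <- J[[2]]; a13 <- J[[3]]
  a21 <- J[[4]]; a22 <- 1 + J[[5]]; a23 <- J[[6]]
  a31 <- J[[7]]; a32 <- J[[8]]; a33 <- 1 + J[[9]]
  a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Write / read deformation fields as 4-D NIfTI displacement volumes
#' @param field An `ng_defield`.
#' @param path Output `.nii`/`.nii.gz` path (x,y,z displacement components
#'   in mm along the 4th dimension).
#' @export
write_deformation <- function(field, path) {
  img <- RNifti::asNifti(field$disp)
  RNifti::sform(img) <- structure(field$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_deformation
#' @export
read_deformation <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(structure(RNifti::xform(img),
                                     imagedim = NULL, code = NULL)), 4, 4)
  deformation_field(as.array(img), aff)
}
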