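#' 3-D image volume with a voxel-to-world affine
#'
#' The basic imaging container: a 3-D numeric array of intensities plus a
#' 4x4 affine mapping 0-based voxel indices to world coordinates in mm
#' (NIfTI convention). All registration and anonymization operations work on
#' this class.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm); last row `c(0,0,0,1)`.
#' @return An object of class `ng_volume` with elements `data` and `affine`.
#' @export
ng_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (any(abs(affine[4, ] - c(0, 0, 0, 1)) > 1e-9))
    stop("last affine row must be (0,0,0,1)")
  structure(list(data = data, affine = affine), class = "ng_volume")
}

#' @export
print.ng_volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("<ng_volume> %d x %d x %d voxels, voxel size %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ng_volume <- function(x) dim(x$data)

#' Voxel edge lengths in mm
#' @param vol An `ng_volume`.
#' @return Numeric length-3 vector of voxel sizes.
#' @export
voxel_size <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

#' Convert between voxel and world coordinates
#'
#' @param vol An `ng_volume`.
#' @param ijk N x 3 matrix of 0-based voxel coordinates (may be fractional).
#' @return N x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind_pts(ijk)
  t(vol$affine[1:3, 1:3] %*% t(ijk)) +
    matrix(vol$affine[1:3, 4], nrow(ijk), 3, byrow = TRUE)
}

#' @rdname voxel_to_world
#' @param xyz N x 3 matrix of world coordinates in mm.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind_pts(xyz)
  inv <- solve(vol$affine)
  t(inv[1:3, 1:3] %*% t(xyz)) +
    matrix(inv[1:3, 4], nrow(xyz), 3, byrow = TRUE)
}

rbind_pts <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) == 1L && nrow(p) == 3L) p <- t(p)
  if (ncol(p) != 3L) stop("points must be N x 3")
  storage.mode(p) <- "double"
  p
}

#' Sample a volume at world-space points
#'
#' @param vol An `ng_volume`.
#' @param xyz N x 3 world coordinates (mm).
#' @param method `"trilinear"` or `"nearest"`.
#' @param outside Fill value for points outside the grid.
#' @return Numeric vector of sampled intensities.
#' @export
sample_volume <- function(vol, xyz, method = c("trilinear", "nearest"),
                          outside = 0) {
  method <- match.arg(method)
  v <- world_to_voxel(vol, xyz)
  dat <- vol$data
  storage.mode(dat) <- "double"
  if (method == "trilinear") cpp_sample_trilinear(dat, v, outside)
  else cpp_sample_nearest(dat, v, outside)
}

# World coordinates of every voxel, as an n x 3 matrix (voxel order).
grid_world <- function(vol) {
  d <- dim(vol$data)
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxel_to_world(vol, ijk)
}

# Periodic (FFT) Gaussian smoothing of a 3-D array; sigma in voxels,
# recycled to length 3. sigma = 0 returns the input.
smooth3d <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3L)
  if (all(sigma <= 0)) return(arr)
  d <- dim(arr)
  k1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1)))
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  K <- outer(outer(fft(k1(d[1], sigma[1])), fft(k1(d[2], sigma[2]))),
             fft(k1(d[3], sigma[3])))
  dim(K) <- d
  Re(fft(fft(arr) * K, inverse = TRUE)) / prod(d)
}

# Central-difference spatial gradient (per mm, world axes assumed aligned
# with voxel axes up to scaling) of a 3-D array. Returns list of 3 arrays.
gradient3d <- function(arr, voxmm = c(1, 1, 1)) {
  d <- dim(arr)
  g <- vector("list", 3L)
  for (ax in 1:3) {
    ip <- pmin(seq_len(d[ax]) + 1L, d[ax])
    im <- pmax(seq_len(d[ax]) - 1L, 1L)
    idx_p <- idx_m <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_p[[ax]] <- ip
    idx_m[[ax]] <- im
    g[[ax]] <- (arr[idx_p[[1]], idx_p[[2]], idx_p[[3]], drop = FALSE] -
                arr[idx_m[[1]], idx_m[[2]], idx_m[[3]], drop = FALSE]) /
      ((ip - im) * voxmm[ax])
    dim(g[[ax]]) <- d
  }
  g
}

# Downsample a volume by integer factor (block mean), adjusting the affine.
downsample_volume <- function(vol, factor) {
  if (factor == 1L) return(vol)
  d <- dim(vol$data)
  nd <- d %/% factor
  a <- vol$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(a, c(2, 4, 6), mean)
  aff <- vol$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * factor
  # centre of the first block: voxel (factor-1)/2 of the original grid
  aff[1:3, 4] <- voxel_to_world(vol, matrix(rep((factor - 1) / 2, 3), 1))
  ng_volume(out, aff)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around \pkg{RNifti} preserving the voxel-to-world affine.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns an `ng_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  ng_volume(as.array(img), matrix(as.numeric(aff), 4, 4))
}

#' @rdname read_volume
#' @param vol An `ng_volume` to write.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
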