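#' Synthetic head template and phantom subjects
#'
#' The phantom module generates a head-shaped template (superellipsoid head
#' with a protruding nose and ear bumps, concentric skull and brain shells),
#' a five-class tissue probability map whose face class excludes the nose,
#' a canonical inner-skull mesh, and subject phantoms obtained by resampling
#' the template through random smooth invertible deformations. Because every
#' subject is a known deformation of the template, registration,
#' anonymization and surface pipelines can be validated against exact ground
#' truth.
#'
#' @name phantom
NULL

# Fixed template geometry (mm). The piecewise-constant intensity model
# (air 0, soft tissue 0.7, skull 0.3, brain 1.0) and the structural layout
# are arbitrary but frozen; see the methods vignette.
phantom_params <- function() {
  list(
    head_center = c(0, -8, 0),
    head_radii = c(62, 72, 75),
    exponent = 2.2,
    brain_scale = 0.68,
    skull_scale = 0.80,
    inner_skull_scale = 0.70,
    nose_center_z = -22,
    nose_radii = c(11, 22, 16),
    nose_margin_mm = 8,       # face-class exclusion margin around the nose
    ear_center = c(64, -8, -15),
    ear_radii = c(8, 14, 18),
    occiput_center_z = -20,
    occiput_radii = c(30, 12, 25),
    occiput_inset_mm = 6,
    face_y_min = 15,
    face_z_range = c(-55, 28),
    scalp_z_min = -30,        # lower bound of the "upper head" sampling zone
    intensities = c(air = 0, soft = 0.7, skull = 0.3, brain = 1.0),
    tpm_sigma_vox = 1.0,
    intensity_sigma_vox = 0.6,
    scalp_threshold = 0.35
  )
}

# Superellipsoid "radial" value: F <= 1 inside the surface.
sellipse_F <- function(xyz, center, radii, p) {
  d <- sweep(rbind_pts(xyz), 2, center)
  (abs(d[, 1] / radii[1])^p + abs(d[, 2] / radii[2])^p +
     abs(d[, 3] / radii[3])^p)^(1 / p)
}

#' Build the synthetic head template package
#'
#' Deterministic given `seed` (the default template is fully deterministic;
#' the seed is reserved for optional randomized variants and recorded in the
#' output). The result holds the template intensity volume, the five-class
#' tissue probability map (background, soft tissue, skull, brain, and face
#' excluding the nose), hard structural masks, the template scalp mesh with
#' nose-vertex flags, the three fiducials and the level-4 icosphere canonical
#' inner-skull mesh fitted inside the template skull.
#'
#' @param grid_shape Integer length-3 grid size (all >= 48).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param seed Integer seed (recorded; the default construction is
#'   deterministic regardless).
#' @return An object of class `ng_template`.
#' @export
make_template <- function(grid_shape = c(48L, 48L, 48L), voxel_size_mm = 4,
                          seed = 1L) {
  grid_shape <- rep(as.integer(grid_shape), length.out = 3L)
  if (any(grid_shape < 48L)) stop("grid too small: need at least 48^3 voxels")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  par <- phantom_params()

  # world extents must contain all structures with margin for deformation
  fov_half <- (grid_shape - 1) * voxel_size_mm / 2
  need <- c(par$ear_center[1] + par$ear_radii[1],
            par$head_center[2] + par$head_radii[2] + par$nose_radii[2],
            par$head_radii[3]) + 2 * voxel_size_mm
  if (any(need > fov_half))
    stop("grid too small to contain all structures: need half-FOV ",
         paste(round(need, 1), collapse = "/"), " mm")

  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- -fov_half
  ref <- ng_volume(array(0, grid_shape), affine)
  gw <- grid_world(ref)

  Fh <- sellipse_F(gw, par$head_center, par$head_radii, par$exponent)
  nose_center <- nose_center_world(par)
  Fn <- sellipse_F(gw, nose_center, par$nose_radii, 2)
  Fe1 <- sellipse_F(gw, par$ear_center * c(1, 1, 1), par$ear_radii, 2)
  Fe2 <- sellipse_F(gw, par$ear_center * c(-1, 1, 1), par$ear_radii, 2)
  Fo <- sellipse_F(gw, occiput_center_world(par), par$occiput_radii, 2)
  Fn_infl <- sellipse_F(gw, nose_center, par$nose_radii + par$nose_margin_mm, 2)

  # the occipital bump breaks the front-back near-symmetry of the upper
  # head, as the external occipital protuberance does on a real skull
  head <- Fh <= 1 | Fn <= 1 | Fe1 <= 1 | Fe2 <= 1 | Fo <= 1
  brain <- Fh <= par$brain_scale
  skull <- Fh > par$brain_scale & Fh <= par$skull_scale
  nose <- Fn <= 1 & Fh > 1                     # protruding part only
  face_zone <- head & !brain & !skull & Fh > par$skull_scale &
    gw[, 2] > par$face_y_min &
    gw[, 3] > par$face_z_range[1] & gw[, 3] < par$face_z_range[2]
  face <- face_zone & Fn_infl > 1              # margin collar spares the nose

  labels <- integer(nrow(gw))                  # 0 air
  labels[head] <- 1L                           # soft tissue
  labels[skull] <- 2L
  labels[brain] <- 3L
  labels[face] <- 4L                           # face (soft) without nose
  labels[nose] <- 5L                           # nose (soft)
  labels <- array(labels, grid_shape)

  inten <- c(par$intensities["air"], par$intensities["soft"],
             par$intensities["skull"], par$intensities["brain"],
             par$intensities["soft"], par$intensities["soft"])[labels + 1L]
  inten <- array(inten, grid_shape)
  inten <- smooth3d(inten, par$intensity_sigma_vox)
  volume <- ng_volume(inten, affine)

  # five-class TPM; face-class probability forced to zero on the nose region
  cls <- list(background = labels == 0L,
              soft = labels == 1L | labels == 5L,
              skull = labels == 2L,
              brain = labels == 3L,
              face = labels == 4L)
  tpm <- lapply(cls, function(m)
    smooth3d(array(as.numeric(m), grid_shape), par$tpm_sigma_vox))
  tpm$face[array(nose, grid_shape)] <- 0
  tot <- Reduce(`+`, tpm)
  tpm <- lapply(tpm, function(a) a / tot)
  tpm <- lapply(tpm, function(a) ng_volume(a, affine))

  # face-including-nose probability for the de-facing comparator, built the
  # same way as the face class so de-facing removes a superset of trimming
  fwn_prob <- smooth3d(array(as.numeric(face_zone | nose), grid_shape),
                       par$tpm_sigma_vox) / tot
  fwn_prob <- ng_volume(pmax(pmin(fwn_prob, 1), 0), affine)

  # canonical inner skull: level-4 icosphere mapped radially inside the skull
  ico <- make_icosphere(4L)
  r_dir <- (abs(ico$vertices[, 1] / par$head_radii[1])^par$exponent +
            abs(ico$vertices[, 2] / par$head_radii[2])^par$exponent +
            abs(ico$vertices[, 3] / par$head_radii[3])^par$exponent)^(-1 / par$exponent)
  inner_skull <- ng_mesh(
    sweep(ico$vertices * (par$inner_skull_scale * r_dir), 2,
          par$head_center, `+`),
    ico$faces)

  scalp <- extract_scalp(volume, par$scalp_threshold)
  nose_vertex <- sellipse_F(scalp$vertices, nose_center,
                            par$nose_radii + 3, 2) <= 1
  sv <- scalp$vertices
  face_vertex <- !nose_vertex & sv[, 2] > par$face_y_min &
    sv[, 3] > par$face_z_range[1] & sv[, 3] < par$face_z_range[2]

  fid <- rbind(
    nasion = par$head_center + c(0, par$head_radii[2], 0),
    lpa = c(-(par$ear_center[1] + par$ear_radii[1]), par$ear_center[2],
            par$ear_center[3]),
    rpa = c(par$ear_center[1] + par$ear_radii[1], par$ear_center[2],
            par$ear_center[3]))
  colnames(fid) <- c("x", "y", "z")

  masks <- list(head = array(head, grid_shape),
                brain = array(brain, grid_shape),
                skull = array(skull, grid_shape),
                face = array(face, grid_shape),
                nose = array(nose, grid_shape),
                # the whole anterior shell incl. the nose and its collar:
                # what a conventional de-facer takes off
                face_with_nose = array(face_zone | nose | (Fn <= 1 & head),
                                       grid_shape))

  structure(list(volume = volume, tpm = tpm, labels = labels, masks = masks,
                 face_with_nose_prob = fwn_prob,
                 canonical_inner_skull = inner_skull, scalp = scalp,
                 scalp_nose_vertex = nose_vertex,
                 scalp_face_vertex = face_vertex, fiducials = fid,
                 params = par, seed = seed),
            class = "ng_template")
}

occiput_center_world <- function(par) {
  z <- par$occiput_center_z
  yr <- par$head_radii[2] *
    (1 - abs((z - par$head_center[3]) / par$head_radii[3])^par$exponent)^(1 / par$exponent)
  c(0, par$head_center[2] - yr + par$occiput_inset_mm, z)
}

nose_center_world <- function(par) {
  z <- par$nose_center_z
  yr <- par$head_radii[2] *
    (1 - abs((z - par$head_center[3]) / par$head_radii[3])^par$exponent)^(1 / par$exponent)
  c(0, par$head_center[2] + yr, z)
}

#' @export
print.ng_template <- function(x, ...) {
  cat("<ng_template>\n  ")
  print(x$volume)
  cat(sprintf("  TPM classes: %s\n", paste(names(x$tpm), collapse = ", ")))
  cat(sprintf("  canonical inner skull: %d vertices\n",
              nrow(x$canonical_inner_skull$vertices)))
  invisible(x)
}

# Band-limited random displacement field (separable sinusoid products) with
# peak vector magnitude = amplitude, as a (nx,ny,nz,3) array in mm.
random_smooth_displacement <- function(ref, amplitude_mm, n_terms = 3L) {
  d <- dim(ref$data)
  ax <- lapply(1:3, function(k) {
    idx <- seq_len(d[k]) - 1
    idx / max(idx, 1)  # normalized 0..1 along axis
  })
  disp <- array(0, c(d, 3L))
  if (amplitude_mm > 0) {
    for (k in 1:3) {
      comp <- array(0, d)
      for (m in seq_len(n_terms)) {
        f <- runif(3, 0.5, 1.25)
        ph <- runif(3, 0, 2 * pi)
        a <- rnorm(1)
        term <- outer(outer(sin(2 * pi * f[1] * ax[[1]] + ph[1]),
                            sin(2 * pi * f[2] * ax[[2]] + ph[2])),
                      sin(2 * pi * f[3] * ax[[3]] + ph[3]))
        comp <- comp + a * term
      }
      disp[, , , k] <- comp
    }
    mag <- sqrt(disp[, , , 1]^2 + disp[, , , 2]^2 + disp[, , , 3]^2)
    disp <- disp * (amplitude_mm / max(mag))
  }
  disp
}

#' Generate a phantom subject by deforming the template
#'
#' Draws a random smooth (band-limited sinusoidal) displacement field with
#' peak magnitude `deform_amplitude_mm`, verifies grid-wide Jacobian
#' positivity (redrawing up to `max_attempts` times), and resamples the
#' template intensities through the inverse map, adding Gaussian intensity
#' noise. Masks are carried through the same deformation by nearest-neighbour
#' label resampling (guaranteeing they stay disjoint), and the scalp and
#' canonical inner-skull meshes and fiducials are warped by the forward map.
#' The ground-truth deformation is stored.
#'
#' @param template An `ng_template`.
#' @param deform_amplitude_mm Peak displacement magnitude (mm).
#' @param intensity_noise_sd Gaussian noise added to the resampled volume.
#' @param seed Integer seed; output is fully deterministic given it.
#' @param max_attempts Redraws allowed before giving up on an invertible field.
#' @return An object of class `ng_phantom` with elements `volume`, `masks`,
#'   `fiducials_mri`, `true_deformation`, `true_scalp`, `scalp_nose_vertex`,
#'   `true_inner_skull`.
#' @export
make_head_phantom <- function(template, deform_amplitude_mm = 5,
                              intensity_noise_sd = 0.05, seed = 1L,
                              max_attempts = 10L) {
  stopifnot(inherits(template, "ng_template"))
  ref <- template$volume
  with_seed(seed, {
    disp <- NULL
    for (att in seq_len(max_attempts)) {
      cand <- random_smooth_displacement(ref, deform_amplitude_mm)
      fld <- structure(list(disp = cand, affine = ref$affine,
                            shape = dim(ref$data), inv_disp = NULL),
                       class = "ng_defield")
      if (min(jacobian_determinant(fld)) > 0.05) {
        disp <- cand
        break
      }
    }
    if (is.null(disp))
      stop("could not draw an invertible deformation after ", max_attempts,
           " attempts; reduce deform_amplitude_mm")
    field <- deformation_field(disp, ref$affine)

    gw <- grid_world(ref)
    back <- apply_deformation(field, gw, inverse = TRUE)
    inten <- sample_volume(ref, back)
    if (intensity_noise_sd > 0)
      inten <- inten + rnorm(length(inten), 0, intensity_noise_sd)
    vol <- ng_volume(array(inten, dim(ref$data)), ref$affine)

    lab_arr <- array(as.numeric(template$labels), dim(ref$data))
    lab_vol <- ng_volume(lab_arr, ref$affine)
    labs <- array(as.integer(round(sample_volume(lab_vol, back, "nearest"))),
                  dim(ref$data))
    masks <- list(head = labs > 0L, brain = labs == 3L, skull = labs == 2L,
                  face = labs == 4L, nose = labs == 5L)
    # collar-inclusive de-facing mask warped from the template directly
    # (the label volume cannot represent it: the nose collar is plain soft)
    fwn_vol <- ng_volume(array(as.numeric(template$masks$face_with_nose),
                               dim(ref$data)), ref$affine)
    masks$face_with_nose <- array(
      sample_volume(fwn_vol, back, "nearest") > 0.5, dim(ref$data))

    scalp <- ng_mesh(apply_deformation(field, template$scalp$vertices),
                     template$scalp$faces)
    iskull <- ng_mesh(
      apply_deformation(field, template$canonical_inner_skull$vertices),
      template$canonical_inner_skull$faces)
    fid <- template$fiducials
    fid[] <- apply_deformation(field, fid)

    structure(list(volume = vol, masks = masks, labels = labs,
                   fiducials_mri = fid, true_deformation = field,
                   true_scalp = scalp,
                   scalp_nose_vertex = template$scalp_nose_vertex,
                   scalp_face_vertex = template$scalp_face_vertex,
                   true_inner_skull = iskull,
                   deform_amplitude_mm = deform_amplitude_mm,
                   intensity_noise_sd = intensity_noise_sd, seed = seed),
              class = "ng_phantom")
  })
}

#' @export
print.ng_phantom <- function(x, ...) {
  cat(sprintf("<ng_phantom> seed %s, deformation amplitude %.3g mm\n",
              format(x$seed), x$deform_amplitude_mm))
  print(x$volume)
  invisible(x)
}

#' Random rigid transform
#'
#' Uniform per-axis Euler rotations up to `max_rot_deg` and translations up
#' to `max_trans_mm`; used for device transforms and ICP restarts.
#'
#' @param max_rot_deg,max_trans_mm Perturbation bounds.
#' @param seed Optional seed.
#' @param from,to Optional frame tags.
#' @return An `ng_transform`.
#' @export
random_rigid <- function(max_rot_deg = 15, max_trans_mm = 10, seed = NULL,
                         from = NULL, to = NULL) {
  with_seed(seed, {
    ang <- runif(3, -max_rot_deg, max_rot_deg) * pi / 180
    t <- runif(3, -max_trans_mm, max_trans_mm)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                   0, -sin(ang[1]), cos(ang[1])), 3, 3)
    Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                   sin(ang[2]), 0, cos(ang[2])), 3, 3)
    Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]),
                   cos(ang[3]), 0, 0, 0, 1), 3, 3)
    rigid_from_parts(Rz %*% Ry %*% Rx, t, from = from, to = to)
  })
}

#' Sample digitized head points from a phantom
#'
#' Emulates MEG head digitization: points drawn uniformly by area on the
#' phantom's true scalp surface (upper head for scalp points, the nose
#' surface for nose points), perturbed by isotropic Gaussian noise, plus the
#' three fiducials with independent (typically larger) noise, all mapped
#' into device coordinates through `device_transform`.
#'
#' @param subject An `ng_phantom`.
#' @param n_scalp Number of scalp points (the field's convention is ~100).
#' @param n_nose Number of nose points.
#' @param noise_sd_mm Isotropic digitization noise for head points.
#' @param fiducial_noise_sd_mm Noise for the digitized fiducials (manual
#'   placement error is typically larger than digitizer noise).
#' @param device_transform `ng_transform` from MRI world to device
#'   coordinates (identity by default).
#' @param seed Integer seed.
#' @return An `ng_points` set in the device frame.
#' @export
sample_head_points <- function(subject, n_scalp = 100L, n_nose = 15L,
                               noise_sd_mm = 2, fiducial_noise_sd_mm = 3,
                               device_transform = NULL, seed = 1L) {
  stopifnot(inherits(subject, "ng_phantom"))
  if (n_scalp + n_nose < 3L) stop("need at least 3 head points")
  if (noise_sd_mm < 0 || fiducial_noise_sd_mm < 0) stop("noise sd must be >= 0")
  device_transform <- device_transform %||%
    rigid_transform(diag(4), from = "mri_world", to = "device")
  mesh <- subject$true_scalp
  nosev <- subject$scalp_nose_vertex
  facev <- subject$scalp_face_vertex
  par <- phantom_params()
  with_seed(seed, {
    fc_z <- (mesh$vertices[mesh$faces[, 1], 3] +
             mesh$vertices[mesh$faces[, 2], 3] +
             mesh$vertices[mesh$faces[, 3], 3]) / 3
    n_nose_verts <- nosev[mesh$faces[, 1]] + nosev[mesh$faces[, 2]] +
      nosev[mesh$faces[, 3]]
    n_face_verts <- facev[mesh$faces[, 1]] + facev[mesh$faces[, 2]] +
      facev[mesh$faces[, 3]]
    scalp_faces <- which(n_nose_verts == 0L & n_face_verts == 0L &
                           fc_z > par$scalp_z_min)
    nose_faces <- which(n_nose_verts >= 2L)
    if (n_nose > 0L && length(nose_faces) == 0L)
      stop("phantom has no nose surface to sample nose points from")
    areas <- face_areas(mesh)
    draw_on <- function(face_ids, n) {
      if (n == 0L) return(matrix(0, 0, 3))
      f <- sample(face_ids, n, replace = TRUE, prob = areas[face_ids])
      u <- runif(n); v <- runif(n)
      flip <- u + v > 1
      u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
      a <- mesh$vertices[mesh$faces[f, 1], , drop = FALSE]
      b <- mesh$vertices[mesh$faces[f, 2], , drop = FALSE]
      c <- mesh$vertices[mesh$faces[f, 3], , drop = FALSE]
      a + u * (b - a) + v * (c - a)
    }
    pts <- rbind(draw_on(scalp_faces, n_scalp), draw_on(nose_faces, n_nose))
    if (noise_sd_mm > 0)
      pts <- pts + matrix(rnorm(length(pts), 0, noise_sd_mm), ncol = 3)
    fid <- subject$fiducials_mri
    if (fiducial_noise_sd_mm > 0)
      fid <- fid + matrix(rnorm(9, 0, fiducial_noise_sd_mm), 3, 3)
    all_pts <- rbind(fid, pts)
    labels <- c("nasion", "lpa", "rpa",
                rep("scalp", n_scalp), rep("nose", n_nose))
    mri_set <- head_points(all_pts, labels, "mri_world")
    apply_transform(device_transform, mri_set, new_frame = "device")
  })
}
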