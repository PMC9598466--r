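#' Slippage demonstration fixture
#'
#' An analytic head-shape fixture isolating the rotational "slippage"
#' failure mode of head-shape coregistration: a spherical scalp (optionally
#' carrying a smooth nose-like radial bump on its anterior-inferior aspect)
#' plus digitized points drawn from its upper cap (and from the nose bump
#' when present). Point coordinates are generated from the same radial
#' function as the mesh, so the ground-truth device-to-MRI transform is the
#' identity. Without the nose the upper cap is rotationally near-symmetric
#' about the sphere centre and ICP has a continuum of near-equal minima;
#' the nose breaks the symmetry.
#'
#' @param with_nose Include the nose bump on the mesh and nose points.
#' @param n_scalp,n_nose Point counts.
#' @param level Icosphere subdivision level of the mesh.
#' @param radius Scalp radius (mm).
#' @param bump_height Nose bump height as a fraction of the radius.
#' @param bump_width Angular half-widths (radians) of the nose ridge,
#'   `c(across, along)`: the ridge is narrower across than along its
#'   inferior direction, as a real nose is, which pins the rotation about
#'   the nose axis that a rotationally symmetric bump would leave free.
#' @param cap_z Lower z bound (mm) of the scalp sampling cap.
#' @param seed Integer seed for the point draws.
#' @return List with `mesh` (`ng_mesh`), `points` (`ng_points`, device
#'   frame) and `truth` (identity `ng_transform`).
#' @export
make_slippage_fixture <- function(with_nose = FALSE, n_scalp = 80L,
                                  n_nose = 12L, level = 5L, radius = 80,
                                  bump_height = 0.30,
                                  bump_width = c(0.12, 0.30),
                                  cap_z = 25, seed = 1L) {
  nose_dir <- c(0, cos(25 * pi / 180), -sin(25 * pi / 180))
  e_across <- c(1, 0, 0)
  e_along <- c(0, -nose_dir[3], nose_dir[2])
  radial <- function(u) {
    # u: unit directions, N x 3; sphere plus an anisotropic nose ridge
    r <- rep(radius, nrow(u))
    if (with_nose) {
      a3 <- pmax(as.vector(u %*% nose_dir), 1e-9)
      ax <- atan2(as.vector(u %*% e_across), a3)
      al <- atan2(as.vector(u %*% e_along), a3)
      r <- r * (1 + bump_height *
                  exp(-(ax^2 / (2 * bump_width[1]^2) +
                        al^2 / (2 * bump_width[2]^2))))
    }
    r
  }
  ico <- make_icosphere(level)
  mesh <- ng_mesh(ico$vertices * radial(ico$vertices), ico$faces)

  with_seed(seed, {
    z0 <- cap_z / radius
    z <- runif(n_scalp, z0, 1)
    phi <- runif(n_scalp, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    u <- cbind(s * cos(phi), s * sin(phi), z)
    pts <- u * radial(u)
    labels <- rep("scalp", n_scalp)
    if (with_nose && n_nose > 0L) {
      tx <- runif(n_nose, -bump_width[1], bump_width[1])
      ty <- runif(n_nose, -bump_width[2], bump_width[2])
      un <- t(vapply(seq_len(n_nose), function(i)
        nose_dir + tan(tx[i]) * e_across + tan(ty[i]) * e_along,
        numeric(3)))
      un <- un / sqrt(rowSums(un^2))
      pts <- rbind(pts, un * radial(un))
      labels <- c(labels, rep("nose", n_nose))
    }
    list(mesh = mesh,
         points = head_points(pts, labels, "device"),
         truth = rigid_transform(diag(4), from = "device", to = "mri_world"))
  })
}
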