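#' Exact point-to-surface distances
#'
#' Unsigned Euclidean distance from each query point to the nearest point of
#' a triangle mesh (face, edge and vertex cases handled exactly),
#' accelerated by a uniform-grid spatial index over triangles.
#'
#' @param pts N x 3 matrix of query points (mm) or an `ng_points` object.
#' @param mesh An `ng_mesh`.
#' @return List with `distance` (N), `closest` (N x 3) and `face` (N).
#' @export
point_to_surface_distance <- function(pts, mesh) {
  if (inherits(pts, "ng_points")) pts <- pts$points
  pts <- rbind_pts(pts)
  stopifnot_finite(pts, "query points")
  if (nrow(mesh$faces) == 0L) stop("empty mesh")
  cpp_closest_point_mesh(mesh$vertices, mesh$faces, pts)
}

#' Head-shape ICP registration to a scalp surface
#'
#' Iterative closest point fitting of digitized points to a surface mesh,
#' run from `n_init` starts (the supplied `init` plus `n_init - 1` random
#' rigid perturbations of it, up to ±`perturb_rot_deg` per axis and
#' ±`perturb_trans_mm`); each start alternates exact closest-point
#' correspondence with closed-form rigid refitting until the RMS change
#' drops below `tol` or `max_iter` is reached. The best final RMS wins.
#' Deterministic given `seed`.
#'
#' @param pts N x 3 matrix (N >= 3) or `ng_points` in the source frame.
#' @param mesh Target `ng_mesh`.
#' @param init Initial `ng_transform` (identity if `NULL`).
#' @param n_init Number of initializations (RHINO-style protocols use 10).
#' @param max_iter,tol Convergence controls (mm RMS change).
#' @param perturb_rot_deg,perturb_trans_mm Restart perturbation bounds.
#' @param seed Integer seed for the random restarts.
#' @return An object of class `ng_coreg`: `transform`, `per_point_residuals`,
#'   `rms`, `n_iterations`, `init_index`, `rms_trace` (winning start),
#'   `all_rms` and `all_transforms` (final RMS and transform of every
#'   start).
#' @export
icp_register <- function(pts, mesh, init = NULL, n_init = 10L,
                         max_iter = 200L, tol = 1e-4,
                         perturb_rot_deg = 15, perturb_trans_mm = 10,
                         seed = NULL) {
  pts_obj <- if (inherits(pts, "ng_points")) pts else NULL
  P <- if (is.null(pts_obj)) rbind_pts(pts) else pts_obj$points
  if (nrow(P) < 3L) stop("at least 3 points required for ICP")
  stopifnot_finite(P, "points")
  init <- init %||% rigid_transform(diag(4))
  index <- cpp_mesh_index(mesh$vertices, mesh$faces)

  starts <- with_seed(seed, {
    c(list(init),
      lapply(seq_len(max(0L, n_init - 1L)), function(i) {
        pert <- random_rigid(perturb_rot_deg, perturb_trans_mm)
        compose_transforms(pert, init)
      }))
  })

  run_one <- function(T0) {
    r <- cpp_icp_run(index, P, T0$matrix, max_iter, tol)
    list(transform = rigid_transform(r$transform, from = init$from,
                                     to = init$to),
         residuals = as.numeric(r$residuals), rms = r$rms,
         n_iterations = r$n_iterations, rms_trace = as.numeric(r$rms_trace))
  }

  runs <- lapply(starts, run_one)
  all_rms <- vapply(runs, function(r) r$rms, 0)
  best <- which.min(all_rms)
  r <- runs[[best]]
  structure(list(transform = r$transform,
                 per_point_residuals = r$residuals,
                 rms = r$rms, n_iterations = r$n_iterations,
                 init_index = best, rms_trace = r$rms_trace,
                 all_rms = all_rms,
                 all_transforms = lapply(runs, function(x) x$transform)),
            class = "ng_coreg")
}

#' @export
print.ng_coreg <- function(x, ...) {
  cat(sprintf(
    "<ng_coreg> rms %.4g mm over %d points; start %d of %d won after %d iterations\n",
    x$rms, length(x$per_point_residuals), x$init_index, length(x$all_rms),
    x$n_iterations))
  invisible(x)
}

#' Two-step MEG-MRI coregistration
#'
#' Step 1 rigidly aligns the three digitized fiducials to their MRI
#' counterparts; step 2 refines with multi-start ICP of the remaining head
#' points onto the scalp surface, initialized at the step-1 transform. With
#' `use_nose = FALSE` the digitized points satisfying the anterior-inferior
#' rule (y > 0 and z < 0 in the head frame built from the digitized
#' fiducials) are excluded before ICP, emulating coregistration against a
#' de-faced image where face points have no valid surface to match.
#'
#' @param headpoints `ng_points` in device coordinates containing the three
#'   fiducials plus head points.
#' @param fiducials_mri 3 x 3 matrix with rows `nasion`, `lpa`, `rpa` (MRI
#'   world mm), or an `ng_points` containing them.
#' @param scalp Scalp `ng_mesh` in MRI world coordinates.
#' @param use_nose Keep anterior-inferior (nose) points in step 2.
#' @param seed Seed for the ICP restarts.
#' @param ... Passed to [icp_register()].
#' @return An `ng_coreg` (device to MRI world) with extra fields
#'   `fiducial_transform` (step 1) and `n_points_used`.
#' @export
coregister_two_step <- function(headpoints, fiducials_mri, scalp,
                                use_nose = TRUE, seed = NULL, ...) {
  stopifnot(inherits(headpoints, "ng_points"))
  if (inherits(fiducials_mri, "ng_points"))
    fiducials_mri <- fiducial_matrix(fiducials_mri)
  fid_dev <- fiducial_matrix(headpoints)
  T1 <- fit_rigid_landmarks(fid_dev, fiducials_mri[rownames(fid_dev), ],
                            from = headpoints$frame, to = "mri_world")

  rest <- subset_points(headpoints,
                        !headpoints$labels %in% c("nasion", "lpa", "rpa"))
  if (!use_nose && length(rest) > 0L) {
    T_head <- build_head_frame(fid_dev["nasion", ], fid_dev["lpa", ],
                               fid_dev["rpa", ])
    in_head <- apply_transform(T_head, rest$points)
    keep <- !(in_head[, 2] > 0 & in_head[, 3] < 0)
    rest <- subset_points(rest, keep)
  }
  if (length(rest) < 3L) {
    # degenerate reduction: nothing beyond the fiducials to refine with
    q <- apply_transform(T1, fid_dev)
    resid <- sqrt(rowSums((q - fiducials_mri[rownames(fid_dev), ])^2))
    out <- structure(list(transform = T1, per_point_residuals = resid,
                          rms = sqrt(mean(resid^2)), n_iterations = 0L,
                          init_index = 1L, rms_trace = numeric(0),
                          all_rms = numeric(0)),
                     class = "ng_coreg")
    out$fiducial_transform <- T1
    out$n_points_used <- 0L
    return(out)
  }
  out <- icp_register(rest, scalp, init = T1, seed = seed, ...)
  out$fiducial_transform <- T1
  out$n_points_used <- length(rest)
  out
}
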