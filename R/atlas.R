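#' Affine intensity registration
#'
#' 12-dof affine (template world to subject world) maximizing intensity
#' similarity by sum-of-squared-differences Gauss-Newton on smoothed volumes,
#' coarse to fine, initialized by intensity centre-of-mass alignment. Used as
#' the initialization stage of the atlas registration that maps the face
#' class into subject space.
#'
#' @param subject,template `ng_volume` objects with overlapping world
#'   fields of view.
#' @param levels List of pyramid levels, each `c(factor, sigma_vox, iters)`.
#' @return 4x4 affine matrix mapping template world mm to subject world mm,
#'   with a `"diagnostics"` attribute (per-level SSD trace).
#' @export
affine_register <- function(subject, template,
                            levels = list(c(2, 2, 25), c(1, 1, 10))) {
  if (sd(subject$data) == 0 || sd(template$data) == 0)
    stop("all-constant image: registration undefined")

  com <- function(v) {
    w <- pmax(v$data, 0)
    if (sum(w) == 0) stop("no positive intensities: no usable overlap")
    colSums(grid_world(v) * as.vector(w)) / sum(w)
  }
  theta <- c(as.vector(diag(3)), com(subject) - com(template))

  diagnostics <- list()
  for (lev in levels) {
    f <- lev[1]; sg <- lev[2]; iters <- lev[3]
    Tl <- downsample_volume(template, f)
    Tl$data <- smooth3d(Tl$data, sg / f)
    Sl <- subject
    Sl$data <- smooth3d(Sl$data, sg)
    voxS <- voxel_size(Sl)
    G <- gradient3d(Sl$data, voxS)
    Gv <- lapply(G, function(g) ng_volume(g, Sl$affine))

    x <- grid_world(Tl)
    tv <- as.vector(Tl$data)
    ssd_of <- function(th) {
      A <- matrix(th[1:9], 3, 3)
      y <- x %*% t(A) + matrix(th[10:12], nrow(x), 3, byrow = TRUE)
      r <- sample_volume(Sl, y) - tv
      sum(r^2)
    }
    trace <- ssd_of(theta)
    for (it in seq_len(iters)) {
      A <- matrix(theta[1:9], 3, 3)
      y <- x %*% t(A) + matrix(theta[10:12], nrow(x), 3, byrow = TRUE)
      sv <- sample_volume(Sl, y)
      r <- sv - tv
      g1 <- sample_volume(Gv[[1]], y)
      g2 <- sample_volume(Gv[[2]], y)
      g3 <- sample_volume(Gv[[3]], y)
      # J columns: dS/dA_jk = g_j * x_k (A stored column-major), then dS/dt_j
      J <- cbind(g1 * x[, 1], g2 * x[, 1], g3 * x[, 1],
                 g1 * x[, 2], g2 * x[, 2], g3 * x[, 2],
                 g1 * x[, 3], g2 * x[, 3], g3 * x[, 3],
                 g1, g2, g3)
      H <- crossprod(J)
      b <- crossprod(J, r)
      delta <- tryCatch(solve(H + diag(1e-8 * max(diag(H)), 12), -b),
                        error = function(e) NULL)
      if (is.null(delta)) break
      cur <- trace[length(trace)]
      step <- 1
      improved <- FALSE
      for (k in 1:6) {
        cand <- theta + step * as.vector(delta)
        val <- ssd_of(cand)
        if (val < cur) {
          theta <- cand
          trace <- c(trace, val)
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved) break
      if (length(trace) > 2 &&
          (trace[length(trace) - 1] - trace[length(trace)]) <
            1e-6 * trace[1]) break
    }
    diagnostics[[length(diagnostics) + 1]] <-
      list(factor = f, ssd = trace)
  }
  out <- diag(4)
  out[1:3, 1:3] <- matrix(theta[1:9], 3, 3)
  out[1:3, 4] <- theta[10:12]
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Nonlinear (demons-style) registration to the template
#'
#' Multi-resolution small-deformation intensity registration: the
#' displacement field (template to subject, mm) is updated by normalized
#' demons forces with per-step magnitude capping and Gaussian (fluid +
#' diffusion) smoothing regularization, coarse to fine on the template grid.
#' Returns the field together with its numerical inverse.
#'
#' @param subject,template `ng_volume` objects.
#' @param init_affine 4x4 template-world-to-subject-world affine (e.g. from
#'   [affine_register()]); identity if `NULL`.
#' @param factors Integer downsampling factors, coarse to fine (last must
#'   be 1).
#' @param iters Demons iterations per level.
#' @param sigma_fluid_vox,sigma_diffusion_vox Gaussian regularization (in
#'   level voxels) of the update and of the accumulated field.
#' @return An `ng_defield` (template grid) with a `"diagnostics"` attribute
#'   holding the per-level mean-squared-difference traces.
#' @export
nonlinear_register <- function(subject, template, init_affine = NULL,
                               factors = c(4L, 2L, 1L),
                               iters = c(40L, 25L, 15L),
                               sigma_fluid_vox = 1.0,
                               sigma_diffusion_vox = 1.5) {
  init_affine <- init_affine %||% diag(4)
  if (sd(subject$data) == 0 || sd(template$data) == 0)
    stop("all-constant image: registration undefined")
  stopifnot(length(factors) == length(iters),
            factors[length(factors)] == 1L)

  d_prev <- NULL
  prev_ref <- NULL
  diagnostics <- list()

  for (li in seq_along(factors)) {
    f <- factors[li]
    Tl <- downsample_volume(template, f)
    Tl$data <- smooth3d(Tl$data, 0.5)
    Sl <- subject
    Sl$data <- smooth3d(Sl$data, f / 2)
    voxT <- voxel_size(Tl)
    kap <- mean(voxT)
    gT <- gradient3d(Tl$data, voxT)
    voxS <- voxel_size(Sl)
    gSv <- lapply(gradient3d(Sl$data, voxS), function(g)
      ng_volume(g, Sl$affine))

    x <- grid_world(Tl)
    n <- nrow(x)
    if (is.null(d_prev)) {
      d <- x %*% t(init_affine[1:3, 1:3]) +
        matrix(init_affine[1:3, 4], n, 3, byrow = TRUE) - x
    } else {
      # upsample previous level's field to this grid
      d <- matrix(0, n, 3)
      for (k in 1:3) {
        comp <- array(d_prev[, k], dim(prev_ref$data))
        v <- world_to_voxel(prev_ref, x)
        d[, k] <- cpp_sample_trilinear(comp, v, 0)
      }
    }

    tv <- as.vector(Tl$data)
    energy <- numeric(0)
    worse <- 0L
    dims_l <- dim(Tl$data)
    aff_part <- x %*% t(init_affine[1:3, 1:3]) +
      matrix(init_affine[1:3, 4], n, 3, byrow = TRUE) - x
    for (it in seq_len(iters[li])) {
      sw <- sample_volume(Sl, x + d)
      diff <- sw - tv
      e <- mean(diff^2)
      energy <- c(energy, e)
      if (length(energy) > 1 && e > min(energy) * 1.02) {
        worse <- worse + 1L
        if (worse >= 8L)
          stop("nonlinear registration diverging: objective increasing ",
               "persistently (level factor ", f, ", iteration ", it, ")")
      } else worse <- 0L
      if (length(energy) > 5 &&
          (energy[length(energy) - 5] - e) < 1e-5 * energy[1]) break
      # symmetric demons force: average of fixed and warped-moving gradients
      g1 <- (as.vector(gT[[1]]) + sample_volume(gSv[[1]], x + d)) / 2
      g2 <- (as.vector(gT[[2]]) + sample_volume(gSv[[2]], x + d)) / 2
      g3 <- (as.vector(gT[[3]]) + sample_volume(gSv[[3]], x + d)) / 2
      denom <- g1^2 + g2^2 + g3^2 + (diff / kap)^2
      denom[denom < 1e-12] <- Inf
      u <- cbind(-diff * g1 / denom, -diff * g2 / denom, -diff * g3 / denom)
      for (k in 1:3) {
        comp <- array(u[, k], dims_l)
        u[, k] <- as.vector(smooth3d(comp, sigma_fluid_vox))
      }
      d <- d + u
      if (sigma_diffusion_vox > 0) {
        # smooth the residual field around its affine part to avoid
        # washing out the global initialization
        for (k in 1:3) {
          comp <- array(d[, k] - aff_part[, k], dims_l)
          d[, k] <- aff_part[, k] +
            as.vector(smooth3d(comp, sigma_diffusion_vox))
        }
      }
    }
    diagnostics[[length(diagnostics) + 1]] <- list(factor = f, mse = energy)
    d_prev <- d
    prev_ref <- Tl
  }

  disp <- array(d_prev, c(dim(template$data), 3L))
  field <- deformation_field(disp, template$affine)
  attr(field, "diagnostics") <- diagnostics
  field
}

#' Warp the tissue probability map into subject space
#'
#' Samples every template TPM class at the inverse-mapped location of each
#' subject voxel (trilinear; nearest-neighbour would alias the face-class
#' threshold boundary) and renormalizes so the classes sum to one.
#'
#' @param subject `ng_volume` defining the output grid.
#' @param template An `ng_template` (its `tpm` classes are warped), or a
#'   named list of `ng_volume` probability classes on the field's grid.
#' @param field `ng_defield` mapping template space to subject space (its
#'   grid must match the TPM grid).
#' @return Named list of `ng_volume` class-probability volumes in subject
#'   space (same classes as the input TPM, including `face`).
#' @export
label_tissues <- function(subject, template, field) {
  tpm <- if (inherits(template, "ng_template")) template$tpm else template
  d0 <- dim(tpm[[1]]$data)
  if (!all(d0 == field$shape))
    stop("deformation field grid does not match the TPM grid")
  if (max(abs(tpm[[1]]$affine - field$affine)) > 1e-6)
    stop("deformation field affine does not match the TPM affine")
  y <- grid_world(subject)
  x <- apply_deformation(field, y, inverse = TRUE)
  probs <- lapply(tpm, function(v) sample_volume(v, x, outside = NA))
  # voxels mapping outside the template grid are background
  out_of_grid <- !is.finite(probs[[1]])
  probs <- lapply(probs, function(p) {
    p[out_of_grid] <- 0
    p
  })
  if ("background" %in% names(probs))
    probs$background[out_of_grid] <- 1
  tot <- Reduce(`+`, probs)
  tot[tot <= 0] <- 1
  lapply(probs, function(p)
    ng_volume(array(p / tot, dim(subject$data)), subject$affine))
}
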