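#' Cohort simulation configuration
#'
#' Default study conditions for the simulated cohort: ~100 digitized scalp
#' points plus nose points, digitizer noise of a couple of mm, larger manual
#' fiducial error, and smooth anatomical variability of a few mm around the
#' template. See the methods vignette for the rationale behind each value.
#'
#' @param n_subjects Number of phantom subjects (paired design; >= 5).
#' @param grid_shape,voxel_size_mm Template grid.
#' @param deform_amplitude_mm Peak anatomical deformation per subject.
#' @param intensity_noise_sd Intensity noise added to each phantom volume.
#' @param n_scalp,n_nose Digitized point counts.
#' @param point_noise_sd_mm,fiducial_noise_sd_mm Digitization noise.
#' @param device_rot_deg,device_trans_mm Bounds of the random device pose.
#' @param trim_threshold Face-probability removal threshold.
#' @param scalp_threshold Intensity threshold for scalp extraction.
#' @param n_init ICP restarts per coregistration.
#' @return Named list of parameters.
#' @export
cohort_config <- function(n_subjects = 30L,
                          grid_shape = c(48L, 48L, 48L),
                          voxel_size_mm = 4,
                          deform_amplitude_mm = 5,
                          intensity_noise_sd = 0.05,
                          n_scalp = 100L, n_nose = 15L,
                          point_noise_sd_mm = 2,
                          fiducial_noise_sd_mm = 3,
                          device_rot_deg = 20, device_trans_mm = 30,
                          trim_threshold = 0.10,
                          scalp_threshold = 0.35,
                          n_init = 10L) {
  as.list(environment())
}

# Warp a logical template-grid mask into subject space through a deformation
# field (trilinear on the indicator, thresholded at 0.5).
warp_template_mask <- function(mask, template_affine, subject, field) {
  v <- ng_volume(array(as.numeric(mask), dim(mask)), template_affine)
  x <- apply_deformation(field, grid_world(subject), inverse = TRUE)
  array(sample_volume(v, x) > 0.5, dim(subject$data))
}

# Atlas pipeline for one volume: affine + nonlinear registration to the
# template, returning the deformation field.
register_to_template <- function(volume, template) {
  aff <- affine_register(volume, template$volume)
  nonlinear_register(volume, template$volume, init_affine = aff)
}

#' Run the simulated coregistration / segmentation cohort experiment
#'
#' For each phantom subject: estimate the atlas deformation from the intact
#' volume; produce the Trimmed (face-class probability > threshold removed)
#' and De-faced (warped face-with-nose template mask removed) volumes;
#' re-register the anonymized volumes to the template and derive the three
#' canonical inner-skull surfaces; extract the three scalp surfaces; sample
#' digitized head points under a random device pose; and coregister the
#' points to each scalp surface with and without the anterior-inferior
#' (nose) points. The paired design is preserved: every condition uses the
#' same phantom and the same sampled points. Fully deterministic given
#' `seed`.
#'
#' @param config List from [cohort_config()].
#' @param seed Integer seed.
#' @param progress Print one line per subject.
#' @return An object of class `ng_cohort`: `table` (one row per subject x
#'   condition x nose-handling with fiducial, ground-truth and surface
#'   errors), `per_vertex` (cohort-mean per-vertex inner-skull distances for
#'   Trimmed and De-faced vs Intact), `canonical_y` (template-mesh anterior
#'   coordinate used for the anterior/posterior split), and `config`.
#' @export
run_cohort_experiment <- function(config = cohort_config(), seed = 1L,
                                  progress = FALSE) {
  if (config$n_subjects < 5L)
    stop("n_subjects must be at least 5 for paired statistics")
  template <- make_template(config$grid_shape, config$voxel_size_mm)
  n <- config$n_subjects
  seeds <- with_seed(seed, matrix(sample.int(2^30, 4L * n), nrow = n))

  rows <- list()
  pv_trim <- pv_def <- 0
  for (s in seq_len(n)) {
    phantom <- make_head_phantom(template, config$deform_amplitude_mm,
                                 config$intensity_noise_sd,
                                 seed = seeds[s, 1])
    device <- random_rigid(config$device_rot_deg, config$device_trans_mm,
                           seed = seeds[s, 2],
                           from = "mri_world", to = "device")
    pts <- sample_head_points(phantom, config$n_scalp, config$n_nose,
                              config$point_noise_sd_mm,
                              config$fiducial_noise_sd_mm,
                              device, seed = seeds[s, 3])
    T_true <- invert_transform(device)

    field_i <- register_to_template(phantom$volume, template)
    tpm_sub <- label_tissues(phantom$volume, template, field_i)
    trimmed <- trim_face(phantom$volume, tpm_sub$face,
                         config$trim_threshold)$volume
    # warped face-with-nose probability, thresholded like the trim, so the
    # de-facing comparator removes a superset of the trimmed region
    xv <- apply_deformation(field_i, grid_world(phantom$volume),
                            inverse = TRUE)
    fwn <- array(sample_volume(template$face_with_nose_prob, xv) >
                   config$trim_threshold, dim(phantom$volume$data))
    defaced <- deface_full(phantom$volume, fwn)$volume

    field_t <- register_to_template(trimmed, template)
    field_d <- register_to_template(defaced, template)
    canon <- template$canonical_inner_skull
    is_i <- warp_canonical_innerskull(canon, field_i)
    is_t <- warp_canonical_innerskull(canon, field_t)
    is_d <- warp_canonical_innerskull(canon, field_d)
    cmp <- list(
      Trimmed = list(un = compare_surfaces(is_i, is_t, align = FALSE),
                     al = compare_surfaces(is_i, is_t, align = TRUE)),
      Defaced = list(un = compare_surfaces(is_i, is_d, align = FALSE),
                     al = compare_surfaces(is_i, is_d, align = TRUE)))
    pv_trim <- pv_trim + cmp$Trimmed$un$per_vertex_distance / n
    pv_def <- pv_def + cmp$Defaced$un$per_vertex_distance / n

    vols <- list(Intact = phantom$volume, Trimmed = trimmed,
                 Defaced = defaced)
    scalps <- lapply(vols, extract_scalp,
                     intensity_threshold = config$scalp_threshold)

    hp <- subset_points(pts, !pts$labels %in% c("nasion", "lpa", "rpa"))
    for (cond in names(vols)) {
      for (nose in c("with", "without")) {
        co <- coregister_two_step(pts, phantom$fiducials_mri,
                                  scalps[[cond]],
                                  use_nose = (nose == "with"),
                                  seed = seeds[s, 4],
                                  n_init = config$n_init)
        fe <- fiducial_registration_error(co$transform, fiducial_matrix(pts),
                                          phantom$fiducials_mri)
        mapped_est <- apply_transform(co$transform, hp$points)
        mapped_true <- apply_transform(T_true, hp$points)
        gt <- mean(sqrt(rowSums((mapped_est - mapped_true)^2)))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = cond, nose_points = nose,
          fiducial_error_mm = fe, ground_truth_error_mm = gt,
          surface_error_unaligned_mm = if (cond == "Intact") 0 else
            cmp[[cond]]$un$mean_mm,
          surface_error_aligned_mm = if (cond == "Intact") 0 else
            cmp[[cond]]$al$mean_mm)
      }
    }
    if (progress)
      message(sprintf("subject %d/%d done", s, n))
  }
  structure(list(table = do.call(rbind, rows),
                 per_vertex = list(Trimmed = pv_trim, Defaced = pv_def),
                 canonical_y = template$canonical_inner_skull$vertices[, 2],
                 config = config, seed = seed),
            class = "ng_cohort")
}

#' @export
print.ng_cohort <- function(x, ...) {
  cat(sprintf("<ng_cohort> %d subjects x {Intact, Trimmed, Defaced} x {with, without} nose points\n",
              x$config$n_subjects))
  s <- cohort_summary(x)
  print(round(s$medians, 2))
  invisible(x)
}

#' Summarize a simulated cohort
#'
#' Per-condition medians of the fiducial and ground-truth coregistration
#' errors, Wilcoxon signed-rank p-values for the headline paired
#' comparisons, median inner-skull surface errors, and the
#' anterior-vs-posterior split of the per-vertex surface error.
#'
#' @param cohort An `ng_cohort`.
#' @return List with `medians` (matrix), `wilcoxon` (named p-values),
#'   `surface` (named medians), `anterior_posterior` (named means).
#' @export
cohort_summary <- function(cohort) {
  tab <- cohort$table
  key <- interaction(tab$condition, tab$nose_points)
  med <- function(var) tapply(tab[[var]], key, median)
  medians <- rbind(fiducial_error_mm = med("fiducial_error_mm"),
                   ground_truth_error_mm = med("ground_truth_error_mm"))

  pick <- function(cond, nose, var = "fiducial_error_mm") {
    sel <- tab$condition == cond & tab$nose_points == nose
    tab[[var]][sel][order(tab$subject[sel])]
  }
  wx <- function(a, b) wilcoxon_signed_rank(a, b)$p_value
  wilcoxon <- c(
    trimmed_with_vs_defaced_with =
      wx(pick("Trimmed", "with"), pick("Defaced", "with")),
    defaced_without_vs_defaced_with =
      wx(pick("Defaced", "without"), pick("Defaced", "with")),
    trimmed_with_vs_defaced_without =
      wx(pick("Trimmed", "with"), pick("Defaced", "without")),
    trimmed_with_vs_intact_with =
      wx(pick("Trimmed", "with"), pick("Intact", "with")),
    surface_trimmed_vs_defaced_unaligned =
      wx(pick("Trimmed", "with", "surface_error_unaligned_mm"),
         pick("Defaced", "with", "surface_error_unaligned_mm")),
    surface_trimmed_vs_defaced_aligned =
      wx(pick("Trimmed", "with", "surface_error_aligned_mm"),
         pick("Defaced", "with", "surface_error_aligned_mm")))

  surface <- c(
    trimmed_unaligned = median(pick("Trimmed", "with",
                                    "surface_error_unaligned_mm")),
    defaced_unaligned = median(pick("Defaced", "with",
                                    "surface_error_unaligned_mm")),
    trimmed_aligned = median(pick("Trimmed", "with",
                                  "surface_error_aligned_mm")),
    defaced_aligned = median(pick("Defaced", "with",
                                  "surface_error_aligned_mm")))

  y <- cohort$canonical_y
  qs <- stats::quantile(y, c(1 / 3, 2 / 3))
  anterior_posterior <- c(
    defaced_anterior_mm = mean(cohort$per_vertex$Defaced[y >= qs[2]]),
    defaced_posterior_mm = mean(cohort$per_vertex$Defaced[y <= qs[1]]),
    trimmed_anterior_mm = mean(cohort$per_vertex$Trimmed[y >= qs[2]]),
    trimmed_posterior_mm = mean(cohort$per_vertex$Trimmed[y <= qs[1]]))

  list(medians = medians, wilcoxon = wilcoxon, surface = surface,
       anterior_posterior = anterior_posterior)
}

#' Write a cohort table and summary to disk
#'
#' TSV table (columns fixed: subject, condition, nose_points,
#' fiducial_error_mm, ground_truth_error_mm, surface_error_unaligned_mm,
#' surface_error_aligned_mm) plus a JSON summary of medians and p-values.
#'
#' @param cohort An `ng_cohort`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @export
write_cohort <- function(cohort, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(cohort$table, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path)) {
    s <- cohort_summary(cohort)
    jsonlite::write_json(
      list(seed = cohort$seed,
           medians = as.data.frame(s$medians),
           wilcoxon_p = as.list(s$wilcoxon),
           surface_error_mm = as.list(s$surface),
           anterior_posterior_mm = as.list(s$anterior_posterior)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(cohort)
}
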