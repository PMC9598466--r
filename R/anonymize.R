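#' Face trimming: nose-preserving MRI de-identification
#'
#' Removes (sets to background 0) every voxel whose face-class probability —
#' from a tissue probability map in which the face is a separate class that
#' excludes the nose — is strictly greater than `threshold` (default 10%).
#' All other voxels are left bit-identical; grid and affine are unchanged.
#'
#' @param volume `ng_volume` to anonymize.
#' @param face_prob `ng_volume` of face-class probabilities on the same grid.
#' @param threshold Removal threshold in (0,1); strictly-greater comparison.
#' @param brain_mask,nose_mask Optional logical arrays used only for the
#'   audit counts in the report.
#' @return List with `volume` (trimmed `ng_volume`) and `report`
#'   (an `ng_anon_report`).
#' @export
trim_face <- function(volume, face_prob, threshold = 0.10,
                      brain_mask = NULL, nose_mask = NULL) {
  if (!all(dim(volume$data) == dim(face_prob$data)))
    stop("face_prob grid does not match the volume grid")
  if (max(abs(volume$affine - face_prob$affine)) > 1e-6)
    stop("face_prob affine does not match the volume affine")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be inside (0, 1)")
  p <- face_prob$data
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9)
    stop("face probabilities must lie in [0, 1]")
  removed <- p > threshold
  out <- volume$data
  out[removed] <- 0
  list(volume = ng_volume(out, volume$affine),
       report = anon_report(volume$data, out, removed, brain_mask, nose_mask))
}

#' Full de-facing comparator
#'
#' Zeroes every voxel of a face mask that *includes* the nose — the
#' comparator condition emulating conventional whole-face removal.
#'
#' @param volume `ng_volume` to anonymize.
#' @param face_mask_with_nose Logical array on the same grid.
#' @param brain_mask,nose_mask Optional logical arrays for the audit counts.
#' @return List with `volume` and `report`, as for [trim_face()].
#' @export
deface_full <- function(volume, face_mask_with_nose,
                        brain_mask = NULL, nose_mask = NULL) {
  m <- face_mask_with_nose
  if (!all(dim(volume$data) == dim(m)))
    stop("mask grid does not match the volume grid")
  m <- array(as.logical(m), dim(volume$data))
  out <- volume$data
  out[m] <- 0
  list(volume = ng_volume(out, volume$affine),
       report = anon_report(volume$data, out, m, brain_mask, nose_mask))
}

anon_report <- function(before, after, removed, brain_mask, nose_mask) {
  diff_mask <- before != after
  head_n <- sum(abs(before) > 0.05)
  structure(list(
    n_voxels_removed = sum(diff_mask),
    removed_fraction_of_head = if (head_n > 0)
      sum(diff_mask & abs(before) > 0.05) / head_n else 0,
    brain_voxels_altered = if (!is.null(brain_mask))
      sum(diff_mask & brain_mask) else NA_integer_,
    nose_voxels_altered = if (!is.null(nose_mask))
      sum(diff_mask & nose_mask) else NA_integer_),
    class = "ng_anon_report")
}

#' @export
print.ng_anon_report <- function(x, ...) {
  cat(sprintf("<anonymization report> %d voxels removed (%.2f%% of head)\n",
              x$n_voxels_removed, 100 * x$removed_fraction_of_head))
  if (!is.na(x$brain_voxels_altered))
    cat(sprintf("  brain voxels altered: %d; nose voxels altered: %d\n",
                x$brain_voxels_altered, x$nose_voxels_altered))
  invisible(x)
}
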