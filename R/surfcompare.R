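#' Warp the canonical inner-skull mesh into subject space
#'
#' Displaces every vertex of the template mesh by the interpolated
#' template-to-subject deformation; topology is unchanged, so the warped
#' surface keeps index-wise vertex correspondence with the canonical mesh.
#'
#' @param template_mesh `ng_mesh` in template world coordinates.
#' @param field `ng_defield` (template to subject).
#' @return `ng_mesh` in subject world coordinates.
#' @export
warp_canonical_innerskull <- function(template_mesh, field) {
  ng_mesh(apply_deformation(field, template_mesh$vertices, strict = TRUE),
          template_mesh$faces)
}

#' Vertex-wise comparison of corresponded surfaces
#'
#' Per-vertex Euclidean distances between two meshes with identical topology
#' (index-wise correspondence), optionally after removing the best rigid
#' transform of `mesh_b` onto `mesh_a` (corresponded least squares, i.e.
#' Procrustes without scaling) so that any residual difference reflects
#' shape rather than pose. If the least-squares pose happens not to reduce
#' the mean distance (it minimizes the sum of squares), the identity
#' alignment is kept, so the aligned mean never exceeds the unaligned mean.
#'
#' @param mesh_a,mesh_b `ng_mesh` objects with identical vertex/face counts.
#' @param align Remove the rigid pose difference first.
#' @return An object of class `ng_surface_comparison`: `per_vertex_distance`
#'   (mm), `mean_mm`, `aligned`, `alignment_transform`.
#' @export
compare_surfaces <- function(mesh_a, mesh_b, align = FALSE) {
  if (nrow(mesh_a$vertices) != nrow(mesh_b$vertices) ||
      nrow(mesh_a$faces) != nrow(mesh_b$faces) ||
      any(mesh_a$faces != mesh_b$faces))
    stop("meshes must share topology (index-wise vertex correspondence)")
  Vb <- mesh_b$vertices
  Tfit <- rigid_transform(diag(4))
  if (align) {
    cand <- fit_rigid_landmarks(Vb, mesh_a$vertices)
    Vb_cand <- apply_transform(cand, Vb)
    if (mean(sqrt(rowSums((Vb_cand - mesh_a$vertices)^2))) <=
        mean(sqrt(rowSums((Vb - mesh_a$vertices)^2)))) {
      Vb <- Vb_cand
      Tfit <- cand
    }
  }
  d <- sqrt(rowSums((mesh_a$vertices - Vb)^2))
  structure(list(per_vertex_distance = d, mean_mm = mean(d),
                 aligned = align, alignment_transform = Tfit),
            class = "ng_surface_comparison")
}

#' @export
print.ng_surface_comparison <- function(x, ...) {
  cat(sprintf("<surface comparison> mean %.4g mm over %d vertices (%s)\n",
              x$mean_mm, length(x$per_vertex_distance),
              if (x$aligned) "rigidly aligned" else "unaligned"))
  invisible(x)
}
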