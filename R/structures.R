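#' Distance-to-mask transform
#'
#' Euclidean distance (mm, voxel center to voxel center) from every voxel to
#' the nearest voxel of `mask`. Voxels inside `mask` have distance 0.
#'
#' @param mask logical matrix.
#' @param spacing_mm isotropic in-plane spacing.
#' @return numeric matrix of distances in mm.
#' @export
distance_to_mask <- function(mask, spacing_mm) {
  if (!any(mask)) wp_stop("distance_to_mask: mask is empty")
  d <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask), ncol(mask)))
  as.matrix(d) * spacing_mm
}

shell_label <- function(d_mm) {
  if (d_mm %% 10 == 0) paste0("shell_", d_mm / 10, "cm") else paste0("shell_", d_mm, "mm")
}

#' Derive conformity shells around the PTV
#'
#' A shell at nominal distance d consists of all body voxels whose Euclidean
#' distance to the PTV lies in `[d, d + voxel diagonal)` -- the one-voxel
#' band that realizes a fixed-distance contour on a discrete grid.
#'
#' @param phantom a `phantom`.
#' @param distances_mm distances in mm; defaults to the wish-list set
#'   (3 mm, 1 cm, 3 cm, 7 cm).
#' @return named list of logical masks (`shell_3mm`, `shell_1cm`, ...).
#' @export
derive_shells <- function(phantom, distances_mm = c(3, 10, 30, 70)) {
  stopifnot(inherits(phantom, "phantom"))
  if (any(distances_mm <= 0)) wp_stop("shell distances must be > 0")
  if (any(distances_mm < phantom$spacing_mm))
    wp_stop("shell distance below the voxel resolution (",
            phantom$spacing_mm, " mm)")
  dist <- distance_to_mask(phantom$masks$PTV, phantom$spacing_mm)
  band <- phantom$spacing_mm * sqrt(2)
  out <- lapply(distances_mm, function(d) {
    sh <- phantom$masks$body & dist >= d & dist < d + band
    if (!any(sh))
      message("derive_shells: shell at ", d, " mm is empty (outside the body)")
    sh
  })
  names(out) <- vapply(distances_mm, shell_label, character(1))
  out
}

#' Derive the external ring
#'
#' Ring of body voxels within 2 cm of the body surface, with the PTV dilated
#' by 4 cm subtracted. Used to cap entrance doses.
#'
#' @param phantom a `phantom`.
#' @param width_mm ring width measured inward from the surface (default 20).
#' @param ptv_margin_mm PTV dilation radius to subtract (default 40).
#' @return logical mask.
#' @export
derive_external_ring <- function(phantom, width_mm = 20, ptv_margin_mm = 40) {
  stopifnot(inherits(phantom, "phantom"))
  body <- phantom$masks$body
  # distance from each body voxel to the nearest outside-body voxel
  depth <- distance_to_mask(!body, phantom$spacing_mm)
  ptv_dist <- distance_to_mask(phantom$masks$PTV, phantom$spacing_mm)
  body & depth <= width_mm & ptv_dist > ptv_margin_mm
}

#' Derive all auxiliary structures
#'
#' Convenience wrapper building the wish-list's shell set and the external
#' ring. Shell distances below the voxel resolution of the phantom cannot be
#' represented and are skipped with a message (coarse grids then simply lack
#' the innermost conformity band).
#'
#' @param phantom a `phantom`.
#' @param distances_mm shell distances, mm.
#' @return list with `shells` (named list) and `external_ring`.
#' @export
derive_structures <- function(phantom, distances_mm = c(3, 10, 30, 70)) {
  ok <- distances_mm >= phantom$spacing_mm
  if (any(!ok))
    message("derive_structures: skipping sub-resolution shell distances: ",
            paste(distances_mm[!ok], collapse = ", "), " mm")
  list(shells = derive_shells(phantom, distances_mm[ok]),
       external_ring = derive_external_ring(phantom))
}

#' Resolve a structure name to its mask
#'
#' Looks the name up among the phantom masks and the derived structures.
#'
#' @param name structure name (e.g. `"lungs"`, `"shell_1cm"`,
#'   `"external_ring"`).
#' @param phantom a `phantom`.
#' @param derived output of [derive_structures()]; computed when `NULL`.
#' @return logical mask, or error if unknown.
#' @export
resolve_structure <- function(name, phantom, derived = NULL) {
  if (name %in% names(phantom$masks)) return(phantom$masks[[name]])
  if (is.null(derived)) derived <- derive_structures(phantom)
  if (name == "external_ring") return(derived$external_ring)
  if (name %in% names(derived$shells)) return(derived$shells[[name]])
  wp_stop("unknown structure '", name, "'")
}
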