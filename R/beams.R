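#' Candidate gantry angles for beam-angle optimization
#'
#' Enumerates the coplanar candidate arc: 140 to 40 degrees for right-sided
#' tumors and 320 to 220 degrees for left-sided tumors, traversed through the
#' tumor's side (right: via 270; left: via 90), inclusive endpoints. Angles
#' follow the IEC gantry convention: 0 = beam entering from anterior,
#' increasing toward the patient's left.
#'
#' @param laterality `"right"` or `"left"`.
#' @param spacing_deg angular spacing; must divide the 260-degree arc.
#' @param arc `"ipsilateral"` (default) traverses the arc through the tumor's
#'   side; `"contralateral"` traverses the complementary way.
#' @return numeric vector of gantry angles in `[0, 360)`, in traversal order.
#' @export
candidate_angles <- function(laterality, spacing_deg = 5, arc = c("ipsilateral", "contralateral")) {
  arc <- match.arg(arc)
  if (!is.character(laterality) || !laterality %in% c("right", "left"))
    wp_stop("unknown laterality: must be \"right\" or \"left\"")
  ends <- if (laterality == "right") c(140, 40) else c(320, 220)
  span <- (ends[2] - ends[1]) %% 360  # 260 along the increasing direction
  if (arc == "contralateral") span <- span - 360  # traverse the other way
  if (abs(span) %% spacing_deg != 0)
    wp_stop("spacing_deg = ", spacing_deg, " does not divide the ",
            abs(span), "-degree arc")
  (ends[1] + seq(0, span, by = sign(span) * spacing_deg)) %% 360
}

#' Beam geometry and dose-model parameters
#'
#' Parallel (non-divergent) beamlet model: each beamlet deposits
#' `exp(-mu * radiological depth)` along its ray, laterally spread by a
#' top-hat of the beamlet width convolved with a Gaussian penumbra. The
#' radiological depth is the water-equivalent path length from the body
#' surface, with lungs at a reduced relative density.
#'
#' @param beamlet_width_mm beamlet width on the lateral axis, mm.
#' @param penumbra_sigma_mm Gaussian penumbra sigma, mm.
#' @param mu_per_mm linear attenuation coefficient, per mm.
#' @param lung_density relative electron density of lung tissue.
#' @param margin_mm lateral margin beyond the PTV projection covered by
#'   beamlets, mm.
#' @param step_mm ray-march step for the depth integral, mm; defaults to half
#'   the voxel spacing at influence computation time when `NULL`.
#' @return a `beam_geometry` list.
#' @export
beam_geometry <- function(beamlet_width_mm = 5, penumbra_sigma_mm = 3,
                          mu_per_mm = 0.004, lung_density = 0.25,
                          margin_mm = 8, step_mm = NULL) {
  if (beamlet_width_mm <= 0) wp_stop("beamlet_width_mm must be > 0")
  structure(list(beamlet_width_mm = beamlet_width_mm,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 mu_per_mm = mu_per_mm, lung_density = lung_density,
                 margin_mm = margin_mm, step_mm = step_mm),
            class = "beam_geometry")
}

# relative electron density grid: body = 1, lungs reduced, solid tumor = 1
density_grid <- function(phantom, geometry) {
  dens <- phantom$masks$body * 1
  dens[phantom$masks$lungs] <- geometry$lung_density
  dens[phantom$masks$PTV] <- 1
  dens
}

# radiological depth (mm water-equivalent) of each body voxel for one gantry
# angle, by midpoint-rule marching from the voxel toward the source
radiological_depth <- function(phantom, dens, angle_deg, step_mm) {
  grid <- phantom$grid
  sp <- phantom$spacing_mm
  coords <- voxel_coords(grid, sp)
  th <- angle_deg * pi / 180
  dir <- c(-sin(th), cos(th))  # beam travel direction (unit)
  idx <- which(phantom$masks$body)
  px <- coords$X[idx]
  py <- coords$Y[idx]
  L <- sqrt(sum((grid * sp)^2)) + 2 * sp
  K <- ceiling(L / step_mm)
  depth <- numeric(length(idx))
  for (k in seq_len(K)) {
    s <- (k - 0.5) * step_mm
    qx <- px - s * dir[1]
    qy <- py - s * dir[2]
    i <- round(qx / sp + (grid[1] + 1) / 2)
    j <- round(qy / sp + (grid[2] + 1) / 2)
    ok <- i >= 1 & i <= grid[1] & j >= 1 & j <= grid[2]
    if (any(ok)) depth[ok] <- depth[ok] + dens[cbind(i[ok], j[ok])] * step_mm
  }
  list(idx = idx, depth = depth, lateral = px * cos(th) + py * sin(th))
}

#' Compute the beamlet dose influence matrix
#'
#' Ray-traces every beamlet of every beam through the phantom and assembles
#' the sparse voxels-by-beamlets transfer matrix (Gy per unit fluence). For
#' each beam, beamlets span the PTV projection on the lateral axis plus a
#' margin. Dose to a voxel from a beamlet is
#' `exp(-mu * depth) * (pnorm((l + w/2)/sigma) - pnorm((l - w/2)/sigma))`
#' with `l` the lateral distance from the beamlet axis; contributions beyond
#' `w/2 + 4 sigma` are truncated to keep the matrix sparse. Only body voxels
#' receive dose.
#'
#' @param phantom a `phantom`.
#' @param angles distinct gantry angles, degrees.
#' @param geometry a [beam_geometry()].
#' @return object of class `influence_matrix`: list with `matrix`
#'   (dgCMatrix, `prod(grid)` rows), `angles`, `beamlet_beam` (beam index per
#'   column), `beamlet_lateral_mm`, `geometry`, `grid`, `spacing_mm`.
#' @export
compute_influence <- function(phantom, angles, geometry = beam_geometry()) {
  stopifnot(inherits(phantom, "phantom"))
  if (anyDuplicated(angles)) wp_stop("beam angles must be distinct")
  validate_phantom(phantom)
  step <- geometry$step_mm %||% (phantom$spacing_mm / 2)
  dens <- density_grid(phantom, geometry)
  coords <- voxel_coords(phantom$grid, phantom$spacing_mm)
  ptv_idx <- which(phantom$masks$PTV)

  w <- geometry$beamlet_width_mm
  sig <- geometry$penumbra_sigma_mm
  reach <- w / 2 + 4 * sig

  trip_i <- list(); trip_j <- list(); trip_x <- list()
  beam_of <- integer(0); lat_of <- numeric(0); col0 <- 0L
  for (bi in seq_along(angles)) {
    ang <- angles[bi]
    th <- ang * pi / 180
    rd <- radiological_depth(phantom, dens, ang, step)
    if (!any(rd$depth > 0))
      wp_stop("beam at gantry angle ", ang, " misses the body entirely")
    att <- exp(-geometry$mu_per_mm * rd$depth)
    lptv <- coords$X[ptv_idx] * cos(th) + coords$Y[ptv_idx] * sin(th)
    lmin <- min(lptv) - geometry$margin_mm
    lmax <- max(lptv) + geometry$margin_mm
    nb <- max(1L, as.integer(ceiling((lmax - lmin) / w)))
    centers <- (lmin + lmax) / 2 + (seq_len(nb) - (nb + 1) / 2) * w
    for (ci in seq_len(nb)) {
      l <- rd$lateral - centers[ci]
      keep <- abs(l) <= reach
      if (!any(keep)) next
      prof <- pnorm((l[keep] + w / 2) / sig) - pnorm((l[keep] - w / 2) / sig)
      trip_i[[length(trip_i) + 1L]] <- rd$idx[keep]
      trip_j[[length(trip_j) + 1L]] <- rep.int(col0 + ci, sum(keep))
      trip_x[[length(trip_x) + 1L]] <- att[keep] * prof
    }
    beam_of <- c(beam_of, rep.int(bi, nb))
    lat_of <- c(lat_of, centers)
    col0 <- col0 + nb
  }
  M <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(prod(phantom$grid), col0))
  structure(list(matrix = M, angles = angles, beamlet_beam = beam_of,
                 beamlet_lateral_mm = lat_of, geometry = geometry,
                 grid = phantom$grid, spacing_mm = phantom$spacing_mm),
            class = "influence_matrix")
}

#' Subset an influence matrix to a set of beams
#'
#' @param influence an `influence_matrix`.
#' @param beams beam indices (into `influence$angles`) to keep.
#' @return an `influence_matrix` restricted to those beams' beamlets.
#' @export
subset_influence <- function(influence, beams) {
  keep <- influence$beamlet_beam %in% beams
  bmap <- match(influence$beamlet_beam[keep], beams)
  structure(list(matrix = influence$matrix[, keep, drop = FALSE],
                 angles = influence$angles[beams],
                 beamlet_beam = bmap,
                 beamlet_lateral_mm = influence$beamlet_lateral_mm[keep],
                 geometry = influence$geometry, grid = influence$grid,
                 spacing_mm = influence$spacing_mm),
            class = "influence_matrix")
}

#' Dose from a fluence vector
#'
#' `dose = influence %*% fluence`; linear in the fluence.
#'
#' @param influence an `influence_matrix`.
#' @param fluence nonnegative vector, one entry per beamlet.
#' @return numeric dose vector (Gy), one entry per grid voxel.
#' @export
compute_dose <- function(influence, fluence) {
  stopifnot(inherits(influence, "influence_matrix"))
  if (length(fluence) != ncol(influence$matrix))
    wp_stop("fluence length ", length(fluence), " != ", ncol(influence$matrix),
            " beamlets")
  if (any(fluence < 0)) wp_stop("fluence must be nonnegative")
  as.numeric(influence$matrix %*% fluence)
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat("influence_matrix: ", nrow(x$matrix), " voxels x ", ncol(x$matrix),
      " beamlets, ", length(x$angles), " beams (",
      paste(round(x$angles), collapse = ", "), " deg), nnz = ",
      length(x$matrix@x), "\n", sep = "")
  invisible(x)
}
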