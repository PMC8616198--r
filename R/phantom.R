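#' Phantom configuration
#'
#' Builds the geometry configuration for [generate_phantom()]. The default
#' layout is a schematic axial thorax cross-section for locally advanced lung
#' cancer planning studies: an elliptical body, two lateral lungs, a
#' mediastinal heart shifted toward the patient's left, a posterior midline
#' esophagus and a posterior spinal canal, plus a planning target volume (PTV)
#' centered in the ipsilateral lung/mediastinum region. All sizes are in mm.
#'
#' Per-seed jitter (organ centers and sizes) emulates inter-patient anatomical
#' variation; setting `jitter_pos_mm = 0` and `jitter_size_frac = 0` gives the
#' nominal geometry.
#'
#' @param grid integer vector of length 2 (or 3 with a trailing 1 for a
#'   thin-3D slab): number of voxels along x (patient right to left) and y
#'   (anterior to posterior).
#' @param spacing_mm in-plane voxel spacing, mm (isotropic).
#' @param laterality `"right"` or `"left"`: side of the tumor.
#' @param prescription_Gy prescribed dose D_p; one of 60, 66, 70 Gy.
#' @param tumor_center_mm PTV center (x, y) in mm for a *right*-sided tumor;
#'   mirrored in x for left-sided tumors. Defaults to the ipsilateral
#'   lung/mediastinum border.
#' @param tumor_radius_mm PTV radius, mm.
#' @param body_semiaxes_mm body ellipse semi-axes (x, y), mm.
#' @param lung_semiaxes_mm lung ellipse semi-axes (x, y), mm.
#' @param lung_offset_mm distance of each lung center from the midline, mm.
#' @param heart_center_mm,heart_semiaxes_mm heart ellipse (for a right-sided
#'   tumor; the heart is not mirrored -- it sits left of midline regardless).
#' @param esophagus_center_mm,esophagus_radius_mm esophagus disk.
#' @param canal_center_mm,canal_radius_mm spinal canal disk.
#' @param brachial_plexus optional list(center_mm=, radius_mm=); `NULL` (the
#'   default) omits the structure, which downstream constraint checks treat
#'   as "not relevant".
#' @param jitter_pos_mm standard deviation of the seeded jitter applied to
#'   organ centers, mm.
#' @param jitter_size_frac standard deviation of the seeded multiplicative
#'   jitter applied to organ sizes (fraction).
#' @param anatomy_scale global scale factor applied to all anatomical sizes
#'   and positions (patient habitus; also convenient for compact study
#'   grids).
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(grid = c(64L, 64L),
                           spacing_mm = 4,
                           laterality = c("right", "left"),
                           prescription_Gy = 66,
                           tumor_center_mm = c(-35, -8),
                           tumor_radius_mm = 24,
                           body_semiaxes_mm = c(115, 88),
                           lung_semiaxes_mm = c(45, 66),
                           lung_offset_mm = 56,
                           heart_center_mm = c(14, 6),
                           heart_semiaxes_mm = c(34, 30),
                           esophagus_center_mm = c(4, 30),
                           esophagus_radius_mm = 6,
                           canal_center_mm = c(0, 62),
                           canal_radius_mm = 7,
                           brachial_plexus = NULL,
                           jitter_pos_mm = 3,
                           jitter_size_frac = 0.05,
                           anatomy_scale = 1) {
  laterality <- match.arg(laterality)
  if (anatomy_scale <= 0) wp_config_error("anatomy_scale must be > 0")
  for (nm in c("tumor_center_mm", "tumor_radius_mm", "body_semiaxes_mm",
               "lung_semiaxes_mm", "lung_offset_mm", "heart_center_mm",
               "heart_semiaxes_mm", "esophagus_center_mm",
               "esophagus_radius_mm", "canal_center_mm", "canal_radius_mm",
               "jitter_pos_mm"))
    assign(nm, get(nm) * anatomy_scale)
  if (!is.null(brachial_plexus))
    brachial_plexus <- lapply(brachial_plexus, function(v) v * anatomy_scale)
  grid <- as.integer(grid)
  if (length(grid) == 3L) {
    if (grid[3L] != 1L) wp_config_error("only thin-3D grids (third dim = 1) are supported")
    grid <- grid[1:2]
  }
  if (length(grid) != 2L || any(grid < 8L))
    wp_config_error("grid must have 2 (or thin-3D) dims with at least 8 voxels each")
  if (spacing_mm <= 0) wp_config_error("spacing_mm must be > 0")
  if (!prescription_Gy %in% c(60, 66, 70))
    wp_config_error("prescription_Gy must be one of 60, 66, 70")
  structure(list(
    grid = grid, spacing_mm = spacing_mm, laterality = laterality,
    prescription_Gy = prescription_Gy,
    tumor_center_mm = tumor_center_mm, tumor_radius_mm = tumor_radius_mm,
    body_semiaxes_mm = body_semiaxes_mm,
    lung_semiaxes_mm = lung_semiaxes_mm, lung_offset_mm = lung_offset_mm,
    heart_center_mm = heart_center_mm, heart_semiaxes_mm = heart_semiaxes_mm,
    esophagus_center_mm = esophagus_center_mm, esophagus_radius_mm = esophagus_radius_mm,
    canal_center_mm = canal_center_mm, canal_radius_mm = canal_radius_mm,
    brachial_plexus = brachial_plexus,
    jitter_pos_mm = jitter_pos_mm, jitter_size_frac = jitter_size_frac
  ), class = "phantom_config")
}

# voxel center coordinates (mm), grid centered on the isocenter;
# x increases toward patient left, y increases posteriorly
voxel_coords <- function(grid, spacing_mm) {
  x <- (seq_len(grid[1]) - (grid[1] + 1) / 2) * spacing_mm
  y <- (seq_len(grid[2]) - (grid[2] + 1) / 2) * spacing_mm
  list(x = x, y = y,
       X = matrix(rep(x, times = grid[2]), grid[1], grid[2]),
       Y = matrix(rep(y, each = grid[1]), grid[1], grid[2]))
}

ellipse_mask <- function(coords, center, semiaxes) {
  ((coords$X - center[1]) / semiaxes[1])^2 +
    ((coords$Y - center[2]) / semiaxes[2])^2 <= 1
}

#' Generate a seeded synthetic thorax phantom
#'
#' Produces a voxelized axial cross-section with boolean masks for the body,
#' PTV, lungs, heart, esophagus and spinal canal (optionally a brachial
#' plexus). Organ positions and sizes are jittered deterministically from the
#' seed; identical `(config, seed)` pairs give bit-identical phantoms.
#'
#' Mask conventions: every non-body mask is a subset of the body; the PTV
#' never intersects the spinal canal (the canal is carved out, emulating the
#' clinical practice of not letting target dose prescriptions overlap the
#' cord); for a left-sided configuration the whole geometry except heart,
#' esophagus and canal is mirrored about the midline.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed fixing all jitter.
#' @return an object of class `phantom`: list with `masks` (named list of
#'   logical matrices), `grid`, `spacing_mm`, `laterality`,
#'   `prescription_Gy`, `config`, `seed`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  coords <- voxel_coords(cfg$grid, cfg$spacing_mm)

  # all jitter from one local RNG stream; the global RNG state is restored
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  jp <- function() rnorm(2, 0, cfg$jitter_pos_mm)
  js <- function() exp(rnorm(1, 0, cfg$jitter_size_frac))

  mirror <- if (cfg$laterality == "left") -1 else 1

  body <- ellipse_mask(coords, c(0, 0), cfg$body_semiaxes_mm * js())
  lung_r <- ellipse_mask(coords, c(-cfg$lung_offset_mm, 0) + jp(),
                         cfg$lung_semiaxes_mm * js())
  lung_l <- ellipse_mask(coords, c(cfg$lung_offset_mm, 0) + jp(),
                         cfg$lung_semiaxes_mm * js())
  heart <- ellipse_mask(coords, cfg$heart_center_mm + jp(), cfg$heart_semiaxes_mm * js())
  eso <- ellipse_mask(coords, cfg$esophagus_center_mm + jp(),
                      rep(cfg$esophagus_radius_mm * js(), 2))
  canal <- ellipse_mask(coords, cfg$canal_center_mm + jp() * 0.3,
                        rep(cfg$canal_radius_mm, 2))
  tc <- cfg$tumor_center_mm + jp()
  tc[1] <- mirror * tc[1]
  tr <- cfg$tumor_radius_mm * js()
  ptv <- ellipse_mask(coords, tc, rep(tr, 2))
  plexus <- NULL
  if (!is.null(cfg$brachial_plexus)) {
    bp <- cfg$brachial_plexus
    pc <- bp$center_mm + jp()
    pc[1] <- mirror * pc[1]
    plexus <- ellipse_mask(coords, pc, rep(bp$radius_mm, 2))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv()))

  if (cfg$laterality == "left") { tmp <- lung_r; lung_r <- lung_l; lung_l <- tmp }
  lungs <- lung_r | lung_l

  # geometric feasibility before carving
  if (cfg$tumor_radius_mm >= min(cfg$body_semiaxes_mm))
    wp_config_error("tumor radius exceeds the body: radius ",
                    cfg$tumor_radius_mm, " mm vs body semi-axes ",
                    paste(cfg$body_semiaxes_mm, collapse = "x"), " mm")

  # containment and exclusivity
  clip <- function(m) m & body
  # on coarse grids a small organ can fall between voxel centers; keep at
  # least the voxel nearest its center
  ensure_voxel <- function(m, center) {
    if (any(m)) return(m)
    i <- which.min(abs(coords$x - center[1]))
    j <- which.min(abs(coords$y - center[2]))
    if (body[i, j]) m[i, j] <- TRUE
    m
  }
  eso <- ensure_voxel(eso, cfg$esophagus_center_mm)
  canal <- ensure_voxel(canal, cfg$canal_center_mm)
  heart <- ensure_voxel(heart, cfg$heart_center_mm)
  ptv <- clip(ptv)
  # lungs are evaluated minus the target volume, the standard delineation
  # for lung dose reporting in lung-cancer planning
  lungs <- clip(lungs) & !heart & !eso & !canal & !ptv
  heart <- clip(heart)
  eso <- clip(eso) & !canal
  canal <- clip(canal)
  ptv <- ptv & !canal
  if (!is.null(plexus)) plexus <- clip(plexus)

  if (!any(ptv)) wp_config_error("PTV is empty: tumor lies outside the body grid")
  masks <- list(body = body, PTV = ptv, lungs = lungs, heart = heart,
                esophagus = eso, spinal_canal = canal)
  if (!is.null(plexus)) masks$brachial_plexus <- plexus

  ph <- structure(list(masks = masks, grid = cfg$grid, spacing_mm = cfg$spacing_mm,
                       laterality = cfg$laterality,
                       prescription_Gy = cfg$prescription_Gy,
                       config = cfg, seed = as.integer(seed)),
                  class = "phantom")
  validate_phantom(ph)
  ph
}

#' Validate phantom invariants
#'
#' Checks that every non-body mask is contained in the body, that the PTV is
#' nonempty and disjoint from the spinal canal, that the body is simply
#' connected, and that the stated laterality matches the PTV centroid side.
#'
#' @param phantom a `phantom`.
#' @return `phantom`, invisibly; errors describe the violated invariant.
#' @export
validate_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  m <- phantom$masks
  need <- c("body", "PTV", "lungs", "heart", "esophagus", "spinal_canal")
  missing <- setdiff(need, names(m))
  if (length(missing)) wp_stop("missing masks: ", paste(missing, collapse = ", "))
  for (nm in setdiff(names(m), "body"))
    if (any(m[[nm]] & !m$body)) wp_stop("mask '", nm, "' extends outside the body")
  if (!any(m$PTV)) wp_stop("PTV mask is empty")
  if (any(m$PTV & m$spinal_canal)) wp_stop("PTV intersects the spinal canal")
  if (!mask_simply_connected(m$body)) wp_stop("body mask is not simply connected")
  coords <- voxel_coords(phantom$grid, phantom$spacing_mm)
  cx <- mean(coords$X[m$PTV])
  side <- if (cx < 0) "right" else "left"
  if (side != phantom$laterality)
    wp_stop("PTV centroid lies on the ", side, " side but laterality is ",
            phantom$laterality)
  invisible(phantom)
}

# one connected foreground component and one background component (the
# background is padded so grid-edge effects cannot split it artificially)
mask_simply_connected <- function(mask) {
  lab_fg <- EBImage::bwlabel(mask * 1)
  if (max(lab_fg) != 1L) return(FALSE)
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  lab_bg <- EBImage::bwlabel((!pad) * 1)
  max(lab_bg) <= 1L
}

#' @export
print.phantom <- function(x, ...) {
  cat("phantom: ", paste(x$grid, collapse = "x"), " voxels @ ",
      x$spacing_mm, " mm, ", x$laterality, "-sided, D_p = ",
      x$prescription_Gy, " Gy\n", sep = "")
  for (nm in names(x$masks))
    cat(sprintf("  %-16s %6d voxels\n", nm, sum(x$masks[[nm]])))
  invisible(x)
}
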