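# --- file formats ---------------------------------------------------------
# Phantoms, influence matrices and plans serialize to HDF5; DVHs to CSV
# (see dvh.R); objective templates to XML (see handover.R); reports,
# stage logs and manifests to JSON.

h5_fresh <- function(path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
}

#' Write / read a phantom as HDF5
#'
#' Masks are stored as uint8 datasets under `/masks`; spacing, laterality
#' and prescription as attributes of the root group.
#'
#' @param phantom a `phantom`.
#' @param path file path.
#' @export
write_phantom_h5 <- function(phantom, path) {
  h5_fresh(path)
  rhdf5::h5createGroup(path, "masks")
  for (nm in names(phantom$masks))
    rhdf5::h5write(matrix(as.integer(phantom$masks[[nm]]),
                          nrow(phantom$masks[[nm]])),
                   path, paste0("masks/", nm))
  rhdf5::h5write(phantom$spacing_mm, path, "spacing_mm")
  rhdf5::h5write(phantom$laterality, path, "laterality")
  rhdf5::h5write(phantom$prescription_Gy, path, "prescription_Gy")
  rhdf5::h5write(as.integer(phantom$grid), path, "grid")
  rhdf5::h5write(as.integer(phantom$seed %||% NA_integer_), path, "seed")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_phantom_h5
#' @export
read_phantom_h5 <- function(path) {
  if (!file.exists(path)) wp_stop("no such file: ", path)
  grid <- as.integer(rhdf5::h5read(path, "grid"))
  mask_names <- rhdf5::h5ls(path)
  mask_names <- mask_names$name[mask_names$group == "/masks"]
  masks <- lapply(mask_names, function(nm) {
    m <- rhdf5::h5read(path, paste0("masks/", nm))
    matrix(as.logical(m), grid[1], grid[2])
  })
  names(masks) <- mask_names
  # keep canonical ordering: body first
  ord <- c(intersect(c("body", "PTV", "lungs", "heart", "esophagus",
                       "spinal_canal", "brachial_plexus"), names(masks)),
           setdiff(names(masks), c("body", "PTV", "lungs", "heart",
                                   "esophagus", "spinal_canal",
                                   "brachial_plexus")))
  masks <- masks[ord]
  ph <- structure(list(masks = masks, grid = grid,
                       spacing_mm = as.numeric(rhdf5::h5read(path, "spacing_mm")),
                       laterality = as.character(rhdf5::h5read(path, "laterality")),
                       prescription_Gy = as.numeric(rhdf5::h5read(path, "prescription_Gy")),
                       config = NULL,
                       seed = as.integer(rhdf5::h5read(path, "seed"))),
                  class = "phantom")
  rhdf5::h5closeAll()
  validate_phantom(ph)
  ph
}

#' Write / read an influence matrix as HDF5
#'
#' Sparse triplet datasets (`i`, `j`, `x`, 1-based) plus dimensions, beam
#' angles, beamlet-beam map and dose-model parameters.
#'
#' @param influence an `influence_matrix`.
#' @param path file path.
#' @export
write_influence_h5 <- function(influence, path) {
  h5_fresh(path)
  M <- methods::as(influence$matrix, "TsparseMatrix")
  rhdf5::h5write(M@i + 1L, path, "i")
  rhdf5::h5write(M@j + 1L, path, "j")
  rhdf5::h5write(M@x, path, "x")
  rhdf5::h5write(dim(influence$matrix), path, "dims")
  rhdf5::h5write(influence$angles, path, "angles")
  rhdf5::h5write(as.integer(influence$beamlet_beam), path, "beamlet_beam")
  rhdf5::h5write(influence$beamlet_lateral_mm, path, "beamlet_lateral_mm")
  rhdf5::h5write(as.integer(influence$grid), path, "grid")
  rhdf5::h5write(influence$spacing_mm, path, "spacing_mm")
  geo <- influence$geometry
  rhdf5::h5write(c(geo$beamlet_width_mm, geo$penumbra_sigma_mm,
                   geo$mu_per_mm, geo$lung_density, geo$margin_mm),
                 path, "geometry")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_influence_h5
#' @export
read_influence_h5 <- function(path) {
  if (!file.exists(path)) wp_stop("no such file: ", path)
  dims <- as.integer(rhdf5::h5read(path, "dims"))
  M <- Matrix::sparseMatrix(i = as.integer(rhdf5::h5read(path, "i")),
                            j = as.integer(rhdf5::h5read(path, "j")),
                            x = as.numeric(rhdf5::h5read(path, "x")),
                            dims = dims)
  geo <- as.numeric(rhdf5::h5read(path, "geometry"))
  out <- structure(list(matrix = M,
                        angles = as.numeric(rhdf5::h5read(path, "angles")),
                        beamlet_beam = as.integer(rhdf5::h5read(path, "beamlet_beam")),
                        beamlet_lateral_mm = as.numeric(rhdf5::h5read(path, "beamlet_lateral_mm")),
                        geometry = beam_geometry(geo[1], geo[2], geo[3], geo[4], geo[5]),
                        grid = as.integer(rhdf5::h5read(path, "grid")),
                        spacing_mm = as.numeric(rhdf5::h5read(path, "spacing_mm"))),
                   class = "influence_matrix")
  rhdf5::h5closeAll()
  out
}

#' Write / read a fluence plan as HDF5
#'
#' @param plan a `fluence_plan`.
#' @param path file path.
#' @export
write_plan_h5 <- function(plan, path) {
  h5_fresh(path)
  rhdf5::h5write(plan$angles, path, "angles")
  rhdf5::h5write(plan$fluence, path, "fluence")
  rhdf5::h5write(plan$dose, path, "dose")
  rhdf5::h5write(as.integer(isTRUE(plan$normalized)), path, "normalized")
  rhdf5::h5write(plan$D_p %||% NA_real_, path, "D_p")
  if (!is.null(plan$achieved)) rhdf5::h5write(plan$achieved, path, "achieved")
  if (!is.null(plan$stage_log))
    rhdf5::h5write(as.character(jsonlite::toJSON(plan$stage_log, digits = NA)),
                   path, "stage_log_json")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_plan_h5
#' @export
read_plan_h5 <- function(path) {
  if (!file.exists(path)) wp_stop("no such file: ", path)
  ls_ <- rhdf5::h5ls(path)$name
  plan <- structure(list(
    angles = as.numeric(rhdf5::h5read(path, "angles")),
    fluence = as.numeric(rhdf5::h5read(path, "fluence")),
    dose = as.numeric(rhdf5::h5read(path, "dose")),
    normalized = as.integer(rhdf5::h5read(path, "normalized")) == 1L,
    achieved = if ("achieved" %in% ls_) as.numeric(rhdf5::h5read(path, "achieved")),
    stage_log = if ("stage_log_json" %in% ls_)
      jsonlite::fromJSON(as.character(rhdf5::h5read(path, "stage_log_json"))),
    D_p = as.numeric(rhdf5::h5read(path, "D_p"))), class = "fluence_plan")
  rhdf5::h5closeAll()
  plan
}

#' Write a constraint report as JSON
#'
#' @param report a `constraint_report` (or the data.frame from
#'   [verify_hard_constraints()]).
#' @param path file path.
#' @export
write_constraint_report_json <- function(report, path) {
  jsonlite::write_json(list(rows = as.data.frame(report),
                            overall_pass = attr(report, "overall_pass")),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# content hash of an R object (dose vectors, masks, ...), independent of
# file-format metadata
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}
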