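# --- end-to-end pipeline driver -------------------------------------------

#' Run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. The
#' defaults reproduce the 6-beam arm with beam-angle optimization on a
#' compact study phantom.
#'
#' @param phantom a [phantom_config()].
#' @param seed phantom / pipeline seed.
#' @param candidate_spacing_deg candidate-arc spacing for BAO, degrees.
#' @param n_beams beam counts to plan (one greedy trajectory; default 6).
#' @param bao `TRUE` to optimize beam angles, `FALSE` to use `fixed_angles`.
#' @param fixed_angles gantry angles for the no-BAO arm; defaults to the
#'   laterality-matched [template_angles()].
#' @param geometry a [beam_geometry()].
#' @param relaxation_factor wish-list relaxation factor.
#' @param score_control,final_control solver controls (see [greedy_bao()]).
#' @param handover `TRUE` to run the template handover and surrogate
#'   re-optimization stage.
#' @param output_dir directory for all artifacts.
#' @return a validated `run_config` list.
#' @export
run_config <- function(phantom = phantom_config(grid = c(40, 40), spacing_mm = 6,
                                                anatomy_scale = 0.9),
                       seed = 1L,
                       candidate_spacing_deg = 20,
                       n_beams = 6,
                       bao = TRUE,
                       fixed_angles = NULL,
                       geometry = beam_geometry(beamlet_width_mm = 6),
                       relaxation_factor = 1.03,
                       score_control = stage_control(gap_tol = 1e-5, mu = 100),
                       final_control = stage_control(),
                       handover = TRUE,
                       output_dir = tempfile("wishplan_run_")) {
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(geometry, "beam_geometry"))
  if (!is.numeric(n_beams) || any(n_beams < 1))
    wp_config_error("n_beams must be positive")
  if (!isTRUE(bao) && !isFALSE(bao)) wp_config_error("bao must be TRUE/FALSE")
  if (isFALSE(bao) && length(n_beams) > 1)
    wp_config_error("beam-count studies require bao = TRUE")
  structure(list(phantom = phantom, seed = as.integer(seed),
                 candidate_spacing_deg = candidate_spacing_deg,
                 n_beams = as.integer(n_beams), bao = bao,
                 fixed_angles = fixed_angles, geometry = geometry,
                 relaxation_factor = relaxation_factor,
                 score_control = score_control, final_control = final_control,
                 handover = handover, output_dir = output_dir),
            class = "run_config")
}

#' Run the full planning pipeline
#'
#' phantom generation -> candidate angles -> influence matrix -> beam-angle
#' optimized (or fixed-angle) two-round lexicographic fluence optimization ->
#' normalization and constraint audits -> DVH export -> objective-template
#' handover -> surrogate re-optimization. All artifacts are written under
#' `config$output_dir` together with a manifest of content hashes; re-running
#' the same configuration reproduces identical hashes.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `output_dir`, `phantom`, `plan`
#'   (normalized), `plans_by_count`, `final_plan` (surrogate, when handover
#'   is on), `audit`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)

  phantom <- generate_phantom(config$phantom, config$seed)
  write_phantom_h5(phantom, out("phantom.h5"))
  derived <- derive_structures(phantom)
  wishlist <- build_wishlist(phantom$prescription_Gy,
                             relaxation_factor = config$relaxation_factor)
  write_wishlist_yaml(wishlist, out("wishlist.yaml"))

  plans_by_count <- NULL
  bao_res <- NULL
  if (config$bao) {
    cands <- candidate_angles(phantom$laterality, config$candidate_spacing_deg)
    influence <- compute_influence(phantom, cands, config$geometry)
    write_influence_h5(influence, out("influence.h5"))
    bao_res <- greedy_bao(phantom, wishlist, cands, config$n_beams,
                          config$geometry,
                          score_control = config$score_control,
                          final_control = config$final_control,
                          influence = influence)
    fmo_plan <- bao_res$plan
    plans_by_count <- bao_res$plans_by_count
    jsonlite::write_json(
      list(selected_angles = bao_res$selected_angles,
           n_beams = bao_res$n_beams,
           iteration_scores = lapply(bao_res$iteration_scores, function(s)
             lapply(s, function(v) if (is.null(v)) "infeasible" else v))),
      out("bao.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    angles <- config$fixed_angles %||% template_angles(phantom$laterality)
    influence <- compute_influence(phantom, angles, config$geometry)
    write_influence_h5(influence, out("influence.h5"))
    fmo_plan <- suppressMessages(
      lexicographic_solve(influence, wishlist, phantom, derived,
                          control = config$final_control))
  }

  jsonlite::write_json(fmo_plan$stage_log, out("stage_log.json"),
                       digits = NA, pretty = TRUE)
  hard_report <- verify_hard_constraints(fmo_plan, wishlist, phantom, derived)
  write_constraint_report_json(hard_report, out("hard_constraints.json"))

  plan_n <- normalize_plan(fmo_plan, phantom)
  write_plan_h5(plan_n, out("fmo_plan.h5"))
  audit <- check_clinical_constraints(plan_n, phantom)
  write_constraint_report_json(audit, out("clinical_audit.json"))

  oars <- intersect(c("lungs", "heart", "esophagus", "spinal_canal",
                      "brachial_plexus"), names(phantom$masks))
  dvhs <- lapply(c(PTV = "PTV", setNames(oars, oars)), function(nm)
    compute_dvh(plan_n$dose, phantom$masks[[nm]], structure = nm))
  for (nm in names(dvhs)) write_dvh_csv(dvhs[[nm]], out(paste0("dvh_", nm, ".csv")))

  final_plan <- NULL
  if (isTRUE(config$handover)) {
    # influence restricted to the planned beams for the surrogate stage
    if (config$bao) {
      sel <- match(bao_res$selected_angles[seq_len(max(config$n_beams))],
                   influence$angles)
      plan_influence <- subset_influence(influence, sel)
    } else plan_influence <- influence
    template <- build_objective_template(dvhs[oars], phantom)
    write_objective_template_xml(template, out("template.xml"))
    final_plan <- surrogate_reoptimize(plan_influence, template, phantom)
    write_plan_h5(final_plan, out("final_plan.h5"))
    final_audit <- check_clinical_constraints(final_plan, phantom)
    write_constraint_report_json(final_audit, out("final_audit.json"))
    for (nm in oars)
      write_dvh_csv(compute_dvh(final_plan$dose, phantom$masks[[nm]],
                                structure = nm),
                    out(paste0("final_dvh_", nm, ".csv")))
  }

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("wishplan")),
    n_beams = config$n_beams,
    bao = config$bao,
    hashes = list(
      phantom = hash_object(phantom$masks),
      fluence = hash_object(plan_n$fluence),
      dose = hash_object(plan_n$dose),
      final_dose = if (!is.null(final_plan)) hash_object(final_plan$dose)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(output_dir = config$output_dir, phantom = phantom,
                 plan = plan_n, plans_by_count = plans_by_count,
                 final_plan = final_plan, audit = audit, manifest = manifest))
}
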