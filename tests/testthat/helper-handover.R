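# Handover fixtures shared between the handover unit tests and the
# acceptance suite.

# shared fidelity fixture: resolution fine enough that single-voxel DVH
# granularity stays below the fidelity tolerance
handover_fixture <- function(seed = 5) {
  memo(paste0("hand", seed), {
    cfg <- phantom_config(grid = c(80, 80), spacing_mm = 3,
                          esophagus_radius_mm = 17,
                          esophagus_center_mm = c(8, 24),
                          canal_radius_mm = 17, canal_center_mm = c(0, 60))
    ph <- generate_phantom(cfg, seed)
    der <- suppressMessages(derive_structures(ph))
    wl <- build_wishlist(66)
    inf <- compute_influence(ph, template_angles("right"), beam_geometry())
    plan <- normalize_plan(
      suppressMessages(lexicographic_solve(inf, wl, ph, der)), ph)
    oars <- c("lungs", "heart", "esophagus", "spinal_canal")
    dvhs <- lapply(setNames(oars, oars), function(nm)
      compute_dvh(plan$dose, ph$masks[[nm]], structure = nm))
    list(ph = ph, inf = inf, plan = plan, oars = oars, dvhs = dvhs,
         template = build_objective_template(dvhs, ph))
  })
}

# lighter fixture for structural (non-fidelity) handover tests
compact_handover_fixture <- function(seed = 3) {
  memo(paste0("handc", seed), {
    ph <- fixture_phantom(seed + 100)
    der <- suppressMessages(derive_structures(ph))
    wl <- build_wishlist(66)
    inf <- compute_influence(ph, template_angles("right"),
                             beam_geometry(beamlet_width_mm = 6))
    plan <- normalize_plan(
      suppressMessages(lexicographic_solve(inf, wl, ph, der)), ph)
    oars <- c("lungs", "heart", "esophagus", "spinal_canal")
    dvhs <- lapply(setNames(oars, oars), function(nm)
      compute_dvh(plan$dose, ph$masks[[nm]], structure = nm))
    list(ph = ph, inf = inf, plan = plan, oars = oars, dvhs = dvhs,
         template = build_objective_template(dvhs, ph))
  })
}

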