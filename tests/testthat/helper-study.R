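# Beam-count study over a seeded phantom population, shared by the BAO and
# trend acceptance checks (and mirrored by scripts/acceptance.R).
#
# For each phantom: one greedy BAO trajectory to 8 beams with 4/6/8-beam
# plans extracted along it, plus a fixed template-angle plan for the
# BAO-vs-template comparison.

beam_count_study <- function(seeds = 1:10, spacing_deg = 20) {
  memo(paste0("study_", paste(range(seeds), collapse = "_"), "_", spacing_deg), {
    geo <- beam_geometry(beamlet_width_mm = 7)
    lapply(seeds, function(seed) {
      lat <- if (seed %% 2) "right" else "left"
      ph <- generate_phantom(compact_config(lat), seed)
      wl <- build_wishlist(66)
      cands <- candidate_angles(lat, spacing_deg)
      res <- greedy_bao(ph, wl, cands, n_beams = c(4, 6, 8), geo)
      tmpl <- plan_without_bao(ph, wl, template_angles(lat), geo)
      plans <- lapply(res$plans_by_count, function(p) normalize_plan(p, ph))
      dm <- function(p, st) dose_metric(p$dose, ph$masks[[st]], "D_mean")
      list(seed = seed, phantom = ph, bao = res, template_plan = tmpl,
           plans = plans,
           heart = vapply(plans, dm, numeric(1), st = "heart"),
           esophagus = vapply(plans, dm, numeric(1), st = "esophagus"))
    })
  })
}
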