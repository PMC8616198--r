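# DVH-to-template conversion, NTO, XML round-trip, surrogate re-optimization.

test_that("line-objective sampling count and positions are exact", {
  # max dose 42.0 Gy -> 61 points at 0.7 Gy spacing
  dvh <- structure(list(dose_Gy = seq(0, 42.5, 0.1),
                        volume_pct = pmax(0, 100 - seq(0, 42.5, 0.1) * 100 / 42),
                        structure = "lungs", max_dose_Gy = 42),
                   class = "dvh")
  lo <- dvh_to_line_objectives(dvh)
  expect_length(lo$dose_Gy, 61)
  expect_equal(lo$dose_Gy, 0.7 * (0:60))
  expect_equal(lo$volume_pct[1], 100)
  expect_true(all(diff(lo$volume_pct) <= 1e-9))

  # uniform-dose step DVH: line hugs the step within one spacing
  step <- structure(list(dose_Gy = seq(0, 30.5, 0.1),
                         volume_pct = ifelse(seq(0, 30.5, 0.1) <= 30, 100, 0),
                         structure = "s", max_dose_Gy = 30),
                    class = "dvh")
  ls <- dvh_to_line_objectives(step)
  expect_equal(max(ls$dose_Gy), 30.1, tolerance = 0.35)  # first multiple >= 30
  expect_true(all(ls$volume_pct[ls$dose_Gy <= 29.4] == 100))

  # sampled volumes equal brute-force re-counting within one bin
  set.seed(12)
  d <- runif(400, 0, 55)
  dvh2 <- compute_dvh(d, rep(TRUE, 400), bin_width = 0.1, structure = "s")
  lo2 <- dvh_to_line_objectives(dvh2)
  for (k in sample(seq_along(lo2$dose_Gy), 10)) {
    brute <- 100 * mean(d >= lo2$dose_Gy[k])
    expect_lt(abs(lo2$volume_pct[k] - brute), 100 / 400 + 0.26)
  }
})

test_that("objective templates transcribe the fixed settings", {
  for (D_p in c(60, 66, 70)) {
    cfg <- default_config(D_p = D_p)
    ph <- generate_phantom(cfg, 2)
    dose <- rep(0, prod(ph$grid))
    for (nm in c("lungs", "heart", "esophagus", "spinal_canal"))
      dose[as.vector(ph$masks[[nm]])] <- runif(sum(ph$masks[[nm]]), 1, 40)
    dvhs <- lapply(setNames(c("lungs", "heart", "esophagus", "spinal_canal"),
                            c("lungs", "heart", "esophagus", "spinal_canal")),
                   function(nm) compute_dvh(dose, ph$masks[[nm]], structure = nm))
    tm <- build_objective_template(dvhs, ph)
    pts <- tm$point_objectives
    expect_equal(pts$dose_Gy[pts$structure == "PTV" & pts$type == "Min"], D_p - 0.5)
    expect_equal(pts$dose_Gy[pts$structure == "PTV" & pts$type == "Max"], D_p + 0.5)
    expect_true(all(pts$priority[pts$structure == "PTV"] == 130))
    expect_equal(pts$dose_Gy[pts$structure == "spinal_canal"], 48)
    expect_equal(pts$priority[pts$structure == "spinal_canal"], 100)
    expect_equal(tm$line_objectives$lungs$priority, 80)
    expect_equal(tm$line_objectives$heart$priority, 80)
    expect_equal(tm$line_objectives$esophagus$priority, 60)
    expect_equal(tm$line_objectives$spinal_canal$priority, 40)
    expect_equal(tm$nto,
                 list(distance_mm = 5, start_frac = 1.05, end_frac = 0.60,
                      falloff = 0.15, priority = 100))
    expect_error(build_objective_template(dvhs[-1], ph), "missing OAR")
  }
})

test_that("NTO threshold hits its anchor values and decreases", {
  expect_equal(nto_threshold(5, 66), 1.05 * 66)
  expect_equal(nto_threshold(0, 66), 1.05 * 66)  # flat inside start distance
  expect_equal(nto_threshold(1e5, 66), 0.60 * 66, tolerance = 1e-6)
  d <- seq(0, 120, 2.5)
  v <- nto_threshold(d, 70)
  expect_true(all(diff(v) <= 0))
  # closed-form midpoint
  expect_equal(nto_threshold(25, 66),
               66 * (0.6 + 0.45 * exp(-0.15 * 20)))
  expect_error(nto_threshold(-1, 66))
})

test_that("template XML round-trips all attributes", {
  ph <- fixture_phantom()
  dose <- rep(0, prod(ph$grid))
  for (nm in c("lungs", "heart", "esophagus", "spinal_canal"))
    dose[as.vector(ph$masks[[nm]])] <- runif(sum(ph$masks[[nm]]), 1, 40)
  dvhs <- lapply(setNames(c("lungs", "heart", "esophagus", "spinal_canal"),
                          c("lungs", "heart", "esophagus", "spinal_canal")),
                 function(nm) compute_dvh(dose, ph$masks[[nm]], structure = nm))
  tm <- build_objective_template(dvhs, ph)
  f <- tempfile(fileext = ".xml")
  write_objective_template_xml(tm, f)
  back <- read_objective_template_xml(f)
  expect_equal(back$D_p, tm$D_p)
  expect_equal(back$point_objectives, tm$point_objectives)
  expect_equal(back$nto, tm$nto)
  for (nm in names(tm$line_objectives)) {
    expect_equal(back$line_objectives[[nm]]$dose_Gy,
                 tm$line_objectives[[nm]]$dose_Gy)
    expect_equal(back$line_objectives[[nm]]$volume_pct,
                 tm$line_objectives[[nm]]$volume_pct, tolerance = 1e-12)
    expect_equal(back$line_objectives[[nm]]$priority,
                 tm$line_objectives[[nm]]$priority)
  }
  writeLines("<not-a-template>", f)
  expect_error(read_objective_template_xml(f), "malformed")
})

test_that("surrogate re-optimization reproduces the FMO OAR DVHs", {
  fx <- handover_fixture()
  fp <- surrogate_reoptimize(fx$inf, fx$template, fx$ph)
  for (nm in fx$oars) {
    lo <- fx$template$line_objectives[[nm]]
    dr <- fx$plan$dose[as.vector(fx$ph$masks[[nm]])]
    d <- fp$dose[as.vector(fx$ph$masks[[nm]])]
    dev <- vapply(lo$dose_Gy, function(b)
      100 * (mean(d >= b) - mean(dr >= b)), numeric(1))
    expect_lt(max(abs(dev)), 2 + 1e-9, label = paste("structure", nm))
  }
  # coverage also survives the handover
  expect_gte(100 * mean(fp$dose[as.vector(fx$ph$masks$PTV)] >= 0.95 * 66), 98)
  # residual line violations are reported, not hidden
  res <- line_objective_residuals(fp, fx$template, fx$ph)
  expect_true(all(res$excess_pct >= 0))
  expect_lt(max(res$excess_pct), 2 + 1e-9)
})

test_that("a PTV-only template constrains only the target", {
  fx <- compact_handover_fixture()
  tm <- fx$template
  tm$line_objectives <- list()
  tm$point_objectives <- tm$point_objectives[tm$point_objectives$structure == "PTV", ]
  tm$nto$priority <- 0
  fp <- surrogate_reoptimize(fx$inf, tm, fx$ph, list(maxit = 800, quick = TRUE))
  d_ptv <- fp$dose[as.vector(fx$ph$masks$PTV)]
  expect_gt(mean(d_ptv >= 65.5 - 1 & d_ptv <= 66.5 + 1), 0.95)
})

test_that("scaling all template priorities leaves the optimum unchanged", {
  # the penalty is homogeneous in the priorities; the optimum is invariant
  # up to optimizer path round-off, so the plans are compared physically
  fx <- compact_handover_fixture()
  tm2 <- fx$template
  tm2$point_objectives$priority <- tm2$point_objectives$priority * 2
  tm2$nto$priority <- tm2$nto$priority * 2
  for (nm in names(tm2$line_objectives))
    tm2$line_objectives[[nm]]$priority <- tm2$line_objectives[[nm]]$priority * 2
  ctl <- list(maxit = 1500, quick = TRUE)
  f1 <- surrogate_reoptimize(fx$inf, fx$template, fx$ph, ctl)
  f2 <- surrogate_reoptimize(fx$inf, tm2, fx$ph, ctl)
  pen <- wishplan:::surrogate_penalty(fx$inf, fx$template, fx$ph, ctl)
  v1 <- pen$fn(f1$fluence / f1$norm_factor)
  v2 <- pen$fn(f2$fluence / f2$norm_factor)
  expect_equal(v1, v2, tolerance = 0.02)
  for (nm in fx$oars)
    expect_equal(mean(f1$dose[as.vector(fx$ph$masks[[nm]])]),
                 mean(f2$dose[as.vector(fx$ph$masks[[nm]])]),
                 tolerance = 0.02, label = paste("mean dose", nm))
})

test_that("full pipeline determinism: same seed, same final plan", {
  cfg <- run_config(seed = 9, n_beams = 2, candidate_spacing_deg = 65,
                    handover = TRUE,
                    phantom = compact_config(),
                    geometry = beam_geometry(beamlet_width_mm = 7))
  r1 <- suppressMessages(run_pipeline(cfg))
  cfg2 <- cfg; cfg2$output_dir <- tempfile("wishplan_rerun_")
  r2 <- suppressMessages(run_pipeline(cfg2))
  expect_identical(r1$manifest$hashes, r2$manifest$hashes)
})
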