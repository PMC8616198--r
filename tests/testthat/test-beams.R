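test_that("candidate arcs enumerate 53 angles and mirror across the midline", {
  right <- candidate_angles("right", 5)
  left <- candidate_angles("left", 5)
  expect_length(right, 53)  # ((40 - 140) mod 360) / 5 + 1
  expect_length(left, 53)
  expect_equal(right[1], 140)
  expect_equal(right[length(right)], 40)
  expect_true(270 %in% right)  # traversed through the right side
  expect_true(90 %in% left)
  expect_setequal((360 - right) %% 360, left)
  # endpoints only at the full arc spacing
  expect_setequal(candidate_angles("right", 260), c(140, 40))
  expect_error(candidate_angles("up"), "laterality")
  expect_error(candidate_angles("right", 7), "divide")
  # the contralateral reading stays available but differs
  contra <- candidate_angles("right", 20, arc = "contralateral")
  expect_false(270 %in% contra)
})

test_that("depth dose follows exponential attenuation in homogeneous media", {
  # body-only disk (no lungs in the beam path), anterior beam
  cfg <- phantom_config(grid = c(56, 56), spacing_mm = 4,
                        body_semiaxes_mm = c(105, 105),
                        lung_semiaxes_mm = c(10, 10), lung_offset_mm = 80,
                        tumor_center_mm = c(-20, 0), tumor_radius_mm = 12,
                        jitter_pos_mm = 0, jitter_size_frac = 0)
  ph <- generate_phantom(cfg, 1)
  geo <- beam_geometry(mu_per_mm = 0.005, beamlet_width_mm = 4)
  inf <- compute_influence(ph, 0, geo)
  # dose along the central column of the beam, at increasing depth
  d <- compute_dose(inf, rep(1, ncol(inf$matrix)))
  dm <- matrix(d, ph$grid[1])
  col <- which.min(abs((seq_len(ph$grid[1]) - (ph$grid[1] + 1) / 2) * 4 + 20))
  prof <- dm[col, ]
  inside <- which(ph$masks$body[col, ])
  # ratio between voxels 200 mm apart ~ exp(-1)
  j1 <- inside[2]
  j2 <- j1 + 50  # 200 mm at 4 mm spacing
  expect_true(j2 <= max(inside))
  expect_equal(prof[j2] / prof[j1], exp(-1), tolerance = 0.03)
  # monotone non-increasing with depth in homogeneous media
  expect_true(all(diff(prof[inside]) <= 1e-9))
})

test_that("opposed beams on a symmetric phantom give a symmetric dose", {
  cfg <- phantom_config(grid = c(40, 40), spacing_mm = 5,
                        body_semiaxes_mm = c(90, 90),
                        lung_semiaxes_mm = c(22, 30), lung_offset_mm = 48,
                        tumor_center_mm = c(0, 0), tumor_radius_mm = 15,
                        heart_center_mm = c(0, 40), heart_semiaxes_mm = c(10, 8),
                        esophagus_center_mm = c(30, 30),
                        canal_center_mm = c(0, 70),
                        jitter_pos_mm = 0, jitter_size_frac = 0,
                        laterality = "left")
  cfg$tumor_center_mm <- c(1e-9, 0)  # centered target, nominally left
  ph <- generate_phantom(cfg, 1)
  inf <- compute_influence(ph, c(90, 270), beam_geometry())
  d <- matrix(compute_dose(inf, rep(1, ncol(inf$matrix))), ph$grid[1])
  # mirror about the sagittal midline: beams at 90/270 are swapped copies
  expect_equal(d, d[rev(seq_len(nrow(d))), ], tolerance = 1e-8)
})

test_that("influence matrix equals the brute-force line-integral oracle", {
  cfg <- phantom_config(grid = c(24, 24), spacing_mm = 8, anatomy_scale = 0.7,
                        jitter_pos_mm = 0, jitter_size_frac = 0)
  ph <- generate_phantom(cfg, 2)
  geo <- beam_geometry(beamlet_width_mm = 8)
  angles <- c(0, 140, 260)
  inf <- compute_influence(ph, angles, geo)
  brute <- brute_influence(ph, angles, geo)
  expect_equal(unname(as.matrix(inf$matrix)), unname(brute), tolerance = 1e-10)
})

test_that("influence errors and sparsity behave", {
  ph <- fixture_phantom()
  expect_error(compute_influence(ph, c(0, 0)), "distinct")
  inf <- fixture_influence()
  expect_true(all(inf$matrix@x >= 0))
  # no dose outside the body
  outside <- which(!as.vector(ph$masks$body))
  expect_equal(sum(abs(inf$matrix[outside, ])), 0)
})

test_that("compute_dose is linear and column-consistent", {
  inf <- fixture_influence()
  n <- ncol(inf$matrix)
  expect_equal(compute_dose(inf, rep(0, n)), rep(0, nrow(inf$matrix)))
  e3 <- replace(rep(0, n), 3, 1)
  expect_equal(compute_dose(inf, e3), as.numeric(inf$matrix[, 3]))
  set.seed(1)
  x <- runif(n); y <- runif(n); a <- 2.5; b <- 0.3
  lhs <- compute_dose(inf, a * x + b * y)
  rhs <- a * compute_dose(inf, x) + b * compute_dose(inf, y)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(compute_dose(inf, rep(-1, n)), "nonnegative")
  expect_error(compute_dose(inf, rep(1, n + 1)), "beamlets")
})
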