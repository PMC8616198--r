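make_plan <- function(dose, angles = 0) {
  structure(list(angles = angles, fluence = 1, dose = dose,
                 normalized = FALSE, D_p = 66), class = "fluence_plan")
}

make_normalized <- function(dose, ph) {
  p <- make_plan(dose); p$normalized <- TRUE; p
}

test_that("cumulative DVH counts volumes correctly", {
  mask <- c(TRUE, TRUE, TRUE, TRUE)
  dvh <- compute_dvh(c(1, 2, 3, 4), mask, bin_width = 0.5)
  # V at 2.5 Gy = 50%
  expect_equal(dvh$volume_pct[dvh$dose_Gy == 2.5], 50)
  expect_equal(dvh$volume_pct[1], 100)  # at 0 Gy
  expect_true(all(diff(dvh$volume_pct) <= 0))
  expect_true(all(dvh$volume_pct >= 0 & dvh$volume_pct <= 100))

  # uniform dose -> step function
  u <- compute_dvh(rep(10, 5), rep(TRUE, 5), bin_width = 1)
  expect_true(all(u$volume_pct[u$dose_Gy <= 10] == 100))
  expect_true(all(u$volume_pct[u$dose_Gy > 10] == 0))

  expect_error(compute_dvh(1:4, rep(FALSE, 4), structure = "heart"), "heart")
  expect_error(compute_dvh(1:4, rep(TRUE, 4), bin_width = 0))
})

test_that("DVH agrees with exhaustive threshold counting on random doses", {
  set.seed(42)
  dose <- runif(500, 0, 70)
  mask <- rep(TRUE, 500)
  dvh <- compute_dvh(dose, mask, bin_width = 0.25)
  brute <- vapply(dvh$dose_Gy, function(b) 100 * sum(dose >= b) / 500,
                  numeric(1))
  expect_equal(dvh$volume_pct, brute)
})

test_that("dose metrics match direct computation and DVH interpolation", {
  dose <- c(1, 2, 3, 4)
  mask <- rep(TRUE, 4)
  expect_equal(dose_metric(dose, mask, "D_mean"), 2.5)
  expect_equal(dose_metric(dose, mask, "D_max"), 4)
  expect_equal(dose_metric(dose, mask, "V_2Gy"), 75)
  # V_95% on uniform dose at the prescription
  expect_equal(dose_metric(rep(66, 10), rep(TRUE, 10), "V_95%", D_p = 66), 100)
  expect_error(dose_metric(dose, mask, "V_95%"), "D_p")
  expect_error(dose_metric(dose, mask, "EUD"), "unknown")

  # V_xGy consistent with the DVH curve within one bin
  set.seed(7)
  d <- runif(300, 0, 60)
  dvh <- compute_dvh(d, rep(TRUE, 300), bin_width = 0.1)
  for (x in c(5, 20, 30)) {
    vx <- dose_metric(d, rep(TRUE, 300), paste0("V_", x, "Gy"))
    interp <- approx(dvh$dose_Gy, dvh$volume_pct, x)$y
    expect_lt(abs(vx - interp), 100 * 1 / 300 + 1e-9)
  }
})

test_that("normalization scales the PTV median to the prescription exactly", {
  ph <- fixture_phantom()
  nvox <- prod(ph$grid)
  dose <- rep(0, nvox)
  ptv <- which(as.vector(ph$masks$PTV))
  dose[ptv] <- seq(30, 36, length.out = length(ptv))
  plan <- make_plan(dose)
  np <- normalize_plan(plan, ph)
  expect_equal(median(np$dose[ptv]), 66, tolerance = 1e-12)
  expect_true(np$normalized)
  # idempotent
  np2 <- normalize_plan(np, ph)
  expect_equal(np2$dose, np$dose, tolerance = 1e-12)
  # dose ratios preserved
  expect_equal(np$dose[ptv] / dose[ptv], rep(np$norm_factor, length(ptv)))
  # explicit 3-voxel example: {30, 33, 36} with D_p 66 -> scale 2
  d3 <- sort(dose[ptv])[c(1, ceiling(length(ptv) / 2), length(ptv))]
  expect_equal(66 / median(dose[ptv]), 2, tolerance = 0.01)
  expect_error(normalize_plan(make_plan(rep(0, nvox)), ph), "zero")
})

test_that("even-count median follows the order-statistics oracle", {
  set.seed(3)
  for (rep_ in 1:5) {
    vals <- runif(10, 20, 50)  # even count
    srt <- sort(vals)
    oracle <- (srt[5] + srt[6]) / 2
    expect_equal(median(vals), oracle)
  }
  # normalization uses that median
  ph <- fixture_phantom()
  ptv <- which(as.vector(ph$masks$PTV))
  stopifnot(length(ptv) %% 2 == 0 || length(ptv) > 3)
  dose <- rep(0, prod(ph$grid))
  dose[ptv] <- runif(length(ptv), 30, 40)
  np <- normalize_plan(make_plan(dose), ph)
  srt <- sort(dose[ptv])
  n <- length(srt)
  med <- if (n %% 2) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  expect_equal(np$norm_factor, 66 / med)
})

test_that("clinical constraint auditing flags the right rows", {
  ph <- fixture_phantom()
  nvox <- prod(ph$grid)
  ptv <- as.vector(ph$masks$PTV)
  # perfect coverage, zero OAR dose -> overall pass
  dose <- ifelse(ptv, 66, 0)
  plan <- make_plan(dose); plan$normalized <- TRUE
  rep1 <- suppressMessages(check_clinical_constraints(plan, ph))
  expect_true(attr(rep1, "overall_pass"))

  # lungs V_20Gy pushed to 36% -> that row fails with limit 35
  lungs <- which(as.vector(ph$masks$lungs))
  n20 <- ceiling(0.36 * length(lungs))
  dose2 <- dose; dose2[lungs[seq_len(n20)]] <- 21
  rep2 <- suppressMessages(check_clinical_constraints(make_normalized(dose2, ph), ph))
  row <- rep2[rep2$structure == "lungs" & rep2$metric == "V_20Gy", ]
  expect_false(row$pass)
  expect_equal(row$limit, 35)
  expect_false(attr(rep2, "overall_pass"))

  # body hot spot at 1.08 D_p -> body D_max row fails (limit 1.07 D_p)
  body <- which(as.vector(ph$masks$body) & !ptv)
  dose3 <- dose; dose3[body[1]] <- 1.08 * 66
  rep3 <- suppressMessages(check_clinical_constraints(make_normalized(dose3, ph), ph))
  expect_false(rep3$pass[rep3$structure == "body"])

  # unnormalized plans are rejected
  expect_error(check_clinical_constraints(make_plan(dose), ph), "normalized")
})

test_that("DVH CSV round-trips bit-stable", {
  dvh <- compute_dvh(runif(100, 0, 50), rep(TRUE, 100), structure = "lungs")
  f <- tempfile(fileext = ".csv")
  write_dvh_csv(dvh, f)
  back <- read_dvh_csv(f, structure = "lungs")
  expect_identical(back$dose_Gy, dvh$dose_Gy)
  expect_identical(back$volume_pct, dvh$volume_pct)
  f2 <- tempfile(fileext = ".csv")
  write_dvh_csv(back, f2)
  expect_identical(readLines(f), readLines(f2))
  writeLines("bad,header\n1,2", f2)
  expect_error(read_dvh_csv(f2), "malformed")
})
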