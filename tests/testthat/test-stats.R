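# Comparison statistics: Wilcoxon, population DVHs, bands, angle histograms.

test_that("small-sample Wilcoxon p-values are exact", {
  # 3 pairs, all differences positive -> two-tailed p = 2/8
  r <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$p.value, 0.25)
  expect_equal(r$method, "exact")
  # degenerate: x == y
  expect_warning(r0 <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(r0$p.value, 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:2))
})

test_that("exact Wilcoxon equals full enumeration on random vectors", {
  set.seed(99)
  for (rep_ in 1:100) {
    n <- sample(3:12, 1)
    x <- round(rnorm(n, 0, 2), 2)
    y <- round(rnorm(n, 0.3, 2), 2)
    mine <- suppressWarnings(wilcoxon_signed_rank(x, y))
    ref <- enumerate_wilcoxon(x, y)
    expect_equal(mine$statistic, ref$statistic, info = rep_)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12, info = rep_)
  }
  # tie-free cases also agree with the standard distribution
  set.seed(100)
  x <- rnorm(10); y <- rnorm(10)
  mine <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("large-sample Wilcoxon uses the tie-corrected normal approximation", {
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30, 0.8)
  mine <- wilcoxon_signed_rank(x, y)
  expect_equal(mine$method, "normal_approx")
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
})

mk_dvh <- function(vol, axis = seq(0, 10, 0.5), structure = "s") {
  structure(list(dose_Gy = axis, volume_pct = vol, structure = structure,
                 max_dose_Gy = max(axis[vol > 0], 0)), class = "dvh")
}

test_that("population DVH averaging", {
  axis <- seq(0, 10, 0.5)
  step1 <- mk_dvh(ifelse(axis <= 3, 100, 0))
  step2 <- mk_dvh(ifelse(axis <= 7, 100, 0))
  avg <- population_average_dvh(list(step1, step2))
  expect_equal(avg$volume_pct[axis > 3 & axis <= 7], rep(50, sum(axis > 3 & axis <= 7)))
  same <- population_average_dvh(list(step1, step1))
  expect_equal(same$volume_pct, step1$volume_pct)
  expect_equal(population_average_dvh(list(step1))$volume_pct, step1$volume_pct)
  expect_error(population_average_dvh(list()), "empty")
  expect_error(population_average_dvh(list(step1, mk_dvh(rep(1, 3), axis = 1:3))),
               "common dose axis")
})

test_that("paired DVH difference bands behave", {
  axis <- seq(0, 10, 0.5)
  set.seed(8)
  A <- lapply(1:6, function(i) mk_dvh(pmin(100, pmax(0, 80 - 5 * axis + rnorm(1)))))
  # identical populations: zero difference, zero-width band
  ci0 <- paired_dvh_difference_ci(A, A, seed = 2)
  expect_equal(ci0$mean_diff, rep(0, length(axis)))
  expect_equal(ci0$lower, ci0$upper)
  # constant offset: band centered at the offset
  B <- lapply(A, function(d) mk_dvh(d$volume_pct - 7))
  ci1 <- paired_dvh_difference_ci(A, B, seed = 2)
  expect_equal(ci1$mean_diff, rep(7, length(axis)))
  expect_true(all(ci1$lower <= 7 & ci1$upper >= 7))
  expect_error(paired_dvh_difference_ci(A[1], A[1]), "2 subjects")
  # seeded: reproducible
  ci2 <- paired_dvh_difference_ci(A, B, seed = 2)
  expect_identical(ci1$lower, ci2$lower)
})

test_that("bootstrap band coverage is near nominal for normal differences", {
  # subject-level curves with iid normal offsets; compare the bootstrap band
  # against the t-interval at moderate n
  axis <- c(0, 1)
  set.seed(21)
  n <- 26
  cover_boot <- 0; reps <- 60
  for (r in 1:reps) {
    offs <- rnorm(n, 1, 2)
    A <- lapply(offs, function(o) mk_dvh(c(50 + o, 50 + o), axis))
    B <- lapply(seq_len(n), function(i) mk_dvh(c(50, 50), axis))
    ci <- paired_dvh_difference_ci(A, B, n_boot = 400, seed = r)
    if (ci$lower[1] <= 1 && ci$upper[1] >= 1) cover_boot <- cover_boot + 1
  }
  # 95% nominal; Monte-Carlo tolerance at 60 replicates
  expect_gt(cover_boot / reps, 0.80)
})

test_that("beam-angle histograms round wrap-aware", {
  p1 <- structure(list(angles = c(0, 90, 180)), class = "fluence_plan")
  h1 <- beam_angle_distribution(list(p1))
  expect_equal(sum(h1$count), 3)
  expect_equal(h1$count[h1$angle_deg %in% c(0, 90, 180)], c(1, 1, 1))
  p2 <- structure(list(angles = c(182, 357.6)), class = "fluence_plan")
  h2 <- beam_angle_distribution(list(p2))
  expect_equal(h2$count[h2$angle_deg == 180], 1)
  expect_equal(h2$count[h2$angle_deg == 0], 1)  # 357.6 wraps to 0
  # conservation across many plans
  plans <- list(p1, p2)
  expect_equal(sum(beam_angle_distribution(plans)$count), 5)
})

test_that("metrics tables report paired medians, IQRs and p-values", {
  ph <- fixture_phantom()
  nvox <- prod(ph$grid)
  mk_plan <- function(dose) structure(list(angles = 0, fluence = 1, dose = dose,
                                           normalized = TRUE, D_p = 66),
                                      class = "fluence_plan")
  set.seed(31)
  plansA <- lapply(1:8, function(i) {
    d <- rep(0, nvox)
    d[as.vector(ph$masks$PTV)] <- 66
    d[as.vector(ph$masks$heart)] <- runif(1, 8, 12)
    d[as.vector(ph$masks$lungs)] <- runif(1, 10, 14)
    d[as.vector(ph$masks$esophagus)] <- runif(1, 15, 25)
    mk_plan(d)
  })
  phs <- rep(list(ph), 8)
  tabAA <- metrics_table(plansA, plansA, phs)
  expect_true(all(tabAA$p_value == 1))
  expect_true(all(tabAA$median_diff == 0))
  # constant metric -> zero IQR
  expect_equal(tabAA$iqr_A[tabAA$structure == "PTV"], 0)

  # halved heart dose: heart rows significant, direction positive (A > B)
  plansB <- lapply(plansA, function(p) {
    p$dose[as.vector(ph$masks$heart)] <- p$dose[as.vector(ph$masks$heart)] / 2
    p
  })
  tabAB <- metrics_table(plansA, plansB, phs)
  hrow <- tabAB[tabAB$structure == "heart" & tabAB$metric == "D_mean", ]
  expect_lt(hrow$p_value, 0.05)
  expect_gt(hrow$median_diff, 0)
  # subject reordering leaves the table unchanged
  ord <- sample(8)
  tab2 <- metrics_table(plansA[ord], plansB[ord], phs[ord])
  expect_equal(tab2$p_value, tabAB$p_value)
  expect_equal(tab2$median_A, tabAB$median_A)
})
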