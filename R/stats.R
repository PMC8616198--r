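# --- plan comparison machinery --------------------------------------------

#' Wilcoxon signed-rank test (exact for small n)
#'
#' Two-tailed paired test. Zero differences are dropped before ranking; ties
#' get midranks. For n <= `exact_max` pairs (after zero removal) the exact
#' null distribution of the positive-rank sum is computed by dynamic
#' programming over the observed (possibly tied) ranks -- equivalent to
#' enumerating all 2^n sign assignments; above that, the normal
#' approximation with tie correction is used.
#'
#' @param x,y paired observation vectors of equal length.
#' @param exact_max exact-enumeration cutoff (default 12).
#' @return list with `statistic` (positive-rank sum V), `p.value`
#'   (two-tailed), `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12) {
  if (length(x) != length(y) || length(x) < 1)
    wp_stop("x and y must have equal length >= 1")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, n_effective = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact distribution of V over all sign assignments: DP on the
    # generating function prod_i (1 + z^(2 r_i)) / 2^n (ranks doubled so
    # midranks become integers)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    w <- numeric(total + 1)
    w[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), w[seq_len(total + 1 - ri)])
      w <- w + shifted
    }
    w <- w / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(w[seq_len(v2 + 1)])
    p_ge <- sum(w[seq.int(v2 + 1, total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = V, p.value = p, n_effective = n, method = method)
}

#' Population average DVH
#'
#' Pointwise arithmetic mean of volume fractions over a set of DVHs sharing
#' one dose axis (resample first with [resample_dvh()] if needed).
#'
#' @param dvhs nonempty list of `dvh` objects on a common dose axis.
#' @return a `dvh` with the averaged curve.
#' @export
population_average_dvh <- function(dvhs) {
  if (!length(dvhs)) wp_stop("empty DVH list")
  axis <- dvhs[[1]]$dose_Gy
  for (d in dvhs)
    if (!isTRUE(all.equal(d$dose_Gy, axis)))
      wp_stop("DVHs must share a common dose axis; resample first")
  vols <- do.call(rbind, lapply(dvhs, `[[`, "volume_pct"))
  structure(list(dose_Gy = axis, volume_pct = colMeans(vols),
                 structure = dvhs[[1]]$structure,
                 max_dose_Gy = max(vapply(dvhs, `[[`, numeric(1), "max_dose_Gy"))),
            class = "dvh")
}

#' Paired DVH difference with bootstrap confidence band
#'
#' Per dose point, the mean of the per-subject differences (A - B) with a
#' seeded percentile-bootstrap confidence band over subjects.
#'
#' @param dvhs_A,dvhs_B lists of `dvh` curves paired by subject, common dose
#'   axis.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed for the resampling.
#' @return list with `dose_Gy`, `mean_diff`, `lower`, `upper` (volume
#'   percentage points).
#' @export
paired_dvh_difference_ci <- function(dvhs_A, dvhs_B, level = 0.95,
                                     n_boot = 2000, seed = 1L) {
  n <- length(dvhs_A)
  if (n != length(dvhs_B)) wp_stop("unpaired DVH lists")
  if (n < 2) wp_stop("need at least 2 subjects for a confidence band")
  axis <- dvhs_A[[1]]$dose_Gy
  diffs <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (!isTRUE(all.equal(dvhs_A[[i]]$dose_Gy, axis)) ||
        !isTRUE(all.equal(dvhs_B[[i]]$dose_Gy, axis)))
      wp_stop("DVHs must share a common dose axis; resample first")
    dvhs_A[[i]]$volume_pct - dvhs_B[[i]]$volume_pct
  }))
  mean_diff <- colMeans(diffs)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  boot_means <- matrix(0, n_boot, length(axis))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot_means[b, ] <- colMeans(diffs[idx, , drop = FALSE])
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  alpha <- (1 - level) / 2
  list(dose_Gy = axis, mean_diff = mean_diff,
       lower = apply(boot_means, 2, quantile, probs = alpha, names = FALSE),
       upper = apply(boot_means, 2, quantile, probs = 1 - alpha, names = FALSE))
}

#' Beam-angle distribution over a plan population
#'
#' Counts beams per gantry-angle bin after rounding each angle to the
#' nearest bin center, wrap-aware (e.g. 357.5 rounds to 0).
#'
#' @param plans list of `fluence_plan` or `bao_result` objects (angles are
#'   taken from each).
#' @param bin_deg bin width, degrees (default 5).
#' @return data.frame: `angle_deg` (bin centers 0, 5, ...), `count`.
#' @export
beam_angle_distribution <- function(plans, bin_deg = 5) {
  if (!length(plans)) wp_stop("empty plan list")
  angs <- unlist(lapply(plans, function(p) {
    if (inherits(p, "bao_result")) p$selected_angles else p$angles
  }))
  binned <- (round(angs / bin_deg) * bin_deg) %% 360
  centers <- seq(0, 360 - bin_deg, by = bin_deg)
  counts <- vapply(centers, function(ct) sum(binned == ct), numeric(1))
  data.frame(angle_deg = centers, count = counts)
}

# default dose-metric panel for paired plan comparison
comparison_metrics <- function() {
  data.frame(
    structure = c("PTV", "lungs", "lungs", "lungs", "heart", "heart",
                  "heart", "esophagus", "esophagus", "esophagus"),
    metric = c("V_95%", "D_mean", "V_5Gy", "V_20Gy", "D_mean", "V_5Gy",
               "V_30Gy", "D_mean", "V_20Gy", "V_60Gy"),
    stringsAsFactors = FALSE)
}

#' Paired dose-metric comparison table
#'
#' Evaluates a panel of dose-volume metrics (target coverage, lung, heart
#' and esophagus mean/volume metrics) on two paired plan populations and
#' reports median and interquartile range per condition plus the two-tailed
#' Wilcoxon signed-rank p-value of the paired difference.
#'
#' @param plans_A,plans_B paired lists of normalized `fluence_plan`s.
#' @param phantoms list of `phantom`s, one per subject.
#' @param metrics data.frame with columns `structure`, `metric`; defaults to
#'   the standard comparison panel.
#' @return data.frame: structure, metric, median_A, iqr_A, median_B, iqr_B,
#'   median_diff, p_value, n.
#' @export
metrics_table <- function(plans_A, plans_B, phantoms,
                          metrics = comparison_metrics()) {
  n <- length(plans_A)
  stopifnot(length(plans_B) == n, length(phantoms) == n)
  rows <- list()
  for (i in seq_len(nrow(metrics))) {
    st <- metrics$structure[i]; me <- metrics$metric[i]
    if (!st %in% names(phantoms[[1]]$masks)) {
      message("metrics_table: structure '", st, "' absent; skipped")
      next
    }
    vA <- vapply(seq_len(n), function(s)
      dose_metric(plans_A[[s]]$dose, phantoms[[s]]$masks[[st]], me,
                  D_p = phantoms[[s]]$prescription_Gy), numeric(1))
    vB <- vapply(seq_len(n), function(s)
      dose_metric(plans_B[[s]]$dose, phantoms[[s]]$masks[[st]], me,
                  D_p = phantoms[[s]]$prescription_Gy), numeric(1))
    wt <- suppressWarnings(wilcoxon_signed_rank(vA, vB))
    rows[[length(rows) + 1]] <- data.frame(
      structure = st, metric = me,
      median_A = median(vA), iqr_A = unname(diff(quantile(vA, c(0.25, 0.75)))),
      median_B = median(vB), iqr_B = unname(diff(quantile(vB, c(0.25, 0.75)))),
      median_diff = median(vA - vB), p_value = wt$p.value, n = n,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
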