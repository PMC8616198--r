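#' Cumulative dose-volume histogram
#'
#' `volume_pct(b)` is the percentage of structure voxels receiving at least
#' `b` Gy, evaluated on a uniform dose axis from 0 to just past the structure
#' maximum. Direct voxel counting, no binning bias.
#'
#' @param dose dose vector over the whole grid (Gy).
#' @param mask logical structure mask (same length when flattened).
#' @param bin_width dose axis step, Gy (default 0.1).
#' @param structure structure name carried in the result.
#' @return object of class `dvh`: list with `dose_Gy`, `volume_pct`,
#'   `structure`, `max_dose_Gy`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1, structure = "structure") {
  if (bin_width <= 0) wp_stop("bin_width must be > 0")
  d <- dose[as.vector(mask)]
  if (!length(d)) wp_stop("empty mask for structure '", structure, "'")
  dmax <- max(d)
  axis <- seq(0, dmax + bin_width, by = bin_width)
  vol <- vapply(axis, function(b) 100 * mean(d >= b), numeric(1))
  structure(list(dose_Gy = axis, volume_pct = vol, structure = structure,
                 max_dose_Gy = dmax),
            class = "dvh")
}

#' Resample a DVH onto a new dose axis
#'
#' Linear interpolation; doses beyond the curve maximum get 0% volume.
#'
#' @param dvh a `dvh`.
#' @param dose_Gy new ascending dose axis.
#' @return a `dvh` on the new axis.
#' @export
resample_dvh <- function(dvh, dose_Gy) {
  vol <- approx(dvh$dose_Gy, dvh$volume_pct, xout = dose_Gy,
                yleft = 100, yright = 0)$y
  structure(list(dose_Gy = dose_Gy, volume_pct = vol,
                 structure = dvh$structure, max_dose_Gy = dvh$max_dose_Gy),
            class = "dvh")
}

#' Dose-volume metric of a structure
#'
#' Supported metrics: `"D_mean"`, `"D_max"`, `"V_<x>Gy"` (% of the structure
#' receiving at least x Gy) and `"V_<x>%"` (% receiving at least x% of the
#' prescription, e.g. the coverage metric `V_95%`). Relative metrics require
#' `D_p`.
#'
#' @param dose dose vector over the grid (Gy).
#' @param mask logical structure mask.
#' @param metric metric name.
#' @param D_p prescription dose in Gy (for relative metrics).
#' @return scalar metric value (Gy or %).
#' @export
dose_metric <- function(dose, mask, metric, D_p = NULL) {
  d <- dose[as.vector(mask)]
  if (!length(d)) wp_stop("empty mask in dose_metric")
  if (metric == "D_mean") return(mean(d))
  if (metric == "D_max") return(max(d))
  m <- regmatches(metric, regexec("^V_([0-9.]+)Gy$", metric))[[1]]
  if (length(m) == 2) return(100 * mean(d >= as.numeric(m[2])))
  m <- regmatches(metric, regexec("^V_([0-9.]+)%$", metric))[[1]]
  if (length(m) == 2) {
    if (is.null(D_p)) wp_stop("metric ", metric, " requires D_p")
    return(100 * mean(d >= as.numeric(m[2]) / 100 * D_p))
  }
  wp_stop("unknown metric '", metric, "'")
}

#' Normalize a plan to the PTV median dose
#'
#' Scales fluence and dose by one global factor so that the median PTV dose
#' equals the prescription exactly. For an even voxel count the median is the
#' midpoint of the two central order statistics. Idempotent.
#'
#' @param plan a `fluence_plan`.
#' @param phantom the `phantom` the plan was computed on.
#' @return the rescaled `fluence_plan` (`normalized = TRUE`, with
#'   `norm_factor` recording the applied factor).
#' @export
normalize_plan <- function(plan, phantom) {
  stopifnot(inherits(plan, "fluence_plan"))
  med <- median(plan$dose[as.vector(phantom$masks$PTV)])
  if (med <= 0) wp_stop("cannot normalize: median PTV dose is zero")
  f <- phantom$prescription_Gy / med
  plan$fluence <- plan$fluence * f
  plan$dose <- plan$dose * f
  plan$normalized <- TRUE
  plan$norm_factor <- f * (plan$norm_factor %||% 1)
  plan
}

# clinical planning constraint set (audited on normalized plans):
# coverage, lung volume/mean limits, heart V30, esophagus mean, cord and
# plexus maxima, global hot-spot limit relative to the prescription
clinical_constraint_rows <- function(D_p) {
  data.frame(
    structure = c("PTV", "lungs", "lungs", "lungs", "heart", "esophagus",
                  "spinal_canal", "brachial_plexus", "body"),
    metric = c("V_95%", "V_5Gy", "V_20Gy", "D_mean", "V_30Gy", "D_mean",
               "D_max", "D_max", "D_max"),
    direction = c(">", "<", "<", "<", "<", "<", "<", "<", "<"),
    limit = c(98, 65, 35, 20, 40, 34, 50, 66, D_p * 1.07),
    stringsAsFactors = FALSE
  )
}

#' Audit a plan against the clinical planning constraints
#'
#' Evaluates the clinical dose-constraint set (PTV V_95% > 98%; lungs
#' V_5Gy < 65%, V_20Gy < 35%, D_mean < 20 Gy; heart V_30Gy < 40%; esophagus
#' D_mean < 34 Gy; spinal canal D_max < 50 Gy; brachial plexus D_max < 66 Gy
#' if delineated; body D_max < 1.07 D_p) on a normalized plan.
#'
#' @param plan a normalized `fluence_plan`.
#' @param phantom the `phantom`.
#' @return object of class `constraint_report`: data.frame with columns
#'   structure, metric, direction, limit, achieved, pass; attribute
#'   `overall_pass` is TRUE iff no row fails.
#' @export
check_clinical_constraints <- function(plan, phantom) {
  stopifnot(inherits(plan, "fluence_plan"))
  if (!isTRUE(plan$normalized))
    wp_stop("plan must be normalized before constraint auditing")
  rows <- clinical_constraint_rows(phantom$prescription_Gy)
  keep <- rows$structure %in% names(phantom$masks)
  if (any(!keep))
    message("check_clinical_constraints: skipping absent structures: ",
            paste(rows$structure[!keep], collapse = ", "))
  rows <- rows[keep, , drop = FALSE]
  rows$achieved <- vapply(seq_len(nrow(rows)), function(i) {
    dose_metric(plan$dose, phantom$masks[[rows$structure[i]]],
                rows$metric[i], D_p = phantom$prescription_Gy)
  }, numeric(1))
  rows$pass <- ifelse(rows$direction == ">", rows$achieved > rows$limit,
                      rows$achieved < rows$limit)
  structure(rows, class = c("constraint_report", "data.frame"),
            overall_pass = all(rows$pass))
}

#' @export
print.constraint_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$achieved <- round(df$achieved, 2)
  print(df, row.names = FALSE)
  cat("overall:", if (attr(x, "overall_pass")) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Write / read a DVH as CSV
#'
#' Two columns: `dose_Gy`, `volume_pct`.
#'
#' @param dvh a `dvh`.
#' @param path file path.
#' @return `read_dvh_csv` returns a `dvh` (structure name taken from the
#'   file name unless given).
#' @export
write_dvh_csv <- function(dvh, path) {
  # full-precision text so the round-trip is exact
  df <- data.frame(dose_Gy = sprintf("%.17g", dvh$dose_Gy),
                   volume_pct = sprintf("%.17g", dvh$volume_pct))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dvh_csv
#' @param structure structure name for the curve read back.
#' @export
read_dvh_csv <- function(path, structure = sub("[.]csv$", "", basename(path))) {
  df <- read.csv(path)
  if (!all(c("dose_Gy", "volume_pct") %in% names(df)))
    wp_stop("malformed DVH CSV '", path, "': need columns dose_Gy, volume_pct")
  df$dose_Gy <- as.numeric(df$dose_Gy)
  df$volume_pct <- as.numeric(df$volume_pct)
  structure(list(dose_Gy = df$dose_Gy, volume_pct = df$volume_pct,
                 structure = structure,
                 max_dose_Gy = max(df$dose_Gy[df$volume_pct > 0], 0)),
            class = "dvh")
}
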