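# --- automated handover to a deliverable-style optimizer ------------------
#
# The fluence plan's OAR DVHs are converted into per-structure line
# objectives (dose-volume pair sequences sampled every 0.7 Gy) and combined
# with fixed PTV point objectives, OAR maximum points and a normal tissue
# objective (NTO) into a patient-specific template.  A surrogate optimizer
# then re-creates a plan from that template alone, minimizing a
# priority-weighted sum of one-sided quadratic penalties -- emulating the
# handover of an optimized plan to a second, template-driven treatment
# planning system.

#' Convert a DVH into a line objective
#'
#' Samples the cumulative DVH at doses `0, spacing, 2*spacing, ...` up to and
#' including the first multiple of `spacing` at or above the structure
#' maximum dose; volumes by linear interpolation.
#'
#' @param dvh a `dvh`.
#' @param spacing_Gy dose spacing between points (default 0.7 Gy).
#' @param priority template priority attached to the line.
#' @return object of class `line_objective`: list with `structure`,
#'   `dose_Gy`, `volume_pct`, `priority`.
#' @export
dvh_to_line_objectives <- function(dvh, spacing_Gy = 0.7, priority = 80) {
  stopifnot(inherits(dvh, "dvh"))
  dmax <- dvh$max_dose_Gy
  n_pts <- ceiling(dmax / spacing_Gy - 1e-9) + 1  # 0 .. first multiple >= dmax
  doses <- (seq_len(n_pts) - 1) * spacing_Gy
  vols <- approx(dvh$dose_Gy, dvh$volume_pct, xout = doses,
                 yleft = 100, yright = 0)$y
  structure(list(structure = dvh$structure, dose_Gy = doses,
                 volume_pct = vols, priority = priority),
            class = "line_objective")
}

# fixed template priorities per structure
LINE_PRIORITIES <- c(lungs = 80, heart = 80, esophagus = 60,
                     spinal_canal = 40, brachial_plexus = 40)

#' Build the patient-specific objective template
#'
#' Combines fixed PTV point objectives (Min `D_p - 0.5`, Max `D_p + 0.5` Gy,
#' priority 130), patient-specific OAR line objectives (lungs/heart at
#' priority 80, esophagus 60, spinal canal and brachial plexus 40), fixed
#' OAR maximum points (spinal canal 48 Gy, brachial plexus 62 Gy, priority
#' 100) and the normal tissue objective (distance from target border 0.5 cm,
#' start dose 105%, end dose 60%, fall-off 0.15, priority 100).
#'
#' @param dvhs named list of `dvh` curves; must contain every OAR present in
#'   the phantom (lungs, heart, esophagus, spinal_canal, and
#'   brachial_plexus when delineated).
#' @param phantom the `phantom`.
#' @param line_spacing_Gy dose spacing of the line objectives (0.7 Gy).
#' @return object of class `objective_template`.
#' @export
build_objective_template <- function(dvhs, phantom, line_spacing_Gy = 0.7) {
  D_p <- phantom$prescription_Gy
  oars <- intersect(names(LINE_PRIORITIES), names(phantom$masks))
  missing <- setdiff(oars, names(dvhs))
  if (length(missing))
    wp_stop("missing OAR DVHs: ", paste(missing, collapse = ", "))
  lines <- lapply(oars, function(nm)
    dvh_to_line_objectives(dvhs[[nm]], line_spacing_Gy,
                           priority = LINE_PRIORITIES[[nm]]))
  names(lines) <- oars
  points <- data.frame(
    structure = c("PTV", "PTV"), type = c("Min", "Max"),
    dose_Gy = c(D_p - 0.5, D_p + 0.5), priority = c(130, 130),
    stringsAsFactors = FALSE)
  if ("spinal_canal" %in% names(phantom$masks))
    points <- rbind(points, data.frame(structure = "spinal_canal",
                                       type = "Max", dose_Gy = 48,
                                       priority = 100))
  if ("brachial_plexus" %in% names(phantom$masks))
    points <- rbind(points, data.frame(structure = "brachial_plexus",
                                       type = "Max", dose_Gy = 62,
                                       priority = 100))
  structure(list(D_p = D_p, point_objectives = points, line_objectives = lines,
                 nto = list(distance_mm = 5, start_frac = 1.05,
                            end_frac = 0.60, falloff = 0.15, priority = 100)),
            class = "objective_template")
}

#' Normal tissue objective dose threshold
#'
#' Allowed dose as a function of distance from the target border:
#' `D_p * (end + (start - end) * exp(-falloff * max(0, d - distance_mm)))`
#' with the fall-off applied per mm. Equals `start * D_p` (105%) at the
#' start distance and tends to `end * D_p` (60%) far from the target;
#' monotone non-increasing in distance.
#'
#' @param distance_mm distance from the PTV border, mm (vectorized).
#' @param D_p prescription dose, Gy.
#' @param params NTO parameter list (see [build_objective_template()]).
#' @return allowed dose in Gy.
#' @export
nto_threshold <- function(distance_mm, D_p,
                          params = list(distance_mm = 5, start_frac = 1.05,
                                        end_frac = 0.60, falloff = 0.15)) {
  if (any(distance_mm < 0)) wp_stop("distance_mm must be >= 0")
  D_p * (params$end_frac + (params$start_frac - params$end_frac) *
           exp(-params$falloff * pmax(0, distance_mm - params$distance_mm)))
}

#' Surrogate re-optimization from an objective template
#'
#' Re-creates a plan from the template alone by minimizing, over nonnegative
#' fluence, a priority-weighted quadratic penalty with these terms: PTV
#' voxels below the Min / above the Max point doses; per line-objective
#' sample, squared excess of the achieved volume over the line volume (the
#' achieved volume uses a smooth sigmoid DVH surrogate, so the term is
#' differentiable), with a lighter symmetric tracking weight below the line;
#' a distribution-tracking term (squared distance between the structure's
#' sorted doses and the line's implied dose quantiles) that anchors the DVH
#' to the template rather than merely bounding it; OAR maximum-point
#' violations; and violations of the NTO's distance-dependent allowed dose
#' for body voxels outside the PTV. Dose-type deviations are expressed as
#' fractions of the prescription so dose- and volume-space terms share a
#' scale. The weighted sum is homogeneous in the priorities, so scaling all
#' priorities leaves the optimum unchanged. The result is normalized to the
#' PTV median dose.
#'
#' @param influence an `influence_matrix`.
#' @param template an `objective_template`.
#' @param phantom the `phantom`.
#' @param control list: `maxit` (default 3000), `tau_Gy` sigmoid width of
#'   the smooth DVH (default 0.2 Gy), `track_weight` distribution-tracking
#'   weight (default 30), `sig_track` below-line volume tracking fraction
#'   (default 0.3), `ptv_scale` extra weight on the PTV point objectives
#'   (default 4).
#' @return a normalized `fluence_plan`.
#' @export
surrogate_reoptimize <- function(influence, template, phantom,
                                 control = list()) {
  stopifnot(inherits(influence, "influence_matrix"),
            inherits(template, "objective_template"))
  maxit <- control$maxit %||% 3000
  pen <- surrogate_penalty(influence, template, phantom, control)
  n <- ncol(influence$matrix)
  masks <- phantom$masks
  # base start: uniform fluence scaled to the prescription at the PTV mean
  x_base <- rep(template$D_p / max(sum(pen$colsum_ptv), 1e-12), n)
  # deterministic multi-start; the sorted-dose tracking term makes the
  # objective piecewise smooth and L-BFGS basin-dependent, so several starts
  # are optimized and the solution that best reproduces the template's
  # sampled DVHs (the component's own goal) is kept
  starts <- list(x_base,
                 x_base * (1 + 0.15 * rep_len(c(1, -1), n)))
  if (isTRUE(control$quick)) starts <- starts[1]
  run_one <- function(x0) {
    opt <- optim(x0, pen$fn, pen$gr, method = "L-BFGS-B", lower = 0,
                 control = list(maxit = maxit, factr = 1e5))
    for (r in 1:2) {  # restart with fresh curvature memory
      opt2 <- optim(pmax(opt$par, 0), pen$fn, pen$gr, method = "L-BFGS-B",
                    lower = 0, control = list(maxit = maxit, factr = 1e5))
      improved <- opt2$value < opt$value - 1e-10 * (1 + abs(opt$value))
      if (opt2$value <= opt$value) opt <- opt2
      if (!improved) break
    }
    opt
  }
  # exact template-DVH reproduction error (pp) and target coverage of a
  # candidate fluence, after the same normalization the returned plan gets
  score_of <- function(x) {
    d_all <- compute_dose(influence, x)
    med <- median(d_all[as.vector(masks$PTV)])
    if (med <= 0) return(list(err = Inf, v95 = 0))
    d_all <- d_all * template$D_p / med
    worst <- 0
    for (nm in names(template$line_objectives)) {
      lo <- template$line_objectives[[nm]]
      d <- d_all[as.vector(masks[[nm]])]
      ach <- vapply(lo$dose_Gy, function(b) 100 * mean(d >= b), numeric(1))
      worst <- max(worst, abs(ach - lo$volume_pct))
    }
    list(err = worst,
         v95 = 100 * mean(d_all[as.vector(masks$PTV)] >= 0.95 * template$D_p))
  }
  # candidate selection: template-DVH reproduction is the component's goal;
  # among candidates that keep target coverage, the closest reproduction wins
  best <- NULL; best_score <- list(err = Inf, v95 = 0)
  consider <- function(opt) {
    if (!opt$convergence %in% c(0, 1)) return(invisible())
    sc <- score_of(pmax(opt$par, 0))
    better <- if ((sc$v95 >= 98) == (best_score$v95 >= 98)) {
      sc$err < best_score$err
    } else sc$v95 >= 98
    if (better) { best <<- opt; best_score <<- sc }
    invisible()
  }
  for (x0 in starts) consider(run_one(x0))
  if (is.null(best))
    wp_stop("surrogate optimizer failed to converge from every start",
            class = "wishplan_solver_error")
  # continuation: re-polish from the best solution with the DVH-tracking
  # terms ramped up; the warm start keeps the basin while the stronger pull
  # snaps the last voxels onto the template curves
  if (!isTRUE(control$quick)) {
    for (ramp in c(8)) {
      ctl2 <- control
      ctl2$track_weight <- (control$track_weight %||% 30) * ramp
      ctl2$sig_track <- (control$sig_track %||% 0.3) * ramp
      pen2 <- surrogate_penalty(influence, template, phantom, ctl2)
      consider(optim(pmax(best$par, 0), pen2$fn, pen2$gr, method = "L-BFGS-B",
                     lower = 0, control = list(maxit = maxit, factr = 1e5)))
    }
  }
  best_err <- best_score$err
  x <- pmax(best$par, 0)
  plan <- structure(list(angles = influence$angles, fluence = x,
                         dose = compute_dose(influence, x),
                         normalized = FALSE, achieved = NULL,
                         stage_log = NULL, D_p = template$D_p,
                         notes = paste0("surrogate re-optimization, penalty ",
                                        signif(best$value, 4),
                                        ", template DVH error ",
                                        signif(best_err, 3), " pp")),
                    class = "fluence_plan")
  normalize_plan(plan, phantom)
}

# builds the template penalty (value + gradient closures) on the fluence
surrogate_penalty <- function(influence, template, phantom, control = list()) {
  tau <- control$tau_Gy %||% 0.2
  track_weight <- control$track_weight %||% 30
  sig_track <- control$sig_track %||% 0.3
  ptv_scale <- control$ptv_scale %||% 4
  M <- influence$matrix
  n <- ncol(M)
  masks <- phantom$masks
  D_p <- template$D_p

  vox <- function(mask) which(as.vector(mask))
  ptv_idx <- vox(masks$PTV)
  D_ptv <- as.matrix(M[ptv_idx, , drop = FALSE])

  pts <- template$point_objectives
  ptv_min <- pts$dose_Gy[pts$structure == "PTV" & pts$type == "Min"]
  ptv_max <- pts$dose_Gy[pts$structure == "PTV" & pts$type == "Max"]
  w_ptv <- pts$priority[pts$structure == "PTV"][1] * ptv_scale

  line_terms <- lapply(names(template$line_objectives), function(nm) {
    lo <- template$line_objectives[[nm]]
    idx <- vox(masks[[nm]])
    m <- length(idx)
    # implied dose quantiles of the line: invert the cumulative curve so the
    # template also fixes the target dose distribution of the structure
    fr <- (seq_len(m) - 0.5) / m * 100  # descending-rank volume fractions
    # step inversion of the line with mid-gap placement: the line only pins
    # volumes at its sample doses, so each rank's target dose is the center
    # of the sampling gap it falls in -- counts at every sample reproduce
    # the line exactly while keeping targets away from the sample edges
    gap <- if (length(lo$dose_Gy) > 1) diff(lo$dose_Gy)[1] else 0.7
    kk <- vapply(fr, function(f) max(which(lo$volume_pct >= f - 1e-9)),
                 integer(1))
    q <- lo$dose_Gy[kk] + gap / 2
    list(D = as.matrix(M[idx, , drop = FALSE]), dose = lo$dose_Gy,
         vol = lo$volume_pct / 100, w = lo$priority, q = q, name = nm)
  })
  max_terms <- lapply(which(pts$type == "Max" & pts$structure != "PTV"),
                      function(i) {
    idx <- vox(masks[[pts$structure[i]]])
    list(D = as.matrix(M[idx, , drop = FALSE]), cap = pts$dose_Gy[i],
         w = pts$priority[i])
  })

  # NTO: allowed dose per body voxel outside the PTV
  ptv_dist <- distance_to_mask(masks$PTV, phantom$spacing_mm)
  nto_idx <- vox(masks$body & !masks$PTV)
  nto_allowed <- nto_threshold(as.vector(ptv_dist)[nto_idx], D_p, template$nto)
  D_nto <- as.matrix(M[nto_idx, , drop = FALSE])
  w_nto <- template$nto$priority

  # dose-type deviations are expressed as fractions of the prescription so
  # that dose-space and volume-space penalty terms live on comparable scales
  objective <- function(x) {
    f <- 0
    d_ptv <- as.numeric(D_ptv %*% x)
    under <- pmin(d_ptv - ptv_min, 0); over <- pmax(d_ptv - ptv_max, 0)
    f <- f + w_ptv * mean((under / D_p)^2 + (over / D_p)^2)
    g_ptv <- w_ptv * 2 * (under + over) / (D_p^2 * length(d_ptv))
    grad <- as.numeric(crossprod(D_ptv, g_ptv))
    for (tm in line_terms) {
      d <- as.numeric(tm$D %*% x)
      m <- length(d)
      K <- length(tm$dose)
      g_d <- numeric(m)
      for (k in seq_len(K)) {
        s <- plogis((d - tm$dose[k]) / tau)
        v <- mean(s) - tm$vol[k]
        # full weight on violations above the line, light symmetric tracking
        # below it (volume-space, so low-dose samples count like high-dose)
        wk <- if (v > 0) tm$w else tm$w * sig_track
        f <- f + wk * v^2 / K
        g_d <- g_d + wk * 2 * v * dlogis((d - tm$dose[k]) / tau) / (tau * m * K)
      }
      # distribution tracking: squared distance between the achieved sorted
      # doses and the line's implied quantiles (a Wasserstein-2 term), so the
      # template DVH is reproduced rather than merely bounded from above.
      # Residuals are weighted relative to the local dose level; the DVH is
      # sampled uniformly in dose, so a 0.3 Gy error matters as much in the
      # scatter tail as at the high-dose end.
      ord <- order(d, decreasing = TRUE)
      resid <- d[ord] - tm$q
      f <- f + tm$w * track_weight * mean((resid / D_p)^2)
      g_d[ord] <- g_d[ord] + tm$w * track_weight * 2 * resid / (D_p^2 * m)
      grad <- grad + as.numeric(crossprod(tm$D, g_d))
    }
    for (tm in max_terms) {
      d <- as.numeric(tm$D %*% x)
      over <- pmax(d - tm$cap, 0)
      f <- f + tm$w * mean((over / D_p)^2)
      grad <- grad + as.numeric(crossprod(tm$D, tm$w * 2 * over / (D_p^2 * length(d))))
    }
    d <- as.numeric(D_nto %*% x)
    over <- pmax(d - nto_allowed, 0)
    f <- f + w_nto * mean((over / D_p)^2)
    grad <- grad + as.numeric(crossprod(D_nto, w_nto * 2 * over / (D_p^2 * length(d))))
    list(f = f, grad = grad)
  }

  list(fn = function(x) objective(x)$f,
       gr = function(x) objective(x)$grad,
       colsum_ptv = colMeans(D_ptv))
}

#' Residual line-objective violations of a plan
#'
#' Evaluates, per line objective, the achieved volume (exact counting) minus
#' the line volume at every sampled dose; positive entries are residual
#' violations.
#'
#' @param plan a `fluence_plan`.
#' @param template the `objective_template`.
#' @param phantom the `phantom`.
#' @return data.frame: structure, dose_Gy, line_volume_pct,
#'   achieved_volume_pct, excess_pct.
#' @export
line_objective_residuals <- function(plan, template, phantom) {
  rows <- list()
  for (nm in names(template$line_objectives)) {
    lo <- template$line_objectives[[nm]]
    d <- plan$dose[as.vector(phantom$masks[[nm]])]
    ach <- vapply(lo$dose_Gy, function(b) 100 * mean(d >= b), numeric(1))
    rows[[nm]] <- data.frame(structure = nm, dose_Gy = lo$dose_Gy,
                             line_volume_pct = lo$volume_pct,
                             achieved_volume_pct = ach,
                             excess_pct = pmax(ach - lo$volume_pct, 0))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- XML serialization ----------------------------------------------------

#' Write / read an objective template as XML
#'
#' Schema: root `<objective_template D_p="..">` containing one
#' `<objective>` element per objective with attributes `structure`, `type`
#' (`Min`, `Max`, `Line`, `NTO`) and `priority`; point objectives carry a
#' `dose_Gy` attribute, line objectives contain `<point dose_Gy=".."
#' volume_pct=".."/>` children and the NTO carries its parameters as
#' attributes.
#'
#' @param template an `objective_template`.
#' @param path file path.
#' @export
write_objective_template_xml <- function(template, path) {
  root <- xml2::xml_new_root("objective_template",
                             D_p = format(template$D_p))
  pts <- template$point_objectives
  for (i in seq_len(nrow(pts)))
    xml2::xml_add_child(root, "objective", structure = pts$structure[i],
                        type = pts$type[i],
                        dose_Gy = format(pts$dose_Gy[i]),
                        priority = format(pts$priority[i]))
  for (lo in template$line_objectives) {
    node <- xml2::xml_add_child(root, "objective", structure = lo$structure,
                                type = "Line", priority = format(lo$priority))
    for (k in seq_along(lo$dose_Gy))
      xml2::xml_add_child(node, "point",
                          dose_Gy = format(lo$dose_Gy[k], digits = 15),
                          volume_pct = format(lo$volume_pct[k], digits = 15))
  }
  nto <- template$nto
  xml2::xml_add_child(root, "objective", structure = "body", type = "NTO",
                      priority = format(nto$priority),
                      distance_mm = format(nto$distance_mm),
                      start_frac = format(nto$start_frac),
                      end_frac = format(nto$end_frac),
                      falloff = format(nto$falloff))
  xml2::write_xml(root, path)
  invisible(path)
}

#' @rdname write_objective_template_xml
#' @export
read_objective_template_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    wp_stop("malformed template XML '", path, "': ", conditionMessage(e)))
  root <- doc
  D_p <- as.numeric(xml2::xml_attr(root, "D_p"))
  objs <- xml2::xml_find_all(root, "objective")
  points <- list(); lines <- list(); nto <- NULL
  for (node in objs) {
    type <- xml2::xml_attr(node, "type")
    stru <- xml2::xml_attr(node, "structure")
    pri <- as.numeric(xml2::xml_attr(node, "priority"))
    if (type %in% c("Min", "Max")) {
      points[[length(points) + 1]] <- data.frame(
        structure = stru, type = type,
        dose_Gy = as.numeric(xml2::xml_attr(node, "dose_Gy")),
        priority = pri, stringsAsFactors = FALSE)
    } else if (type == "Line") {
      kids <- xml2::xml_find_all(node, "point")
      lines[[stru]] <- structure(list(
        structure = stru,
        dose_Gy = as.numeric(xml2::xml_attr(kids, "dose_Gy")),
        volume_pct = as.numeric(xml2::xml_attr(kids, "volume_pct")),
        priority = pri), class = "line_objective")
    } else if (type == "NTO") {
      nto <- list(distance_mm = as.numeric(xml2::xml_attr(node, "distance_mm")),
                  start_frac = as.numeric(xml2::xml_attr(node, "start_frac")),
                  end_frac = as.numeric(xml2::xml_attr(node, "end_frac")),
                  falloff = as.numeric(xml2::xml_attr(node, "falloff")),
                  priority = pri)
    } else wp_stop("unknown objective type '", type, "' in ", path)
  }
  structure(list(D_p = D_p, point_objectives = do.call(rbind, points),
                 line_objectives = lines, nto = nto),
            class = "objective_template")
}
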