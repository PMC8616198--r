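# --- lexicographic fluence-map optimization -------------------------------
#
# The optimizer minimizes the wish-list objectives one at a time in priority
# order under the hard constraints; after each minimization a bound on that
# objective is inserted so later stages cannot degrade it.  Round 1 inserts
# the Goal value when it was met (leaving headroom for lower priorities),
# otherwise the achieved value with a configurable relaxation.  Round 2
# re-minimizes, in priority order, every objective without a Sufficient
# value to the fullest extent, replacing its round-1 bound by the new
# optimum.  Objectives with a Sufficient value stay at their round-1 bound.

# numerical slack added to inserted bounds so the previous iterate remains
# strictly feasible for the next stage
BOUND_EPS <- 1e-6

# resolve every structure the wish-list mentions into a dense dose matrix;
# absent or empty structures are dropped with a note
fmo_structure_doses <- function(influence, wishlist, phantom, derived) {
  wanted <- unique(c(wishlist$hard_constraints$structure,
                     wishlist$objectives$structure))
  Ds <- list(); notes <- character(0)
  for (nm in wanted) {
    mask <- tryCatch(resolve_structure(nm, phantom, derived), error = function(e) NULL)
    if (is.null(mask) || !any(mask)) {
      notes <- c(notes, paste0("structure '", nm, "' absent or empty; skipped"))
      next
    }
    Ds[[nm]] <- as.matrix(influence$matrix[which(as.vector(mask)), , drop = FALSE])
  }
  list(Ds = Ds, notes = notes)
}

fmo_objective <- function(entry, Ds, wishlist) {
  D <- Ds[[entry$structure]]
  switch(entry$type,
         Mean = objective_mean(D),
         Max = objective_max(D),
         LTCP = objective_ltcp(D, wishlist$ltcp$alpha, wishlist$ltcp$ref_Gy),
         wp_stop("unknown objective type '", entry$type, "'"))
}

# assemble the constraint set for one stage from the symbolic list of hard
# constraints and inserted bounds (each: structure, type, bound).  Bounds of
# the same (structure, type) coalesce to the tightest value, which keeps the
# constraint matrix small when a structure carries both a hard cap and an
# inserted objective bound.
fmo_stage_constraints <- function(sym, Ds, wishlist, skip_priority = NA) {
  keep <- vapply(sym, function(s)
    is.na(skip_priority) || is.na(s$priority) || s$priority != skip_priority,
    logical(1))
  sym <- sym[keep]
  key <- vapply(sym, function(s) paste(s$structure, s$type), character(1))
  A <- NULL; b <- numeric(0); lse <- list()
  for (k in unique(key)) {
    grp <- sym[key == k]
    bound <- min(vapply(grp, function(s) s$bound, numeric(1)))
    slack_bound <- bound + BOUND_EPS * abs(bound) + 1e-12
    st <- grp[[1]]
    D <- Ds[[st$structure]]
    if (st$type == "LTCP") {
      lse <- c(lse, list(list(D = D, alpha = wishlist$ltcp$alpha,
                              ref = wishlist$ltcp$ref_Gy, bound = slack_bound)))
    } else if (st$type == "Mean") {
      A <- rbind(A, colMeans(D)); b <- c(b, slack_bound)
    } else {
      A <- rbind(A, D); b <- c(b, rep(slack_bound, nrow(D)))
    }
  }
  stage_constraints(A, b, lse)
}

#' Solve a single priority stage
#'
#' Minimizes one objective subject to an explicit constraint set; thin
#' exported wrapper over the interior-point stage solver operating on an
#' influence matrix. See [solve_stage()] for the generic form.
#'
#' @param influence an `influence_matrix`.
#' @param constraints a [stage_constraints()] on the fluence.
#' @param objective a [stage objective][objective_mean].
#' @param x0 optional warm start.
#' @param control a [stage_control()].
#' @return list with `value` and `fluence`.
#' @export
solve_priority_stage <- function(influence, constraints, objective, x0 = NULL,
                                 control = stage_control()) {
  res <- solve_stage(objective, constraints, ncol(influence$matrix), x0, control)
  list(value = res$value, fluence = res$x, status = res$status, gap = res$gap)
}

#' Two-round lexicographic fluence-map optimization
#'
#' Runs the full wish-list-driven procedure: round 1 minimizes each
#' objective in priority order and inserts its Goal value as a constraint
#' when met (regardless of further improvement possible), otherwise the
#' achieved value times the relaxation factor; round 2 re-minimizes every
#' objective without a Sufficient value to the fullest extent, keeping all
#' other bounds fixed and replacing its own bound by the new optimum.
#'
#' @param influence an `influence_matrix`.
#' @param wishlist a `wish_list`.
#' @param phantom the `phantom`.
#' @param derived derived structures; computed when `NULL`.
#' @param control a [stage_control()].
#' @return object of class `fluence_plan`: list with `angles`, `fluence`,
#'   `dose`, `normalized`, `achieved` (one value per objective priority; NA
#'   where the structure was absent), `stage_log` (data.frame), `D_p`,
#'   `notes`.
#' @export
lexicographic_solve <- function(influence, wishlist, phantom, derived = NULL,
                                control = stage_control()) {
  stopifnot(inherits(influence, "influence_matrix"),
            inherits(wishlist, "wish_list"))
  validate_wishlist(wishlist)
  if (is.null(derived)) derived <- derive_structures(phantom)
  sd_ <- fmo_structure_doses(influence, wishlist, phantom, derived)
  Ds <- sd_$Ds
  obj_df <- wishlist$objectives
  active <- which(obj_df$structure %in% names(Ds))
  notes <- sd_$notes

  # symbolic constraint list: hard constraints now, inserted bounds appended
  sym <- list()
  for (i in seq_len(nrow(wishlist$hard_constraints))) {
    hc <- wishlist$hard_constraints[i, ]
    if (!hc$structure %in% names(Ds)) next
    sym[[length(sym) + 1L]] <- list(structure = hc$structure, type = hc$type,
                                    bound = hc$limit_Gy, priority = NA_integer_)
  }

  n <- ncol(influence$matrix)
  x <- NULL
  log_rows <- list()

  insert_bound <- function(sym, entry, bound) {
    # replace this priority's previous bound, if any
    keep <- vapply(sym, function(s) is.na(s$priority) || s$priority != entry$priority,
                   logical(1))
    sym <- sym[keep]
    sym[[length(sym) + 1L]] <- list(structure = entry$structure,
                                    type = entry$type, bound = bound,
                                    priority = entry$priority)
    sym
  }

  run_stage <- function(k, round, x) {
    entry <- obj_df[k, ]
    cons <- fmo_stage_constraints(sym, Ds, wishlist,
                                  skip_priority = if (round == 2) entry$priority else NA)
    res <- tryCatch(
      solve_stage(fmo_objective(entry, Ds, wishlist), cons, n, x, control),
      error = function(e) {
        wp_stop("round ", round, " priority ", entry$priority, " (",
                entry$structure, " ", entry$type, "): ", conditionMessage(e),
                class = "wishplan_infeasible")
      })
    res
  }

  for (k in active) {  # round 1
    entry <- obj_df[k, ]
    res <- run_stage(k, 1L, x)
    x <- res$x
    achieved <- res$value
    if (achieved <= entry$goal) {
      bound <- entry$goal; btype <- "goal"
    } else {
      bound <- achieved * wishlist$relaxation_factor; btype <- "relaxed"
    }
    sym <- insert_bound(sym, entry, bound)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      round = 1L, priority = entry$priority, structure = entry$structure,
      type = entry$type, achieved = achieved, bound_inserted = bound,
      bound_type = btype, solver_status = res$status, gap = res$gap)
  }

  for (k in active) {  # round 2: only objectives without a Sufficient value
    entry <- obj_df[k, ]
    if (!is.na(entry$sufficient)) next
    res <- run_stage(k, 2L, x)
    x <- res$x
    achieved <- res$value
    sym <- insert_bound(sym, entry, achieved)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      round = 2L, priority = entry$priority, structure = entry$structure,
      type = entry$type, achieved = achieved, bound_inserted = achieved,
      bound_type = "optimum", solver_status = res$status, gap = res$gap)
  }

  dose <- compute_dose(influence, pmax(x, 0))
  achieved_all <- rep(NA_real_, nrow(obj_df))
  for (k in active)
    achieved_all[k] <- evaluate_objective(obj_df[k, ], dose, phantom,
                                          wishlist, derived)
  structure(list(angles = influence$angles, fluence = pmax(x, 0), dose = dose,
                 normalized = FALSE, achieved = achieved_all,
                 stage_log = do.call(rbind, log_rows), D_p = wishlist$D_p,
                 notes = notes),
            class = "fluence_plan")
}

#' Verify the wish-list hard constraints on a plan
#'
#' Evaluates all hard constraints on the plan dose (upper bounds), with the
#' achieved value, margin and pass flag. The PTV Mean cap acts as the dose
#' scale anchor of the optimization: on a solved plan it is expected to be
#' tight (active); its tightness is reported in the `tight` column.
#'
#' @param plan a `fluence_plan`.
#' @param wishlist the `wish_list` it was solved against.
#' @param phantom the `phantom`.
#' @param derived derived structures; computed when `NULL`.
#' @param tol relative feasibility tolerance (default 1e-6).
#' @return data.frame: structure, type, limit_Gy, achieved, margin, pass,
#'   tight; attribute `overall_pass`.
#' @export
verify_hard_constraints <- function(plan, wishlist, phantom, derived = NULL,
                                    tol = 1e-6) {
  stopifnot(inherits(plan, "fluence_plan"))
  if (is.null(derived)) derived <- derive_structures(phantom)
  hc <- wishlist$hard_constraints
  rows <- list()
  for (i in seq_len(nrow(hc))) {
    mask <- tryCatch(resolve_structure(hc$structure[i], phantom, derived),
                     error = function(e) NULL)
    if (is.null(mask) || !any(mask)) next
    d <- plan$dose[as.vector(mask)]
    achieved <- if (hc$type[i] == "Max") max(d) else mean(d)
    margin <- hc$limit_Gy[i] - achieved
    rows[[length(rows) + 1L]] <- data.frame(
      structure = hc$structure[i], type = hc$type[i],
      limit_Gy = hc$limit_Gy[i], achieved = achieved, margin = margin,
      pass = achieved <= hc$limit_Gy[i] * (1 + tol) + tol,
      tight = abs(margin) <= hc$limit_Gy[i] * 1e-3)
  }
  out <- do.call(rbind, rows)
  structure(out, overall_pass = all(out$pass))
}

#' @export
print.fluence_plan <- function(x, ...) {
  cat("fluence_plan: ", length(x$angles), " beams (",
      paste(round(x$angles), collapse = ", "), " deg), ",
      length(x$fluence), " beamlets, ",
      if (isTRUE(x$normalized)) "normalized" else "unnormalized", "\n", sep = "")
  if (!is.null(x$achieved))
    cat("achieved objective vector: ",
        paste(signif(x$achieved, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}
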