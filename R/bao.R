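# --- integrated beam-angle optimization -----------------------------------
#
# Greedy sequential addition with full wish-list optimization per candidate:
# at every iteration each unused candidate angle is scored by running the
# complete two-round lexicographic optimization on the current beam set plus
# that candidate, and the lexicographically best objective vector wins.
# Because candidates are judged by the same optimization that produces the
# final plan, angle selection and profile optimization are integrated rather
# than surrogate-driven.

#' Compare two objective vectors lexicographically
#'
#' Walks both vectors in priority order; the first position where the values
#' differ by more than `tolerance` decides (lower is better, all objectives
#' being minimized). Positions where both values are `NA` (objective skipped
#' on this phantom) are ignored.
#'
#' When `goals` is supplied, values are first clamped from below to their
#' Goal -- the wish-list treats everything at or below a Goal as equally
#' satisfied, so two plans beating a Goal by different amounts tie at that
#' priority -- and a second raw-value pass breaks full ties. This is the
#' plan-quality order induced by the wish-list semantics and is what
#' beam-angle scoring uses.
#'
#' @param a,b numeric objective vectors of equal length, same priority order.
#' @param tolerance absolute tie tolerance per component (scalar or vector).
#' @param goals optional vector of Goal values (same length).
#' @return `"a_better"`, `"b_better"` or `"tie"`.
#' @export
lexicographic_compare <- function(a, b, tolerance = 1e-3, goals = NULL) {
  if (length(a) != length(b))
    wp_stop("objective vectors differ in length: ", length(a), " vs ", length(b))
  tol <- rep_len(tolerance, length(a))
  walk <- function(a, b) {
    for (i in seq_along(a)) {
      if (is.na(a[i]) && is.na(b[i])) next
      if (is.na(a[i]) || is.na(b[i]))
        wp_stop("objective ", i, " is NA in one vector only")
      if (abs(a[i] - b[i]) <= tol[i]) next
      return(if (a[i] < b[i]) "a_better" else "b_better")
    }
    "tie"
  }
  if (!is.null(goals)) {
    if (length(goals) != length(a))
      wp_stop("goals must match the objective vectors in length")
    res <- walk(pmax(a, goals), pmax(b, goals))
    if (res != "tie") return(res)
  }
  walk(a, b)
}

#' Greedy integrated beam-angle optimization
#'
#' Starting from the empty beam set, adds `n_beams` gantry angles one at a
#' time. Each iteration runs the full two-round lexicographic optimization
#' for every unused candidate added to the current set and keeps the
#' candidate whose final objective vector is lexicographically best; ties go
#' to the earliest candidate in the ordering. The influence matrix for the
#' whole candidate set is computed once and subset per evaluation.
#'
#' @param phantom a `phantom`.
#' @param wishlist a `wish_list`.
#' @param candidates candidate gantry angles (see [candidate_angles()]).
#' @param n_beams number of beams to select (or a vector; plans are then
#'   returned for every count along one shared greedy trajectory, emulating
#'   a beam-count study in a single optimization run).
#' @param geometry a [beam_geometry()].
#' @param score_control [stage_control()] used during candidate scoring
#'   (looser than the final solve by default).
#' @param final_control [stage_control()] for the final plan solve(s).
#' @param compare_tolerance tolerance of [lexicographic_compare()] during
#'   scoring.
#' @param influence optional precomputed influence matrix over `candidates`.
#' @return object of class `bao_result`: list with `selected_angles` (in
#'   order of addition), `iteration_scores` (per iteration, named list
#'   angle -> objective vector), `plan` (final `fluence_plan` at
#'   `max(n_beams)`), `plans_by_count` (named list, one plan per requested
#'   beam count), `n_beams`.
#' @export
greedy_bao <- function(phantom, wishlist, candidates, n_beams = 6,
                       geometry = beam_geometry(),
                       score_control = stage_control(gap_tol = 1e-5, mu = 100),
                       final_control = stage_control(),
                       compare_tolerance = 1e-3,
                       influence = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(wishlist, "wish_list"))
  counts <- sort(unique(as.integer(n_beams)))
  k_max <- max(counts)
  if (k_max > length(candidates))
    wp_stop("n_beams = ", k_max, " exceeds ", length(candidates), " candidates")
  derived <- derive_structures(phantom)
  if (is.null(influence))
    influence <- compute_influence(phantom, candidates, geometry)
  goals <- wishlist$objectives$goal

  selected <- integer(0)
  iteration_scores <- list()
  for (k in seq_len(k_max)) {
    pool <- setdiff(seq_along(candidates), selected)
    best <- NULL; best_vec <- NULL
    scores <- list()
    n_ok <- 0L
    for (ci in pool) {
      sub <- subset_influence(influence, c(selected, ci))
      vec <- tryCatch(
        suppressMessages(lexicographic_solve(sub, wishlist, phantom, derived,
                                             control = score_control))$achieved,
        error = function(e) NULL)
      scores[[as.character(candidates[ci])]] <- vec
      if (is.null(vec)) next
      n_ok <- n_ok + 1L
      if (is.null(best) ||
          lexicographic_compare(vec, best_vec, compare_tolerance,
                                goals = goals) == "a_better") {
        best <- ci; best_vec <- vec
      }
    }
    if (n_ok == 0L)
      wp_stop("all candidate angles infeasible at beam ", k,
              class = "wishplan_infeasible")
    selected <- c(selected, best)
    iteration_scores[[k]] <- scores
  }

  plans <- list()
  for (ct in counts) {
    sub <- subset_influence(influence, selected[seq_len(ct)])
    plans[[as.character(ct)]] <-
      suppressMessages(lexicographic_solve(sub, wishlist, phantom, derived,
                                           control = final_control))
  }
  structure(list(selected_angles = candidates[selected],
                 iteration_scores = iteration_scores,
                 plan = plans[[as.character(k_max)]],
                 plans_by_count = plans,
                 n_beams = counts),
            class = "bao_result")
}

#' Plan at fixed user-supplied beam angles (BAO switched off)
#'
#' Runs the identical two-round lexicographic optimization at a fixed beam
#' configuration, the no-BAO comparison arm.
#'
#' @param phantom a `phantom`.
#' @param wishlist a `wish_list`.
#' @param fixed_angles gantry angles, degrees.
#' @param geometry a [beam_geometry()].
#' @param control a [stage_control()].
#' @return a `fluence_plan`.
#' @export
plan_without_bao <- function(phantom, wishlist, fixed_angles,
                             geometry = beam_geometry(),
                             control = stage_control()) {
  influence <- compute_influence(phantom, fixed_angles, geometry)
  suppressMessages(lexicographic_solve(influence, wishlist, phantom,
                                       control = control))
}

#' Template beam arrangement
#'
#' A 6-beam arrangement with weight on the anterior-posterior directions and
#' two ipsilateral oblique/lateral fields, the kind of template manual
#' planners adapt per patient.
#'
#' @param laterality `"right"` or `"left"`.
#' @return numeric gantry angles, degrees.
#' @export
template_angles <- function(laterality) {
  base <- c(0, 25, 180, 205, 230, 330)  # right-sided template
  if (laterality == "right") sort(base) else sort((360 - base) %% 360)
}

#' @export
print.bao_result <- function(x, ...) {
  cat("bao_result: selected angles (order of addition): ",
      paste(round(x$selected_angles), collapse = ", "), " deg\n", sep = "")
  cat("beam counts solved:", paste(x$n_beams, collapse = ", "), "\n")
  invisible(x)
}
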