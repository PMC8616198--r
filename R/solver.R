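#' Stage solver control parameters
#'
#' @param gap_tol target barrier duality gap (absolute, objective units; for
#'   the LTCP objective the gap applies in log space, i.e. relatively).
#' @param mu barrier parameter multiplier per outer iteration.
#' @param max_newton Newton iteration cap per centering step.
#' @param t0 initial barrier parameter; chosen from the problem scale when
#'   `NULL`.
#' @return a `stage_control` list.
#' @export
stage_control <- function(gap_tol = 1e-8, mu = 30, max_newton = 60, t0 = NULL) {
  structure(list(gap_tol = gap_tol, mu = mu, max_newton = max_newton, t0 = t0),
            class = "stage_control")
}

#' Stage objectives
#'
#' Constructors for the three objective types of a wish-list stage, expressed
#' on the fluence vector through a (dense) structure dose matrix `D`
#' (structure voxels by beamlets): `objective_mean` minimizes the structure
#' mean dose, `objective_max` the structure maximum dose (via an auxiliary
#' bound variable), `objective_ltcp` the LTCP (minimized in log space, which
#' has the same minimizer and far better numerical behavior).
#' `objective_linear` takes an explicit coefficient vector.
#'
#' @param D dense matrix mapping fluence to structure voxel doses.
#' @param c coefficient vector (for `objective_linear`).
#' @param alpha,ref_Gy LTCP parameters.
#' @return a `stage_objective`.
#' @export
objective_mean <- function(D) {
  structure(list(type = "linear", c = colMeans(D)), class = "stage_objective")
}

#' @rdname objective_mean
#' @export
objective_linear <- function(c) {
  structure(list(type = "linear", c = c), class = "stage_objective")
}

#' @rdname objective_mean
#' @export
objective_max <- function(D) {
  structure(list(type = "max", D = D), class = "stage_objective")
}

#' @rdname objective_mean
#' @export
objective_ltcp <- function(D, alpha, ref_Gy) {
  structure(list(type = "ltcp", D = D, alpha = alpha, ref = ref_Gy),
            class = "stage_objective")
}

#' Stage constraint set
#'
#' Linear inequalities `A x <= b` on the fluence plus optional LTCP-type
#' upper bounds, each `list(D=, alpha=, ref=, bound=)` meaning
#' `LTCP(D x) <= bound`.
#'
#' @param A matrix (rows are constraints) or `NULL`.
#' @param b right-hand sides.
#' @param lse list of LTCP bound constraints.
#' @return a `stage_constraints` object.
#' @export
stage_constraints <- function(A = NULL, b = numeric(0), lse = list()) {
  if (is.null(A)) A <- matrix(0, 0, 0)
  structure(list(A = as.matrix(A), b = as.numeric(b), lse = lse),
            class = "stage_constraints")
}

# strict feasibility margin check; returns min slack (negative = infeasible)
stage_min_slack <- function(x, cons) {
  s <- min(x)
  if (nrow(cons$A) > 0) s <- min(s, min(cons$b - as.numeric(cons$A %*% x)))
  for (lc in cons$lse) {
    v <- ltcp(as.numeric(lc$D %*% x), lc$alpha, lc$ref)
    s <- min(s, lc$bound - v)
  }
  s
}

# find a strictly feasible start for upper-bound-dominated problems; falls
# back to a phase-1 solve for general linear constraints
stage_feasible_start <- function(cons, n, x0 = NULL) {
  if (!is.null(x0)) {
    x0 <- pmax(x0, 1e-12)
    if (stage_min_slack(x0, cons) > 0) return(x0)
  }
  for (eps in 10^seq(-2, -10)) {
    x <- rep(eps, n)
    if (stage_min_slack(x, cons) > 0) return(x)
  }
  if (length(cons$lse))
    wp_stop("no strictly feasible start found for a stage with LTCP bounds; ",
            "supply a warm start")
  phase1_start(cons, n)
}

# phase 1: minimize the shifted slack variable s' in
#   A x - s' <= b - shift,  x >= 0, s' >= 0;
# an interior point exists iff the optimum is below `shift`
phase1_start <- function(cons, n) {
  m <- nrow(cons$A)
  shift <- max(1, 0.1 * max(abs(cons$b), 0))
  A1 <- cbind(cons$A, -1)
  b1 <- cons$b - shift
  # start: x tiny, s' large enough to cover all violations
  x <- rep(1e-6, n)
  viol <- max(as.numeric(cons$A %*% x) - cons$b, 0)
  s0 <- viol + 2 * shift
  res <- .barrier_solve_cpp(c(rep(0, n), 1), FALSE, list(), A1, b1, list(),
                            c(x, s0), 1, 30, 1e-6 * shift, 200L)
  xs <- res$x
  attained <- xs[n + 1]
  if (attained >= shift * (1 - 1e-9)) {
    viol_rows <- which(as.numeric(cons$A %*% xs[seq_len(n)]) - cons$b > 0)
    wp_stop("constraint set has no interior; most binding rows: ",
            paste(head(viol_rows, 5), collapse = ", "),
            class = "wishplan_infeasible")
  }
  xf <- pmax(xs[seq_len(n)], 1e-12)
  if (stage_min_slack(xf, cons) <= 0)
    wp_stop("phase-1 produced a boundary point; constraint interior too thin",
            class = "wishplan_infeasible")
  xf
}

#' Solve one convex stage problem
#'
#' Minimizes a [stage objective][objective_mean] over nonnegative fluence
#' subject to a [stage_constraints()] set, using the package's log-barrier
#' interior-point method. This is the single-objective building block of the
#' lexicographic optimizer; it is exposed for testing and for custom
#' pipelines.
#'
#' @param objective a `stage_objective`.
#' @param constraints a `stage_constraints`.
#' @param n number of fluence variables.
#' @param x0 optional strictly feasible warm start.
#' @param control a [stage_control()].
#' @return list with `value` (solver-optimal objective), `x` (fluence),
#'   `status`, `gap`, `newton_iters`.
#' @export
solve_stage <- function(objective, constraints, n, x0 = NULL,
                        control = stage_control()) {
  stopifnot(inherits(objective, "stage_objective"),
            inherits(constraints, "stage_constraints"))
  cons <- constraints
  if (nrow(cons$A) > 0 && ncol(cons$A) != n)
    wp_stop("constraint matrix has ", ncol(cons$A), " columns, expected ", n)
  # warm starts go straight to the solver (it absorbs round-off-level
  # boundary violations itself); cold starts are constructed here
  if (is.null(x0)) x0 <- stage_feasible_start(cons, n, NULL) else x0 <- pmax(x0, 1e-12)

  aux <- objective$type == "max"
  if (aux) {
    # epigraph form: minimize t subject to D x - t <= 0
    nD <- nrow(objective$D)
    A <- rbind(cbind(if (nrow(cons$A)) cons$A else matrix(0, 0, n), 0),
               cbind(objective$D, -1))
    b <- c(cons$b, rep(0, nD))
    lse <- lapply(cons$lse, function(lc) {
      lc$D <- cbind(lc$D, 0); lc
    })
    t0v <- max(as.numeric(objective$D %*% x0)) * 1.001 + 1e-6
    x_in <- c(x0, t0v)
    cvec <- c(rep(0, n), 1)
    has_lse <- FALSE
    lse_obj <- list()
  } else {
    A <- cons$A
    b <- cons$b
    lse <- cons$lse
    x_in <- x0
    if (objective$type == "linear") {
      cvec <- objective$c
      has_lse <- FALSE
      lse_obj <- list()
    } else {
      cvec <- rep(0, length(x0))
      has_lse <- TRUE
      lse_obj <- list(D = objective$D, alpha = objective$alpha,
                      ref = objective$ref)
    }
  }
  lse_in <- lapply(lse, function(lc)
    list(D = lc$D, alpha = lc$alpha, ref = lc$ref, bound = log(lc$bound)))

  f0 <- if (has_lse) {
    log(ltcp(as.numeric(objective$D %*% x0), objective$alpha, objective$ref))
  } else sum(cvec * x_in)
  m_total <- nrow(A) + length(x_in) + length(lse_in)
  t0 <- control$t0 %||% max(1, m_total / max(1, abs(f0)))

  res <- .barrier_solve_cpp(cvec, has_lse, lse_obj, A, b, lse_in,
                            x_in, t0, control$mu, control$gap_tol,
                            as.integer(control$max_newton))
  if (identical(res$status, "infeasible_start")) {
    # warm start genuinely violated the constraint set; rebuild a cold one
    x0 <- stage_feasible_start(cons, n, NULL)
    x_in[seq_len(n)] <- x0
    if (aux) x_in[n + 1] <- max(as.numeric(objective$D %*% x0)) * 1.001 + 1e-6
    res <- .barrier_solve_cpp(cvec, has_lse, lse_obj, A, b, lse_in,
                              x_in, t0, control$mu, control$gap_tol,
                              as.integer(control$max_newton))
  }
  if (!res$status %in% "optimal")
    wp_stop("stage solver failed with status '", res$status, "'",
            class = "wishplan_solver_error")
  x <- res$x[seq_len(n)]
  # for epigraph (Max) stages report the maximum actually achieved by the
  # fluence, not the auxiliary variable, which sits above it by its barrier
  # slack
  value <- if (aux) max(as.numeric(objective$D %*% x)) else res$value
  list(value = value, x = x, status = res$status, gap = res$gap,
       newton_iters = res$newton_iters)
}
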