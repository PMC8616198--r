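# Independent oracles used across the test suite.
#
# The lexicographic oracle re-implements the two-round wish-list procedure
# from scratch on top of generic solvers (nloptr::slsqp for stages involving
# the LTCP term, pracma::linprog for pure-LP stage chains), sharing no code
# with the package's interior-point solver.

# ---- generic stage solve via slsqp --------------------------------------
# minimizes a stage objective subject to A x <= b, x >= 0 and optional LTCP
# bounds; objective spec: list(type = "linear"|"max"|"ltcp", ...)
oracle_stage_slsqp <- function(obj, A, b, lse, n, x_start) {
  aux <- obj$type == "max"
  nz <- n + as.integer(aux)
  if (is.null(A)) A <- matrix(0, 0, n)
  if (aux) {
    A2 <- rbind(cbind(A, 0), cbind(obj$D, -1))
    b2 <- c(b, rep(0, nrow(obj$D)))
    lse2 <- lapply(lse, function(lc) { lc$D <- cbind(lc$D, 0); lc })
    z0 <- c(x_start, max(as.numeric(obj$D %*% x_start)) * 1.01 + 1e-3)
    fn <- function(z) z[nz]
    gr <- function(z) { g <- numeric(nz); g[nz] <- 1; g }
  } else {
    A2 <- A; b2 <- b; lse2 <- lse
    z0 <- x_start
    if (obj$type == "linear") {
      fn <- function(z) sum(obj$c * z)
      gr <- function(z) obj$c
    } else {
      fn <- function(z) log(mean(exp(-obj$alpha * (as.numeric(obj$D %*% z) - obj$ref))))
      gr <- function(z) {
        e <- exp(-obj$alpha * (as.numeric(obj$D %*% z) - obj$ref))
        -obj$alpha * as.numeric(crossprod(obj$D, e / sum(e)))
      }
    }
  }
  hin <- function(z) {
    v <- c(as.numeric(A2 %*% z) - b2, -z)
    for (lc in lse2)
      v <- c(v, log(mean(exp(-lc$alpha * (as.numeric(lc$D %*% z) - lc$ref)))) -
               log(lc$bound))
    v
  }
  hinjac <- function(z) {
    J <- rbind(A2, -diag(nz))
    for (lc in lse2) {
      e <- exp(-lc$alpha * (as.numeric(lc$D %*% z) - lc$ref))
      J <- rbind(J, matrix(-lc$alpha * as.numeric(crossprod(lc$D, e / sum(e))), 1))
    }
    J
  }
  o <- nloptr::slsqp(z0, fn, gr, hin = hin, hinjac = hinjac,
                     control = list(xtol_rel = 1e-14, maxeval = 20000),
                     deprecatedBehavior = FALSE)
  # restart polishing: slsqp occasionally stalls just short of the optimum
  for (r in 1:3) {
    o2 <- nloptr::slsqp(o$par, fn, gr, hin = hin, hinjac = hinjac,
                        control = list(xtol_rel = 1e-14, maxeval = 20000),
                        deprecatedBehavior = FALSE)
    if (o2$value > o$value - 1e-10 * (1 + abs(o$value))) { o <- o2; break }
    o <- o2
  }
  x <- o$par[seq_len(n)]
  val <- if (obj$type == "ltcp") exp(fn(o$par)) else if (aux)
    max(as.numeric(obj$D %*% x)) else o$value
  list(value = val, x = x, convergence = o$convergence)
}

# pure-LP stage via pracma::linprog (simplex); constraints A x <= b, x >= 0
oracle_stage_linprog <- function(obj, A, b, n) {
  aux <- obj$type == "max"
  if (is.null(A)) A <- matrix(0, 0, n)
  if (aux) {
    A2 <- rbind(cbind(A, 0), cbind(obj$D, -1))
    b2 <- c(b, rep(0, nrow(obj$D)))
    cc <- c(rep(0, n), 1)
  } else {
    A2 <- A; b2 <- b; cc <- obj$c
  }
  o <- pracma::linprog(cc, A = A2, b = b2, maxiter = 200, maximize = FALSE)
  x <- o$x[seq_len(n)]
  val <- if (aux) max(as.numeric(obj$D %*% x)) else sum(cc * x)
  list(value = val, x = x)
}

# ---- scripted two-round lexicographic procedure -------------------------
# problem: list with
#   n          number of beamlets
#   hard       list of list(D=, type="Max"/"Mean", bound=)
#   objectives data.frame-ish list of entries:
#              list(priority=, type="Mean"/"Max"/"LTCP", D=, goal=,
#                   sufficient= (NA if none))
#   ltcp       list(alpha=, ref=) used by LTCP entries
#   relax      relaxation factor
oracle_lexicographic <- function(prob, solver = c("slsqp", "linprog")) {
  solver <- match.arg(solver)
  n <- prob$n
  bounds <- list()  # per priority: list(entry=, bound=)

  assemble <- function(skip_priority = NA) {
    A <- NULL; b <- numeric(0); lse <- list()
    add_lin <- function(D, type, bound) {
      if (type == "Mean") { A <<- rbind(A, colMeans(D)); b <<- c(b, bound) }
      else if (type == "MeanLower") { A <<- rbind(A, -colMeans(D)); b <<- c(b, -bound) }
      else { A <<- rbind(A, D); b <<- c(b, rep(bound, nrow(D))) }
    }
    for (h in prob$hard) add_lin(h$D, h$type, h$bound)
    for (bd in bounds) {
      if (!is.na(skip_priority) && bd$entry$priority == skip_priority) next
      if (bd$entry$type == "LTCP")
        lse[[length(lse) + 1]] <- list(D = bd$entry$D, alpha = prob$ltcp$alpha,
                                       ref = prob$ltcp$ref, bound = bd$bound)
      else add_lin(bd$entry$D, bd$entry$type, bd$bound)
    }
    # same internal slack policy as the implementation, so the two chains
    # solve identical stage problems
    if (length(b)) b <- b + 1e-6 * abs(b) + 1e-12
    lse <- lapply(lse, function(lc) { lc$bound <- lc$bound * (1 + 1e-6); lc })
    list(A = A, b = b, lse = lse)
  }

  stage_obj <- function(entry) {
    switch(entry$type,
           Mean = list(type = "linear", c = colMeans(entry$D)),
           Max = list(type = "max", D = entry$D),
           LTCP = list(type = "ltcp", D = entry$D, alpha = prob$ltcp$alpha,
                       ref = prob$ltcp$ref))
  }

  solve1 <- function(entry, cs, x) {
    if (solver == "linprog" && length(cs$lse) == 0 && entry$type != "LTCP") {
      # pracma's simplex can hit degenerate bases; fall back to slsqp then
      res <- tryCatch(oracle_stage_linprog(stage_obj(entry), cs$A, cs$b, n),
                      error = function(e) NULL)
      if (!is.null(res)) return(res)
    }
    # best of two starts; slsqp can stall from a single warm start
    r1 <- oracle_stage_slsqp(stage_obj(entry), cs$A, cs$b, cs$lse, n, x)
    r2 <- oracle_stage_slsqp(stage_obj(entry), cs$A, cs$b, cs$lse, n,
                             0.5 * x + 0.5 * mean(x))
    if (r2$value < r1$value) r2 else r1
  }

  x <- rep(1e-3, n)
  log_rows <- list()
  for (entry in prob$objectives) {  # round 1
    cs <- assemble()
    res <- solve1(entry, cs, x)
    x <- pmax(res$x, 0)
    bound <- if (res$value <= entry$goal) entry$goal else res$value * prob$relax
    bounds[[as.character(entry$priority)]] <- list(entry = entry, bound = bound)
    log_rows[[length(log_rows) + 1]] <-
      data.frame(round = 1, priority = entry$priority, achieved = res$value,
                 bound = bound)
  }
  for (entry in prob$objectives) {  # round 2
    if (!is.na(entry$sufficient)) next
    cs <- assemble(skip_priority = entry$priority)
    res <- solve1(entry, cs, x)
    x <- pmax(res$x, 0)
    bounds[[as.character(entry$priority)]] <- list(entry = entry, bound = res$value)
    log_rows[[length(log_rows) + 1]] <-
      data.frame(round = 2, priority = entry$priority, achieved = res$value,
                 bound = res$value)
  }
  list(x = x, log = do.call(rbind, log_rows))
}

# ---- random small planning instances ------------------------------------
# random nonnegative influence-like matrices and a small wish-list; used for
# solver and lexicographic equivalence testing.  `with_ltcp = FALSE` builds a
# pure-LP chain (coverage kept by a hard lower bound on the target mean).
random_stage_instance <- function(seed, n_beamlets = 12, with_ltcp = TRUE) {
  set.seed(seed)
  n <- n_beamlets
  # dense strictly positive transfer matrices keep the stage optima unique
  # and well conditioned
  mk <- function(rows) matrix(runif(rows * n, 0.05, 1.5), rows, n)
  ptv <- mk(8) + 0.8          # target well covered by all beamlets
  oar1 <- mk(6)
  oar2 <- mk(5)
  ring <- mk(7) * 0.6
  hard <- list(list(D = ptv, type = "Max", bound = 66 * 1.02),
               list(D = ptv, type = "Mean", bound = 66 * 0.997),
               list(D = ring, type = "Max", bound = 0.8 * 66))
  objectives <- list()
  if (with_ltcp) {
    objectives[[1]] <- list(priority = 1, type = "LTCP", D = ptv,
                            goal = 0.15, sufficient = 0.15)
  } else {
    # coverage as a hard lower bound on the target mean dose
    hard[[length(hard) + 1]] <- list(D = ptv, type = "MeanLower", bound = 55)
  }
  k <- length(objectives)
  objectives[[k + 1]] <- list(priority = k + 1, type = "Mean", D = oar1,
                              goal = runif(1, 2, 8), sufficient = NA)
  objectives[[k + 2]] <- list(priority = k + 2, type = "Max", D = ring,
                              goal = runif(1, 20, 30), sufficient = NA)
  objectives[[k + 3]] <- list(priority = k + 3, type = "Mean", D = oar2,
                              goal = 0, sufficient = NA)
  list(n = n, hard = hard, objectives = objectives,
       ltcp = list(alpha = 0.8, ref = 62.7),
       relax = 1.03)
}

# run the package's lexicographic procedure on a raw oracle-style problem
# (bypassing phantom/influence plumbing) so the two can be compared head on
wishplan_lexicographic_raw <- function(prob, control = stage_control()) {
  n <- prob$n
  bounds <- list()
  assemble <- function(skip_priority = NA) {
    A <- NULL; b <- numeric(0); lse <- list()
    add_lin <- function(D, type, bound) {
      if (type == "Mean") { A <<- rbind(A, colMeans(D)); b <<- c(b, bound) }
      else if (type == "MeanLower") { A <<- rbind(A, -colMeans(D)); b <<- c(b, -bound) }
      else { A <<- rbind(A, D); b <<- c(b, rep(bound, nrow(D))) }
    }
    for (h in prob$hard) add_lin(h$D, h$type, h$bound)
    for (bd in bounds) {
      if (!is.na(skip_priority) && bd$entry$priority == skip_priority) next
      if (bd$entry$type == "LTCP")
        lse[[length(lse) + 1]] <- list(D = bd$entry$D, alpha = prob$ltcp$alpha,
                                       ref = prob$ltcp$ref, bound = bd$bound)
      else add_lin(bd$entry$D, bd$entry$type, bd$bound)
    }
    # row-level slack so warm starts stay strictly feasible
    b <- b + 1e-6 * abs(b) + 1e-12
    lse <- lapply(lse, function(lc) { lc$bound <- lc$bound * (1 + 1e-6); lc })
    stage_constraints(A, b, lse)
  }
  stage_obj <- function(entry) {
    switch(entry$type,
           Mean = objective_linear(colMeans(entry$D)),
           Max = objective_max(entry$D),
           LTCP = objective_ltcp(entry$D, prob$ltcp$alpha, prob$ltcp$ref))
  }
  # objective evaluators used for the bound-protection trace
  eval_entry <- function(entry, x) {
    d <- as.numeric(entry$D %*% x)
    switch(entry$type, Mean = mean(d), Max = max(d),
           LTCP = mean(exp(-prob$ltcp$alpha * (d - prob$ltcp$ref))))
  }
  x <- NULL
  log_rows <- list()
  trace <- list()
  record <- function(round, entry, res, bound) {
    log_rows[[length(log_rows) + 1]] <<-
      data.frame(round = round, priority = entry$priority,
                 achieved = res$value, bound = bound)
    trace[[length(trace) + 1]] <<-
      list(round = round, priority = entry$priority, x = res$x,
           bounds = lapply(bounds, function(bd)
             list(priority = bd$entry$priority, bound = bd$bound,
                  value = eval_entry(bd$entry, res$x))))
  }
  for (entry in prob$objectives) {
    res <- solve_stage(stage_obj(entry), assemble(), n, x, control)
    x <- res$x
    bound <- if (res$value <= entry$goal) entry$goal else res$value * prob$relax
    record(1, entry, res, bound)
    bounds[[as.character(entry$priority)]] <- list(entry = entry, bound = bound)
  }
  for (entry in prob$objectives) {
    if (!is.na(entry$sufficient)) next
    res <- solve_stage(stage_obj(entry), assemble(entry$priority), n, x, control)
    x <- res$x
    record(2, entry, res, res$value)
    bounds[[as.character(entry$priority)]] <- list(entry = entry, bound = res$value)
  }
  list(x = x, log = do.call(rbind, log_rows), trace = trace)
}

# literal enumeration over all 2^n sign assignments
enumerate_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p.value = 1))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.numeric(signs %*% r)
  p_le <- mean(Vs <= V + 1e-9)
  p_ge <- mean(Vs >= V - 1e-9)
  list(statistic = V, p.value = min(1, 2 * min(p_le, p_ge)))
}

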