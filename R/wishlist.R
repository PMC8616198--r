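#' Build the lung wish-list
#'
#' Returns the prioritized wish-list used for LA-NSCLC-style planning: seven
#' hard constraints (PTV maximum and mean caps, spinal canal and brachial
#' plexus maxima, conformity shell and external ring caps) and thirteen
#' prioritized objectives. Priority 1 minimizes the logarithmic tumor control
#' probability (LTCP) of the PTV; lower priorities trade off lung, heart and
#' esophagus mean dose against conformity shell maxima. Goal values encode
#' "good enough to move on"; a Sufficient value marks objectives that are not
#' pushed further in the second lexicographic round.
#'
#' LTCP settings depend on the prescription: reference dose `0.95 * D_p`,
#' cell-kill slope `alpha` = 0.85 /Gy at 60 Gy and 0.8 /Gy at 66 or 70 Gy,
#' goal (= sufficient) 0.14 at 60 Gy and 0.12 otherwise.
#'
#' @param D_p prescription dose; one of 60, 66, 70 Gy.
#' @param relaxation_factor multiplicative relaxation applied to an achieved
#'   objective value when its goal was not met (default 1.03).
#' @return object of class `wish_list`: list with `D_p`, `hard_constraints`
#'   (data.frame: structure, type, limit_Gy), `objectives` (data.frame:
#'   priority, structure, type, goal, sufficient), `ltcp`
#'   (list: alpha, ref_Gy), `relaxation_factor`.
#' @export
build_wishlist <- function(D_p, relaxation_factor = 1.03) {
  if (!D_p %in% c(60, 66, 70)) wp_stop("unsupported prescription D_p = ", D_p)
  if (relaxation_factor <= 1) wp_stop("relaxation_factor must be > 1")
  hard <- data.frame(
    structure = c("PTV", "PTV", "spinal_canal", "brachial_plexus",
                  "shell_1cm", "shell_7cm", "external_ring"),
    type = c("Max", "Mean", "Max", "Max", "Max", "Max", "Max"),
    limit_Gy = c(D_p * 1.02, D_p * 0.997, 47, 60, D_p, D_p * 0.75, D_p * 0.8),
    stringsAsFactors = FALSE
  )
  ltcp_goal <- if (D_p == 60) 0.14 else 0.12
  obj <- data.frame(
    priority = 1:13,
    structure = c("PTV", "lungs", "shell_3mm", "shell_1cm", "shell_7cm",
                  "lungs", "heart", "esophagus", "shell_3cm", "shell_7cm",
                  "lungs", "heart", "esophagus"),
    type = c("LTCP", "Mean", "Max", "Max", "Max", "Mean", "Mean", "Mean",
             "Max", "Max", "Mean", "Mean", "Mean"),
    goal = c(ltcp_goal, 19, D_p, D_p * 0.9, D_p * 0.65, 13, 13, 18,
             D_p * 0.75, D_p * 0.55, 0, 0, 0),
    sufficient = c(ltcp_goal, NA, D_p, D_p * 0.9, NA, NA, NA, NA,
                   NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(list(D_p = D_p, hard_constraints = hard, objectives = obj,
                 ltcp = list(alpha = if (D_p == 60) 0.85 else 0.8,
                             ref_Gy = D_p * 0.95),
                 relaxation_factor = relaxation_factor),
            class = "wish_list")
}

#' Logarithmic tumor control probability (LTCP)
#'
#' `LTCP = (1/m) * sum_j exp(-alpha * (d_j - ref))` over the PTV voxel doses
#' `d_j`. Equals 1 on a uniform dose at the reference, is strictly decreasing
#' in every voxel dose and convex in the dose vector; low values indicate
#' good coverage.
#'
#' @param ptv_doses dose values over the PTV voxels, Gy.
#' @param alpha cell-kill slope, per Gy.
#' @param ref_Gy reference (prescription-derived) dose, Gy.
#' @return scalar LTCP.
#' @export
ltcp <- function(ptv_doses, alpha, ref_Gy) {
  if (!length(ptv_doses)) wp_stop("ltcp: empty PTV dose vector")
  if (alpha <= 0 || ref_Gy <= 0) wp_stop("ltcp: alpha and ref_Gy must be > 0")
  mean(exp(-alpha * (ptv_doses - ref_Gy)))
}

#' Evaluate one wish-list objective on a dose distribution
#'
#' Dispatches on the objective type: `Mean` and `Max` return Gy over the
#' structure's voxels, `LTCP` returns the dimensionless [ltcp()] with the
#' wish-list's prescription-dependent parameters.
#'
#' @param entry one row of `wishlist$objectives` (data.frame or list with
#'   `structure`, `type`).
#' @param dose dose vector over the grid, Gy.
#' @param phantom the `phantom`.
#' @param wishlist the `wish_list` (for LTCP parameters).
#' @param derived derived structures ([derive_structures()]); computed when
#'   `NULL`.
#' @return scalar objective value.
#' @export
evaluate_objective <- function(entry, dose, phantom, wishlist, derived = NULL) {
  mask <- resolve_structure(entry$structure, phantom, derived)
  d <- dose[as.vector(mask)]
  if (!length(d)) wp_stop("structure '", entry$structure, "' is empty")
  switch(entry$type,
         Mean = mean(d),
         Max = max(d),
         LTCP = ltcp(d, wishlist$ltcp$alpha, wishlist$ltcp$ref_Gy),
         wp_stop("unknown objective type '", entry$type, "'"))
}

#' Wish-list YAML round-trip
#'
#' Serializes a wish-list so that site-specific lists can be stored and
#' edited as plain text.
#'
#' @param wishlist a `wish_list`.
#' @param path file path.
#' @export
write_wishlist_yaml <- function(wishlist, path) {
  yaml::write_yaml(list(
    D_p = wishlist$D_p,
    relaxation_factor = wishlist$relaxation_factor,
    ltcp = wishlist$ltcp,
    hard_constraints = lapply(seq_len(nrow(wishlist$hard_constraints)), function(i)
      as.list(wishlist$hard_constraints[i, ])),
    objectives = lapply(seq_len(nrow(wishlist$objectives)), function(i)
      as.list(wishlist$objectives[i, ]))
  ), path)
  invisible(path)
}

#' @rdname write_wishlist_yaml
#' @export
read_wishlist_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  hard <- do.call(rbind, lapply(y$hard_constraints, function(r)
    data.frame(structure = r$structure, type = r$type,
               limit_Gy = as.numeric(r$limit_Gy), stringsAsFactors = FALSE)))
  obj <- do.call(rbind, lapply(y$objectives, function(r)
    data.frame(priority = as.integer(r$priority), structure = r$structure,
               type = r$type, goal = as.numeric(r$goal),
               sufficient = if (is.null(r$sufficient)) NA_real_ else as.numeric(r$sufficient),
               stringsAsFactors = FALSE)))
  wl <- structure(list(D_p = y$D_p, hard_constraints = hard, objectives = obj,
                       ltcp = list(alpha = y$ltcp$alpha, ref_Gy = y$ltcp$ref_Gy),
                       relaxation_factor = y$relaxation_factor),
                  class = "wish_list")
  validate_wishlist(wl)
  wl
}

#' Validate wish-list invariants
#'
#' Priorities must be unique and contiguous from 1; goal/sufficient values
#' must be finite where present.
#'
#' @param wishlist a `wish_list`.
#' @return the wish-list, invisibly.
#' @export
validate_wishlist <- function(wishlist) {
  pr <- wishlist$objectives$priority
  if (!identical(sort(pr), seq_along(pr)) || anyDuplicated(pr))
    wp_stop("objective priorities must be unique and contiguous from 1")
  if (any(!is.finite(wishlist$objectives$goal)))
    wp_stop("all goal values must be finite")
  invisible(wishlist)
}

#' @export
print.wish_list <- function(x, ...) {
  cat("wish_list (D_p =", x$D_p, "Gy, relaxation", x$relaxation_factor, ")\n")
  cat("hard constraints:\n"); print(x$hard_constraints, row.names = FALSE)
  cat("objectives:\n"); print(x$objectives, row.names = FALSE)
  invisible(x)
}
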