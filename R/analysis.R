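#' Ideal levels of the two objectives
#'
#' Solves each single-objective model independently over the full constraint
#' set; the optima are the ideal levels `R_1` (minimum weighted waiting
#' loss) and `R_2` (minimum logistics cost).  `R_2` is always 0: the empty
#' plan opens nothing and moves nothing at zero cost, and every cost
#' coefficient is non-negative — but it is computed by the solver, not
#' assumed.
#'
#' @param instance a [ppe_instance()].
#' @param options a [bnb_options()].
#' @param use_improved use the warm-start solver per stage.
#' @return List with `R1` and `R2` (yuan) and the two `solve_result`s.
#' @export
ideal_levels <- function(instance, options = bnb_options(),
                         use_improved = TRUE) {
  f <- build_formulation(instance)
  solver <- if (use_improved) improved_solve else
    function(...) branch_and_bound(...)
  s1 <- solver(f, objective = "G1", options = options)
  s2 <- solver(f, objective = "G2", options = options)
  if (s1$status != "optimal" || s2$status != "optimal")
    stop("single-objective solve failed: ", s1$status, " / ", s2$status)
  list(R1 = s1$objective, R2 = s2$objective, solve_G1 = s1, solve_G2 = s2)
}

#' Worst (maximum) values of the two objectives
#'
#' Upper bounds used for percentage deviations.  The worst waiting loss has
#' the closed form `sum_j sum_k d_jk * lambda_max_k * w_k`: the waiting cost
#' of a delivered kg never exceeds the plateau, so no plan loses more than
#' delivering nothing.  The worst logistics cost is found by maximizing G2
#' as a MILP.  With `cross_check = TRUE` the closed form is also verified by
#' maximizing G1 with the solver.
#'
#' @param instance a [ppe_instance()].
#' @param options a [bnb_options()].
#' @param cross_check also maximize G1 with the solver and verify agreement.
#' @return List with `max_G1`, `max_G2` (yuan) and, if requested,
#'   `max_G1_solved`.
#' @export
worst_values <- function(instance, options = bnb_options(),
                         cross_check = FALSE) {
  plateau <- vapply(instance$curves, `[[`, 0, "plateau")
  max_G1 <- sum(sweep(instance$demand, 2L, plateau * instance$ppe_weight,
                      `*`))
  f <- build_formulation(instance)
  neg <- branch_and_bound(f, objective = -f$obj_G2, options = options)
  if (neg$status != "optimal") stop("G2 maximization failed: ", neg$status)
  max_G2 <- -neg$objective + f$const_G2
  out <- list(max_G1 = max_G1, max_G2 = max_G2)
  if (cross_check) {
    neg1 <- branch_and_bound(f, objective = -f$obj_G1, options = options)
    if (neg1$status != "optimal")
      stop("G1 maximization failed: ", neg1$status)
    out$max_G1_solved <- -neg1$objective + f$const_G1
  }
  out
}

#' Percentage deviation of an objective between its bounds
#'
#' `(current - lower) / (upper - lower)`, the normalized position of an
#' achieved objective value between its ideal (lower) and worst (upper)
#' level.  Scale-invariant: multiplying all three arguments by a positive
#' constant leaves the result unchanged.
#'
#' @param current achieved objective value (yuan).
#' @param lower ideal level (yuan).
#' @param upper worst level (yuan); must satisfy `upper >= lower`.
#' @return Fraction in `[0, 1]` for in-range input.  Degenerate bounds
#'   (`upper == lower`) return 0 with a warning; out-of-range `current` is
#'   allowed but flagged with a warning.
#' @export
percentage_deviation <- function(current, lower, upper) {
  stopifnot(is.numeric(current), is.numeric(lower), is.numeric(upper))
  if (upper < lower) stop("'upper' must be >= 'lower'")
  if (upper == lower) {
    warning("degenerate bounds (upper == lower); returning 0")
    return(0)
  }
  if (current < lower || current > upper)
    warning("'current' lies outside [lower, upper]")
  (current - lower) / (upper - lower)
}

#' Trace the loss-cost tradeoff (Pareto front)
#'
#' Re-solves the lexicographic goal program with the ideal loss level
#' relaxed to `multiplier * R_1` and records the minimum attainable
#' logistics cost at each relaxation.  As the loss ceiling loosens the
#' feasible set grows, so the minimum cost is non-increasing in the
#' multiplier; the resulting points trace the fairness-efficiency frontier.
#'
#' @param instance a [ppe_instance()].
#' @param multipliers numeric vector `>= 1`, ascending.
#' @param options a [bnb_options()].
#' @param use_improved use the warm-start solver per stage.
#' @return A data.frame with one row per multiplier: `multiplier`,
#'   `ideal_level_R1`, `achieved_G1`, `min_G2`, `theta1_plus`,
#'   `theta2_plus`, `nodes`.
#' @export
pareto_trace <- function(instance, multipliers, options = bnb_options(),
                         use_improved = TRUE) {
  stopifnot(all(multipliers >= 1), !is.unsorted(multipliers))
  base <- ideal_levels(instance, options, use_improved)
  rows <- lapply(multipliers, function(kappa) {
    spec <- goal_spec(c(kappa * base$R1, base$R2))
    res <- lexicographic_solve(instance, spec, options,
                               use_improved = use_improved)
    data.frame(multiplier = kappa, ideal_level_R1 = kappa * base$R1,
               achieved_G1 = res$objectives$total_loss,
               min_G2 = res$objectives$logistics_cost,
               theta1_plus = unname(res$theta["theta1_plus"]),
               theta2_plus = unname(res$theta["theta2_plus"]),
               nodes = res$stage1$stats$nodes + res$stage2$stats$nodes)
  })
  do.call(rbind, rows)
}

#' Robustness scan over the ideal loss level
#'
#' Re-solves the goal program across a grid of loss-level multipliers and
#' compares the warm-start solver's stage-2 optimum against an independent
#' reference — the plain branch and bound (default) or, on small instances,
#' the exhaustive two-stage oracle.  The error column is
#' `|improved - reference| / max(1, reference)`; runtimes are recorded but
#' are hardware-dependent and informational only.
#'
#' @param instance a [ppe_instance()].
#' @param multipliers numeric vector `>= 1` of loss-level multipliers.
#' @param options a [bnb_options()].
#' @param reference `"plain"` or `"oracle"`.
#' @param oracle_cap combination cap passed to [oracle_goal()].
#' @return A data.frame: `multiplier`, `objective` (stage-2 theta2+ of the
#'   warm-start solver), `reference`, `error`, `nodes`, `runtime_s`.
#' @export
sensitivity_scan <- function(instance, multipliers,
                             options = bnb_options(),
                             reference = c("plain", "oracle"),
                             oracle_cap = 1e5) {
  reference <- match.arg(reference)
  stopifnot(all(multipliers >= 1))
  base <- ideal_levels(instance, options, use_improved = TRUE)
  rows <- lapply(multipliers, function(kappa) {
    spec <- goal_spec(c(kappa * base$R1, base$R2))
    t0 <- proc.time()[["elapsed"]]
    imp <- lexicographic_solve(instance, spec, options, use_improved = TRUE)
    dt <- proc.time()[["elapsed"]] - t0
    ref_val <- if (reference == "plain") {
      pl <- lexicographic_solve(instance, spec, options,
                                use_improved = FALSE)
      unname(pl$theta["theta2_plus"])
    } else {
      oracle_goal(instance, spec$ideals, cap = oracle_cap)$theta2_plus
    }
    obj <- unname(imp$theta["theta2_plus"])
    data.frame(multiplier = kappa, objective = obj, reference = ref_val,
               error = abs(obj - ref_val) / max(1, abs(ref_val)),
               nodes = imp$stage1$stats$nodes + imp$stage2$stats$nodes,
               runtime_s = dt)
  })
  do.call(rbind, rows)
}
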