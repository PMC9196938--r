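#' Allocation plan: DC openings, vehicle routing and PPE shipments
#'
#' The three decision-variable blocks of the location-allocation model:
#' `open_dc[i]` (binary, whether candidate DC i is rented), `vehicles[h,i,j,m]`
#' (non-negative integer count of vehicles of type m on path h -> i -> j) and
#' `shipped[h,i,j,k,m]` (kg of PPE k carried on that path by that vehicle
#' type).
#'
#' @param instance a [ppe_instance()] giving the dimensions.
#' @param open_dc numeric/logical `[I]`, coerced to 0/1.
#' @param vehicles numeric array `[H, I, J, M]` of integer counts.
#' @param shipped numeric array `[H, I, J, K, M]` of kg.
#' @return An object of class `allocation_plan`.
#' @export
allocation_plan <- function(instance, open_dc, vehicles, shipped) {
  stopifnot(inherits(instance, "ppe_instance"))
  nH <- length(instance$reserve_ids); nI <- length(instance$dc_ids)
  nJ <- length(instance$area_ids); nK <- length(instance$ppe_ids)
  nM <- length(instance$vehicle_ids)

  open_dc <- as.numeric(open_dc)
  if (length(open_dc) != nI || !all(open_dc %in% c(0, 1)))
    stop("'open_dc' must be a 0/1 vector of length |I|")
  vehicles <- check_plan_array(vehicles, c(nH, nI, nJ, nM), "vehicles")
  if (any(abs(vehicles - round(vehicles)) > 1e-9))
    stop("'vehicles' must be integer-valued")
  vehicles <- round(vehicles)
  shipped <- check_plan_array(shipped, c(nH, nI, nJ, nK, nM), "shipped")

  names(open_dc) <- instance$dc_ids
  dimnames(vehicles) <- list(instance$reserve_ids, instance$dc_ids,
                             instance$area_ids, instance$vehicle_ids)
  dimnames(shipped) <- list(instance$reserve_ids, instance$dc_ids,
                            instance$area_ids, instance$ppe_ids,
                            instance$vehicle_ids)
  structure(list(open_dc = open_dc, vehicles = vehicles, shipped = shipped),
            class = "allocation_plan")
}

check_plan_array <- function(x, dims, what) {
  x <- as.array(x * 1.0)
  if (length(dim(x)) != length(dims) || !all(dim(x) == dims))
    stop(sprintf("'%s' must be an array of dim (%s)", what,
                 paste(dims, collapse = ", ")))
  if (any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be finite and non-negative", what))
  x
}

#' The all-zero plan (nothing opened, nothing moved)
#'
#' Always feasible: every model constraint is a capacity or demand ceiling.
#'
#' @param instance a [ppe_instance()].
#' @return An [allocation_plan()] of zeros.
#' @export
zero_plan <- function(instance) {
  nH <- length(instance$reserve_ids); nI <- length(instance$dc_ids)
  nJ <- length(instance$area_ids); nK <- length(instance$ppe_ids)
  nM <- length(instance$vehicle_ids)
  allocation_plan(instance, rep(0, nI), array(0, c(nH, nI, nJ, nM)),
                  array(0, c(nH, nI, nJ, nK, nM)))
}

#' Waiting loss of one area for one PPE type
#'
#' Unmet demand is charged at the curve plateau (an infinite wait), delivered
#' kilograms at the waiting cost of their route time:
#' `L_jk = (d_jk - sum(y)) * lambda_max_k + sum(y * lambda_k(t_route))`.
#'
#' @param instance a [ppe_instance()].
#' @param plan an [allocation_plan()].
#' @param j,k area and PPE index (position or id).
#' @return Loss in yuan (non-negative).
#' @export
area_loss <- function(instance, plan, j, k) {
  stopifnot(inherits(plan, "allocation_plan"))
  j <- resolve_index(j, instance$area_ids, "area")
  k <- resolve_index(k, instance$ppe_ids, "ppe")
  y <- plan$shipped[, , j, k, , drop = FALSE]
  delivered <- sum(y)
  d <- instance$demand[j, k]
  if (delivered > d + 1e-6 * max(1, d))
    stop(sprintf("over-delivery to area %s / PPE %s: %g kg shipped, %g kg demanded",
                 instance$area_ids[j], instance$ppe_ids[k], delivered, d))
  tt <- route_time_array(instance)[, , j, , drop = FALSE]  # [H, I, 1, M]
  lam <- waiting_cost(instance$curves[[k]], tt)
  (d - delivered) * instance$curves[[k]]$plateau + sum(y * as.vector(lam))
}

#' Total weighted waiting loss (first objective, G1)
#'
#' Sum over areas and PPE types of [area_loss()] weighted by the PPE
#' importance weights.
#'
#' @param instance a [ppe_instance()].
#' @param plan an [allocation_plan()].
#' @return Total loss in yuan.
#' @export
total_loss <- function(instance, plan) {
  stopifnot(inherits(instance, "ppe_instance"),
            inherits(plan, "allocation_plan"))
  delivered <- apply(plan$shipped, c(3L, 4L), sum)          # [J, K]
  over <- delivered > instance$demand +
    1e-6 * pmax(1, instance$demand)
  if (any(over)) {
    jk <- which(over, arr.ind = TRUE)[1L, ]
    stop(sprintf("over-delivery to area %s / PPE %s",
                 instance$area_ids[jk[1L]], instance$ppe_ids[jk[2L]]))
  }
  plateau <- vapply(instance$curves, `[[`, 0, "plateau")
  unmet <- sweep(instance$demand - delivered, 2L, plateau, `*`)
  lam <- unit_loss_array(instance)                          # [H,I,J,K,M]
  waited <- apply(plan$shipped * lam, 4L, sum)              # by K
  sum(sweep(unmet, 2L, instance$ppe_weight, `*`)) +
    sum(waited * instance$ppe_weight)
}

#' Total logistics cost (second objective, G2)
#'
#' DC renting costs plus distance-proportional transportation costs:
#' `sum(c_i * z_i) + sum(D_hij * f_m * x_hijm)`.
#'
#' @param instance a [ppe_instance()].
#' @param plan an [allocation_plan()].
#' @return Cost in yuan.
#' @export
logistics_cost <- function(instance, plan) {
  stopifnot(inherits(instance, "ppe_instance"),
            inherits(plan, "allocation_plan"))
  dist_cost <- outer(instance$distance, instance$unit_cost)  # [H,I,J,M]
  sum(instance$rent * plan$open_dc) + sum(dist_cost * plan$vehicles)
}

#' Both objective values of a plan
#'
#' @param instance a [ppe_instance()].
#' @param plan an [allocation_plan()].
#' @return List with components `total_loss` (G1) and `logistics_cost` (G2),
#'   both in yuan.
#' @export
objective_values <- function(instance, plan) {
  list(total_loss = total_loss(instance, plan),
       logistics_cost = logistics_cost(instance, plan))
}

#' Check a plan against every model constraint
#'
#' Evaluates the coverage, supply, capacity, vehicle-load, demand and
#' variable-range constraints and reports every violation with the constraint
#' number used throughout the package's documentation, the offending indices
#' and the slack (negative slack = amount of violation).
#'
#' Constraint numbering: (5) coverage `x = 0` beyond range, (6) reserve
#' vehicle supply, (7) reserve PPE supply, (8) DC vehicle capacity gated by
#' `z`, (9) DC PPE capacity gated by `z`, (10) vehicle load capacity, (11)
#' demand ceiling, (12)-(14) variable ranges.
#'
#' @param instance a [ppe_instance()].
#' @param plan an [allocation_plan()].
#' @param tol numeric slack below which a violation is ignored (absolute,
#'   after scaling by constraint magnitude).
#' @return A data.frame with columns `constraint`, `indices`, `slack`; zero
#'   rows iff the plan is feasible.
#' @export
check_feasibility <- function(instance, plan, tol = 1e-6) {
  stopifnot(inherits(instance, "ppe_instance"),
            inherits(plan, "allocation_plan"))
  viol <- list()
  add <- function(constraint, indices, slack) {
    viol[[length(viol) + 1L]] <<- data.frame(constraint = constraint,
                                             indices = indices, slack = slack)
  }
  x <- plan$vehicles; y <- plan$shipped; z <- plan$open_dc
  ids <- instance
  lab <- function(...) paste(..., sep = ",")

  # (5) coverage: x = 0 wherever D_hij > C
  far <- outer(instance$distance > instance$coverage,
               rep(TRUE, length(instance$vehicle_ids)))
  bad <- which(far & x > tol, arr.ind = TRUE)
  for (r in seq_len(nrow(bad))) {
    b <- bad[r, ]
    add("(5)", lab(ids$reserve_ids[b[1L]], ids$dc_ids[b[2L]],
                   ids$area_ids[b[3L]], ids$vehicle_ids[b[4L]]),
        -x[b[1L], b[2L], b[3L], b[4L]])
  }
  # (6) sum_{i,j} x_hijm <= U_hm
  lhs <- apply(x, c(1L, 4L), sum)
  s <- instance$vehicle_supply - lhs
  bad <- which(s < -tol * pmax(1, instance$vehicle_supply), arr.ind = TRUE)
  for (r in seq_len(nrow(bad))) {
    b <- bad[r, ]
    add("(6)", lab(ids$reserve_ids[b[1L]], ids$vehicle_ids[b[2L]]),
        s[b[1L], b[2L]])
  }
  # (7) sum_{i,j,m} y_hijkm <= W_hk
  lhs <- apply(y, c(1L, 4L), sum)
  s <- instance$ppe_supply - lhs
  bad <- which(s < -tol * pmax(1, instance$ppe_supply), arr.ind = TRUE)
  for (r in seq_len(nrow(bad))) {
    b <- bad[r, ]
    add("(7)", lab(ids$reserve_ids[b[1L]], ids$ppe_ids[b[2L]]), s[b[1L], b[2L]])
  }
  # (8) sum_{h,j} x_hijm <= P_im * z_i
  lhs <- apply(x, c(2L, 4L), sum)
  rhs <- instance$dc_vehicle_cap * z
  s <- rhs - lhs
  bad <- which(s < -tol * pmax(1, rhs), arr.ind = TRUE)
  for (r in seq_len(nrow(bad))) {
    b <- bad[r, ]
    add("(8)", lab(ids$dc_ids[b[1L]], ids$vehicle_ids[b[2L]]), s[b[1L], b[2L]])
  }
  # (9) sum_{h,j,m} y_hijkm <= Q_ik * z_i
  lhs <- apply(y, c(2L, 4L), sum)
  rhs <- instance$dc_ppe_cap * z
  s <- rhs - lhs
  bad <- which(s < -tol * pmax(1, rhs), arr.ind = TRUE)
  for (r in seq_len(nrow(bad))) {
    b <- bad[r, ]
    add("(9)", lab(ids$dc_ids[b[1L]], ids$ppe_ids[b[2L]]), s[b[1L], b[2L]])
  }
  # (10) sum_k y_hijkm <= V_m * x_hijm
  lhs <- apply(y, c(1L, 2L, 3L, 5L), sum)
  rhs <- sweep(x, 4L, instance$vehicle_capacity, `*`)
  s <- rhs - lhs
  bad <- which(s < -tol * pmax(1, rhs), arr.ind = TRUE)
  for (r in seq_len(nrow(bad))) {
    b <- bad[r, ]
    add("(10)", lab(ids$reserve_ids[b[1L]], ids$dc_ids[b[2L]],
                    ids$area_ids[b[3L]], ids$vehicle_ids[b[4L]]),
        s[b[1L], b[2L], b[3L], b[4L]])
  }
  # (11) sum_{h,i,m} y_hijkm <= d_jk
  lhs <- apply(y, c(3L, 4L), sum)
  s <- instance$demand - lhs
  bad <- which(s < -tol * pmax(1, instance$demand), arr.ind = TRUE)
  for (r in seq_len(nrow(bad))) {
    b <- bad[r, ]
    add("(11)", lab(ids$area_ids[b[1L]], ids$ppe_ids[b[2L]]), s[b[1L], b[2L]])
  }
  # (12)-(14) value ranges (constructor enforces most; re-check defensively)
  if (!all(z %in% c(0, 1))) add("(12)", "z", -1)
  if (any(abs(x - round(x)) > 1e-9) || any(x < -tol)) add("(13)", "x", -1)
  if (any(y < -tol)) add("(14)", "y", -1)

  if (length(viol) == 0L)
    return(data.frame(constraint = character(), indices = character(),
                      slack = numeric()))
  do.call(rbind, viol)
}
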