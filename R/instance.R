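#' Problem instance for the PPE location-allocation network
#'
#' Bundles every set and parameter of the three-layer network: reserve
#' centers hold PPE stocks and vehicle fleets, candidate distribution centers
#' (DCs) relay them, affected areas demand them.  All quantities are stored in
#' canonical units: kilograms, meters, seconds, yuan.
#'
#' @param reserve_ids,dc_ids,area_ids,ppe_ids,vehicle_ids character vectors of
#'   unique ids for the five index sets (reserve centers H, candidate DCs I,
#'   affected areas J, PPE types K, vehicle types M).
#' @param distance numeric array `[H, I, J]`: path length in meters from
#'   reserve center through DC to area (one-way, traversed once).
#' @param coverage scalar, meters: maximum distance a vehicle may travel.
#' @param ppe_weight numeric `[K]`: dimensionless importance weight of each
#'   PPE type in the loss objective.
#' @param vehicle_capacity numeric `[M]`: load capacity, kg per vehicle.
#' @param vehicle_supply numeric `[H, M]`: vehicles available per reserve.
#' @param ppe_supply numeric `[H, K]`: kg of each PPE stored per reserve.
#' @param dc_vehicle_cap numeric `[I, M]`: vehicle throughput cap per DC.
#' @param dc_ppe_cap numeric `[I, K]`: kg throughput cap per DC.
#' @param demand numeric `[J, K]`: kg demanded per area and PPE.
#' @param unit_cost numeric `[M]`: transport cost, yuan per meter.
#' @param unit_time numeric `[M]`: travel time, seconds per meter.
#' @param rent numeric `[I]`: one-off renting cost of opening each DC, yuan.
#' @param curves list of [waiting_cost_curve()]s, one per PPE type, or a
#'   single curve recycled across types.
#' @param name optional instance label.
#' @return An object of class `ppe_instance`.
#' @export
ppe_instance <- function(reserve_ids, dc_ids, area_ids, ppe_ids, vehicle_ids,
                         distance, coverage, ppe_weight, vehicle_capacity,
                         vehicle_supply, ppe_supply, dc_vehicle_cap,
                         dc_ppe_cap, demand, unit_cost, unit_time, rent,
                         curves, name = "unnamed") {
  ids <- list(reserve = reserve_ids, dc = dc_ids, area = area_ids,
              ppe = ppe_ids, vehicle = vehicle_ids)
  for (nm in names(ids)) {
    v <- ids[[nm]]
    if (length(v) == 0L) stop(sprintf("id set '%s' must be non-empty", nm))
    if (anyDuplicated(v)) stop(sprintf("duplicate ids in set '%s'", nm))
  }
  nH <- length(reserve_ids); nI <- length(dc_ids); nJ <- length(area_ids)
  nK <- length(ppe_ids); nM <- length(vehicle_ids)

  if (inherits(curves, "waiting_cost_curve")) curves <- rep(list(curves), nK)
  if (length(curves) != nK || !all(vapply(curves, inherits, TRUE,
                                          "waiting_cost_curve")))
    stop("'curves' must be one waiting_cost_curve per PPE type")
  names(curves) <- ppe_ids

  distance <- check_param_array(distance, c(nH, nI, nJ), "distance")
  vehicle_supply <- check_param_array(vehicle_supply, c(nH, nM),
                                      "vehicle_supply")
  ppe_supply <- check_param_array(ppe_supply, c(nH, nK), "ppe_supply")
  dc_vehicle_cap <- check_param_array(dc_vehicle_cap, c(nI, nM),
                                      "dc_vehicle_cap")
  dc_ppe_cap <- check_param_array(dc_ppe_cap, c(nI, nK), "dc_ppe_cap")
  demand <- check_param_array(demand, c(nJ, nK), "demand")
  ppe_weight <- check_param_array(ppe_weight, nK, "ppe_weight")
  vehicle_capacity <- check_param_array(vehicle_capacity, nM,
                                        "vehicle_capacity")
  unit_cost <- check_param_array(unit_cost, nM, "unit_cost")
  unit_time <- check_param_array(unit_time, nM, "unit_time")
  rent <- check_param_array(rent, nI, "rent")
  if (!is.numeric(coverage) || length(coverage) != 1L || !is.finite(coverage)
      || coverage <= 0)
    stop("'coverage' must be a positive finite scalar (meters)")

  dimnames(distance) <- list(reserve_ids, dc_ids, area_ids)
  dimnames(vehicle_supply) <- list(reserve_ids, vehicle_ids)
  dimnames(ppe_supply) <- list(reserve_ids, ppe_ids)
  dimnames(dc_vehicle_cap) <- list(dc_ids, vehicle_ids)
  dimnames(dc_ppe_cap) <- list(dc_ids, ppe_ids)
  dimnames(demand) <- list(area_ids, ppe_ids)
  names(ppe_weight) <- ppe_ids
  names(vehicle_capacity) <- names(unit_cost) <- names(unit_time) <- vehicle_ids
  names(rent) <- dc_ids

  structure(list(name = name, reserve_ids = reserve_ids, dc_ids = dc_ids,
                 area_ids = area_ids, ppe_ids = ppe_ids,
                 vehicle_ids = vehicle_ids, distance = distance,
                 coverage = coverage, ppe_weight = ppe_weight,
                 vehicle_capacity = vehicle_capacity,
                 vehicle_supply = vehicle_supply, ppe_supply = ppe_supply,
                 dc_vehicle_cap = dc_vehicle_cap, dc_ppe_cap = dc_ppe_cap,
                 demand = demand, unit_cost = unit_cost,
                 unit_time = unit_time, rent = rent, curves = curves),
            class = "ppe_instance")
}

# shape + non-negativity + finiteness check for one parameter array;
# dimensionless input of the right length is reshaped, arrays must match
check_param_array <- function(x, dims, what) {
  x <- x * 1.0
  if (length(dims) == 1L) {
    if (length(x) != dims)
      stop(sprintf("'%s' must have length %d", what, dims))
    x <- as.numeric(x)
  } else if (is.null(dim(x)) || length(dim(x)) == 1L) {
    if (length(x) != prod(dims))
      stop(sprintf("'%s' must be an array of dim (%s)", what,
                   paste(dims, collapse = ", ")))
    x <- array(as.numeric(x), dims)
  } else {
    if (length(dim(x)) != length(dims) || !all(dim(x) == dims))
      stop(sprintf("'%s' must be an array of dim (%s)", what,
                   paste(dims, collapse = ", ")))
    dimnames(x) <- NULL
  }
  if (any(!is.finite(x))) stop(sprintf("'%s' contains non-finite values", what))
  if (any(x < 0)) stop(sprintf("'%s' contains negative values", what))
  x
}

#' Travel time of a vehicle along one reserve-DC-area path
#'
#' @param instance a [ppe_instance()].
#' @param h,i,j,m indices (position or id) of the reserve center, DC, area and
#'   vehicle type.
#' @return Travel time in seconds: `unit_time[m] * distance[h, i, j]`.
#' @export
route_time <- function(instance, h, i, j, m) {
  stopifnot(inherits(instance, "ppe_instance"))
  h <- resolve_index(h, instance$reserve_ids, "reserve")
  i <- resolve_index(i, instance$dc_ids, "dc")
  j <- resolve_index(j, instance$area_ids, "area")
  m <- resolve_index(m, instance$vehicle_ids, "vehicle")
  unname(instance$unit_time[m] * instance$distance[h, i, j])
}

resolve_index <- function(idx, ids, what) {
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop(sprintf("unknown %s id '%s'", what, idx[is.na(pos)][1L]))
    return(pos)
  }
  if (!is.numeric(idx) || any(idx < 1L) || any(idx > length(ids)))
    stop(sprintf("%s index out of range [1, %d]", what, length(ids)))
  as.integer(idx)
}

#' Route-time array for every path and vehicle type
#'
#' @param instance a [ppe_instance()].
#' @return Array `[H, I, J, M]` of travel times in seconds.
#' @keywords internal
route_time_array <- function(instance) {
  nM <- length(instance$vehicle_ids)
  tt <- outer(instance$distance, instance$unit_time)
  dimnames(tt) <- c(dimnames(instance$distance),
                    list(instance$vehicle_ids))
  tt
}

# per-(h,i,j,k,m) unit waiting cost lambda_k(e_m * D_hij), the linear
# coefficient multiplying delivered kg in the loss objective
unit_loss_array <- function(instance) {
  tt <- route_time_array(instance)              # [H, I, J, M]
  nK <- length(instance$ppe_ids)
  dims <- c(dim(tt)[1:3], nK, dim(tt)[4L])
  lam <- array(NA_real_, dims,
               dimnames = c(dimnames(tt)[1:3], list(instance$ppe_ids),
                            dimnames(tt)[4L]))
  for (k in seq_len(nK))
    lam[, , , k, ] <- waiting_cost(instance$curves[[k]], tt)
  lam
}

#' @export
print.ppe_instance <- function(x, ...) {
  cat(sprintf("PPE allocation instance '%s'\n", x$name))
  cat(sprintf("  %d reserve centers, %d candidate DCs, %d areas, %d PPE types, %d vehicle types\n",
              length(x$reserve_ids), length(x$dc_ids), length(x$area_ids),
              length(x$ppe_ids), length(x$vehicle_ids)))
  cat(sprintf("  total demand %.5g kg, total PPE supply %.5g kg, coverage %g m\n",
              sum(x$demand), sum(x$ppe_supply), x$coverage))
  invisible(x)
}
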