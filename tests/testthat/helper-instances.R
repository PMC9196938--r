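# Shared fixtures, all built in code.

# a 1x1x1x1x1 instance with round numbers: one reserve, one candidate DC,
# one area, one PPE, one vehicle class
toy_instance <- function(distance = 100000, coverage = 150000,
                         demand = 1000, supply = 1500, u = 2, vcap = 600,
                         curve = wenzhou_curve()) {
  ppe_instance("R1", "DC1", "A1", "P1", "V1",
               distance = array(distance, c(1, 1, 1)), coverage = coverage,
               ppe_weight = 1, vehicle_capacity = vcap, vehicle_supply = u,
               ppe_supply = supply, dc_vehicle_cap = u + 1,
               dc_ppe_cap = supply, demand = demand,
               unit_cost = 0.2, unit_time = 0.06, rent = 500000,
               curves = curve, name = "toy")
}

# small random instances whose (z, x) grid the enumeration oracle can cover
tiny_config <- function(seed, n_reserve = 2, n_dc = 2, n_area = 2,
                        rho = 0.7) {
  synthetic_config(n_reserve = n_reserve, n_dc = n_dc, n_area = n_area,
                   n_ppe = 1, n_vehicle = 1, region = 50000,
                   coverage = 200000, rho = rho, seed = seed,
                   demand_range = c(5000, 20000),
                   vehicle_supply_range = c(1, 2),
                   vehicle_cap_range = c(4000, 8000))
}

tiny_instance <- function(seed, ...) synthetic_instance(tiny_config(seed, ...))

# mid-size random instance (not oracle-enumerable; for solver/analysis tests)
small_config <- function(seed) {
  synthetic_config(n_reserve = 2, n_dc = 2, n_area = 3, n_ppe = 2,
                   n_vehicle = 2, region = 60000, coverage = 180000,
                   rho = 0.8, seed = seed, demand_range = c(10000, 60000),
                   vehicle_supply_range = c(2, 5),
                   vehicle_cap_range = c(5000, 15000))
}

# random feasible plan: greedy random shipments within all capacities
random_feasible_plan <- function(instance, seed, n_moves = 25L) {
  set.seed(seed)
  nH <- length(instance$reserve_ids); nI <- length(instance$dc_ids)
  nJ <- length(instance$area_ids); nK <- length(instance$ppe_ids)
  nM <- length(instance$vehicle_ids)
  x <- array(0, c(nH, nI, nJ, nM))
  y <- array(0, c(nH, nI, nJ, nK, nM))
  z <- rep(0, nI)
  for (mv in seq_len(n_moves)) {
    h <- sample.int(nH, 1L); i <- sample.int(nI, 1L)
    j <- sample.int(nJ, 1L); k <- sample.int(nK, 1L)
    m <- sample.int(nM, 1L)
    if (instance$distance[h, i, j] > instance$coverage) next
    slack6 <- instance$vehicle_supply[h, m] - sum(x[h, , , m])
    slack8 <- instance$dc_vehicle_cap[i, m] - sum(x[, i, , m])
    if (slack6 < 1 || slack8 < 1) next
    x[h, i, j, m] <- x[h, i, j, m] + 1
    z[i] <- 1
    room <- min(
      instance$ppe_supply[h, k] - sum(y[h, , , k, ]),
      instance$dc_ppe_cap[i, k] - sum(y[, i, , k, ]),
      instance$demand[j, k] - sum(y[, , j, k, ]),
      instance$vehicle_capacity[m] * x[h, i, j, m] - sum(y[h, i, j, , m]))
    if (room > 0)
      y[h, i, j, k, m] <- y[h, i, j, k, m] + stats::runif(1, 0, room)
  }
  allocation_plan(instance, z, x, y)
}
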