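#' The Wenzhou PPE distribution case
#'
#' A three-reserve (Shiqu, Yongjia, Yueqing), two-candidate-DC, five-area
#' (Rui'an, Pingyang, Cangnan, Wencheng, Taishun) network with two PPE types
#' (masks, protective clothing) and three vehicle classes (light, medium,
#' heavy).  Demands, supplies, DC capacities, vehicle parameters, rents
#' (800000 / 600000 yuan), importance weights (0.6 / 0.4), coverage radius
#' (150 km) and the waiting-cost curve are packaged verbatim; stock and
#' demand tables are given in thousands of kg and converted to kg here.
#'
#' The reserve-DC-area distance matrix of the original case was never
#' published, so it must be supplied: either pass a strictly positive
#' `3 x 2 x 5` array in meters, or a `seed`, in which case a clearly
#' synthetic matrix is drawn by the planar generator, constrained so every
#' area is reachable (within coverage) through at least one reserve-DC path.
#' Every quantity that depends on distances therefore depends on this choice;
#' quantities derived from the tables alone (demand totals, the worst-case
#' loss, the zero-cost ideal of the second objective) do not.
#'
#' @param distances optional numeric array `[3, 2, 5]`, meters, all `> 0`.
#' @param seed optional integer; used to draw a synthetic distance matrix
#'   when `distances` is missing.
#' @return A [ppe_instance()].
#' @export
wenzhou_case <- function(distances = NULL, seed = NULL) {
  reserve <- c("Shiqu", "Yongjia", "Yueqing")
  dc <- c("DC1", "DC2")
  area <- c("Rui'an", "Pingyang", "Cangnan", "Wencheng", "Taishun")
  ppe <- c("masks", "protective_clothing")
  vehicle <- c("light", "medium", "heavy")

  kkg <- 1000  # stock/demand tables are in 1,000 kg
  demand <- kkg * rbind(c(146, 0), c(150, 0), c(165, 0.16),
                        c(150, 11.4), c(320, 3.04))
  ppe_supply <- kkg * rbind(c(500, 6), c(150, 2), c(300, 4))
  vehicle_supply <- rbind(c(30, 15, 10), c(10, 5, 2), c(20, 10, 5))
  dc_ppe_cap <- kkg * rbind(c(800, 10), c(600, 8))
  dc_vehicle_cap <- rbind(c(50, 25, 12), c(40, 20, 10))

  if (is.null(distances)) {
    if (is.null(seed))
      stop("supply either a 3 x 2 x 5 distance array or a seed for the synthetic generator")
    distances <- synthetic_distances(n_reserve = 3L, n_dc = 2L, n_area = 5L,
                                     region = 100000, road_factor = 1.3,
                                     coverage = 150000, seed = seed)
  }
  distances <- check_param_array(distances, c(3L, 2L, 5L), "distances")
  if (any(distances <= 0)) stop("'distances' must be strictly positive")

  ppe_instance(reserve, dc, area, ppe, vehicle,
               distance = distances, coverage = 150000,
               ppe_weight = c(0.6, 0.4),
               vehicle_capacity = c(5000, 10000, 20000),
               vehicle_supply = vehicle_supply, ppe_supply = ppe_supply,
               dc_vehicle_cap = dc_vehicle_cap, dc_ppe_cap = dc_ppe_cap,
               demand = demand, unit_cost = c(0.1, 0.2, 0.3),
               unit_time = c(0.06, 0.07, 0.09),
               rent = c(800000, 600000), curves = wenzhou_curve(),
               name = "wenzhou")
}

# seeded planar distance matrix with every area reachable within coverage
synthetic_distances <- function(n_reserve, n_dc, n_area, region, road_factor,
                                coverage, seed) {
  with_local_seed(seed, {
    for (attempt in 1:200) {
      pr <- matrix(stats::runif(2 * n_reserve, 0, region), ncol = 2L)
      pd <- matrix(stats::runif(2 * n_dc, 0, region), ncol = 2L)
      pa <- matrix(stats::runif(2 * n_area, 0, region), ncol = 2L)
      d1 <- sqrt(outer(pr[, 1L], pd[, 1L], `-`)^2 +
                   outer(pr[, 2L], pd[, 2L], `-`)^2)   # [H, I]
      d2 <- sqrt(outer(pd[, 1L], pa[, 1L], `-`)^2 +
                   outer(pd[, 2L], pa[, 2L], `-`)^2)   # [I, J]
      D <- road_factor * (outer(d1, rep(1, n_area)) +
                            aperm(outer(d2, rep(1, n_reserve)),
                                  c(3L, 1L, 2L)))
      reachable <- apply(D <= coverage, 3L, any)
      if (all(reachable) && all(D > 0)) return(D)
    }
    stop("could not draw an admissible distance matrix; enlarge coverage or shrink the region")
  })
}

# run expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic instance generator
#'
#' Describes the family of random instances the generator draws: network
#' sizes, the planar region the sites are scattered over, a road factor
#' inflating Euclidean distances, and the shortage ratio `rho` = total
#' supply / total demand per PPE type (`rho < 1` puts the instance in the
#' shortage regime where fairness matters).  The magnitude ranges default to
#' brackets around the packaged case study; the seed fixes all randomness.
#'
#' @param n_reserve,n_dc,n_area,n_ppe,n_vehicle set sizes, all `>= 1`.
#' @param region side length (m) of the square the sites are placed in.
#' @param road_factor multiplier `>= 1` applied to Euclidean legs.
#' @param rho shortage ratio: per-PPE total supply / total demand.
#' @param coverage vehicle coverage radius (m).
#' @param seed integer seed fixing all randomness.
#' @param demand_range kg demanded per (area, PPE), drawn uniformly.
#' @param vehicle_supply_range integer vehicles per (reserve, type).
#' @param vehicle_cap_range kg per vehicle.
#' @param rent_range yuan per DC.
#' @param unit_cost_range yuan per meter.
#' @param unit_time_range seconds per meter.
#' @param curve a [waiting_cost_curve()] shared by all PPE types.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reserve = 3L, n_dc = 2L, n_area = 5L,
                             n_ppe = 2L, n_vehicle = 3L,
                             region = 100000, road_factor = 1.3, rho = 0.8,
                             coverage = 150000, seed = 1L,
                             demand_range = c(10000, 300000),
                             vehicle_supply_range = c(2L, 30L),
                             vehicle_cap_range = c(5000, 20000),
                             rent_range = c(500000, 1000000),
                             unit_cost_range = c(0.1, 0.3),
                             unit_time_range = c(0.06, 0.09),
                             curve = wenzhou_curve()) {
  counts <- c(n_reserve, n_dc, n_area, n_ppe, n_vehicle)
  stopifnot(all(counts >= 1L), region > 0, road_factor >= 1, rho > 0,
            coverage > 0, inherits(curve, "waiting_cost_curve"))
  structure(list(n_reserve = n_reserve, n_dc = n_dc, n_area = n_area,
                 n_ppe = n_ppe, n_vehicle = n_vehicle, region = region,
                 road_factor = road_factor, rho = rho, coverage = coverage,
                 seed = seed, demand_range = demand_range,
                 vehicle_supply_range = vehicle_supply_range,
                 vehicle_cap_range = vehicle_cap_range,
                 rent_range = rent_range, unit_cost_range = unit_cost_range,
                 unit_time_range = unit_time_range, curve = curve),
            class = "synthetic_config")
}

#' Generate a random instance from a configuration
#'
#' Sites are placed uniformly in the square region; path lengths are
#' `road_factor * (Euclid(reserve, DC) + Euclid(DC, area))`.  Demands are
#' uniform in `demand_range`; per-PPE supplies are scaled so total supply
#' equals `rho` times total demand (to the kg).  DC capacities are drawn
#' between 50% and 150% of the corresponding system-wide supply so they
#' sometimes bind.  Deterministic: the same configuration (same seed) always
#' yields the same instance.
#'
#' @param config a [synthetic_config()].
#' @return A [ppe_instance()].
#' @export
synthetic_instance <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  with_local_seed(cf$seed, {
    D <- synthetic_distances(cf$n_reserve, cf$n_dc, cf$n_area, cf$region,
                             cf$road_factor, cf$coverage,
                             seed = stats::runif(1, 1, 2^30))
    demand <- matrix(round(stats::runif(cf$n_area * cf$n_ppe,
                                        cf$demand_range[1L],
                                        cf$demand_range[2L])),
                     cf$n_area, cf$n_ppe)
    supply_raw <- matrix(stats::runif(cf$n_reserve * cf$n_ppe, 0.5, 1.5),
                         cf$n_reserve, cf$n_ppe)
    supply <- round(sweep(sweep(supply_raw, 2L, colSums(supply_raw), `/`),
                          2L, cf$rho * colSums(demand), `*`))
    # fix rounding drift so the per-PPE ratio holds to the kg
    for (k in seq_len(cf$n_ppe))
      supply[1L, k] <- supply[1L, k] +
        round(cf$rho * sum(demand[, k])) - sum(supply[, k])
    vcap <- sort(round(stats::runif(cf$n_vehicle, cf$vehicle_cap_range[1L],
                                    cf$vehicle_cap_range[2L]) / 100) * 100)
    uvals <- seq(cf$vehicle_supply_range[1L], cf$vehicle_supply_range[2L])
    usup <- matrix(uvals[sample.int(length(uvals),
                                    cf$n_reserve * cf$n_vehicle,
                                    replace = TRUE)],
                   cf$n_reserve, cf$n_vehicle)
    pcap <- matrix(0, cf$n_dc, cf$n_vehicle)
    for (m in seq_len(cf$n_vehicle))
      pcap[, m] <- pmax(1, round(stats::runif(cf$n_dc, 0.5, 1.5) *
                                   sum(usup[, m])))
    qcap <- matrix(0, cf$n_dc, cf$n_ppe)
    for (k in seq_len(cf$n_ppe))
      qcap[, k] <- pmax(1, round(stats::runif(cf$n_dc, 0.5, 1.5) *
                                   sum(supply[, k])))
    ucost <- sort(round(stats::runif(cf$n_vehicle, cf$unit_cost_range[1L],
                                     cf$unit_cost_range[2L]), 3L))
    utime <- sort(round(stats::runif(cf$n_vehicle, cf$unit_time_range[1L],
                                     cf$unit_time_range[2L]), 3L))
    rent <- round(stats::runif(cf$n_dc, cf$rent_range[1L],
                               cf$rent_range[2L]) / 1000) * 1000
    weights <- stats::runif(cf$n_ppe, 0.2, 1)
    weights <- round(weights / sum(weights), 4L)

    ppe_instance(
      reserve_ids = paste0("R", seq_len(cf$n_reserve)),
      dc_ids = paste0("DC", seq_len(cf$n_dc)),
      area_ids = paste0("A", seq_len(cf$n_area)),
      ppe_ids = paste0("P", seq_len(cf$n_ppe)),
      vehicle_ids = paste0("V", seq_len(cf$n_vehicle)),
      distance = D, coverage = cf$coverage, ppe_weight = weights,
      vehicle_capacity = vcap, vehicle_supply = usup, ppe_supply = supply,
      dc_vehicle_cap = pcap, dc_ppe_cap = qcap, demand = demand,
      unit_cost = ucost, unit_time = utime, rent = rent, curves = cf$curve,
      name = sprintf("synthetic-%s", format(cf$seed)))
  })
}

#' Save an instance as a YAML document
#'
#' One structured text document: metadata (name, units declaration), id
#' sets, parameter tables keyed by ids, and curve parameters per PPE type.
#' Always written in canonical units (kg, m, s, yuan).
#'
#' @param instance a [ppe_instance()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [load_instance()]
#' @export
save_instance <- function(instance, path) {
  stopifnot(inherits(instance, "ppe_instance"))
  keyed <- function(v) as.list(stats::setNames(as.list(unname(v)), names(v)))
  keyed2 <- function(m) lapply(stats::setNames(seq_len(nrow(m)),
                                               rownames(m)),
                               function(r) keyed(stats::setNames(m[r, ],
                                                                 colnames(m))))
  doc <- list(
    name = instance$name,
    units = list(mass = "kg", distance = "m", time = "s",
                 currency = "yuan"),
    sets = list(reserve = as.list(instance$reserve_ids),
                dc = as.list(instance$dc_ids),
                area = as.list(instance$area_ids),
                ppe = as.list(instance$ppe_ids),
                vehicle = as.list(instance$vehicle_ids)),
    parameters = list(
      coverage = instance$coverage,
      ppe_weight = keyed(instance$ppe_weight),
      vehicle_capacity = keyed(instance$vehicle_capacity),
      unit_cost = keyed(instance$unit_cost),
      unit_time = keyed(instance$unit_time),
      rent = keyed(instance$rent),
      demand = keyed2(instance$demand),
      ppe_supply = keyed2(instance$ppe_supply),
      vehicle_supply = keyed2(instance$vehicle_supply),
      dc_ppe_cap = keyed2(instance$dc_ppe_cap),
      dc_vehicle_cap = keyed2(instance$dc_vehicle_cap),
      distance = lapply(stats::setNames(seq_along(instance$reserve_ids),
                                        instance$reserve_ids), function(h)
                                          keyed2(matrix(
                                            instance$distance[h, , ],
                                            length(instance$dc_ids),
                                            length(instance$area_ids),
                                            dimnames = list(
                                              instance$dc_ids,
                                              instance$area_ids))))),
    curves = lapply(instance$curves, function(cv)
      list(quad_coeff = cv$quad_coeff, breakpoint = cv$breakpoint,
           plateau = cv$plateau)))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Load an instance from a YAML document
#'
#' Validates the document schema and referential integrity (every table key
#' must belong to its id set and every combination must be present), applies
#' the declared units (a `mass: '1000 kg'` declaration multiplies the
#' demand, PPE-supply and DC PPE-capacity tables by 1000 on load; vehicle
#' load capacities are always per-vehicle kg), and returns the instance.
#' `load_instance(save_instance(x))` is the identity.
#'
#' @param path path to a YAML instance document.
#' @return A [ppe_instance()].
#' @export
load_instance <- function(path) {
  doc <- yaml::read_yaml(path)
  for (fld in c("name", "units", "sets", "parameters", "curves"))
    if (is.null(doc[[fld]]))
      stop(sprintf("schema violation at '%s': missing", fld))
  sets <- doc$sets
  for (s in c("reserve", "dc", "area", "ppe", "vehicle"))
    if (length(sets[[s]]) == 0L)
      stop(sprintf("schema violation at 'sets.%s': empty or missing", s))
  sets <- lapply(sets, function(v) as.character(unlist(v)))
  mass_scale <- switch(as.character(doc$units$mass %||% "kg"),
                       "kg" = 1, "1000 kg" = 1000, "1,000 kg" = 1000,
                       stop(sprintf("unknown mass unit '%s'",
                                    doc$units$mass)))
  p <- doc$parameters
  grab1 <- function(tab, ids, what) {
    if (is.null(tab)) stop(sprintf("schema violation at 'parameters.%s'",
                                   what))
    extra <- setdiff(names(tab), ids)
    if (length(extra)) stop(sprintf("dangling id '%s' in '%s'", extra[1L],
                                    what))
    miss <- setdiff(ids, names(tab))
    if (length(miss)) stop(sprintf("referential error: '%s' missing row '%s'",
                                   what, miss[1L]))
    vapply(ids, function(id) as.numeric(tab[[id]]), 0)
  }
  grab2 <- function(tab, rows, cols, what) {
    if (is.null(tab)) stop(sprintf("schema violation at 'parameters.%s'",
                                   what))
    extra <- setdiff(names(tab), rows)
    if (length(extra)) stop(sprintf("dangling id '%s' in '%s'", extra[1L],
                                    what))
    miss <- setdiff(rows, names(tab))
    if (length(miss)) stop(sprintf("referential error: '%s' missing row '%s'",
                                   what, miss[1L]))
    vals <- vapply(rows, function(r) grab1(tab[[r]], cols,
                                           paste0(what, ".", r)),
                   numeric(length(cols)))
    t(matrix(vals, length(cols), length(rows)))
  }
  D <- array(NA_real_, c(length(sets$reserve), length(sets$dc),
                         length(sets$area)))
  for (h in seq_along(sets$reserve)) {
    m <- grab2(p$distance[[sets$reserve[h]]] %||%
                 stop(sprintf("referential error: 'distance' missing row '%s'",
                              sets$reserve[h])),
               sets$dc, sets$area, paste0("distance.", sets$reserve[h]))
    D[h, , ] <- m
  }
  curves <- lapply(sets$ppe, function(k) {
    cv <- doc$curves[[k]]
    if (is.null(cv)) stop(sprintf("referential error: 'curves' missing '%s'",
                                  k))
    waiting_cost_curve(cv$quad_coeff, cv$breakpoint, cv$plateau)
  })

  ppe_instance(
    sets$reserve, sets$dc, sets$area, sets$ppe, sets$vehicle,
    distance = D, coverage = as.numeric(p$coverage),
    ppe_weight = grab1(p$ppe_weight, sets$ppe, "ppe_weight"),
    vehicle_capacity = grab1(p$vehicle_capacity, sets$vehicle,
                             "vehicle_capacity"),
    vehicle_supply = grab2(p$vehicle_supply, sets$reserve, sets$vehicle,
                           "vehicle_supply"),
    ppe_supply = mass_scale * grab2(p$ppe_supply, sets$reserve, sets$ppe,
                                    "ppe_supply"),
    dc_vehicle_cap = grab2(p$dc_vehicle_cap, sets$dc, sets$vehicle,
                           "dc_vehicle_cap"),
    dc_ppe_cap = mass_scale * grab2(p$dc_ppe_cap, sets$dc, sets$ppe,
                                    "dc_ppe_cap"),
    demand = mass_scale * grab2(p$demand, sets$area, sets$ppe, "demand"),
    unit_cost = grab1(p$unit_cost, sets$vehicle, "unit_cost"),
    unit_time = grab1(p$unit_time, sets$vehicle, "unit_time"),
    rent = grab1(p$rent, sets$dc, "rent"),
    curves = curves, name = as.character(doc$name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a plan's flows as CSV
#'
#' One row per (reserve, dc, area, ppe, vehicle) combination that moves
#' vehicles or kilograms; all-zero rows are omitted.  The set of opened DCs
#' is recorded in a `# open_dc:` comment header so that re-import is
#' lossless even for DCs opened without flow.
#'
#' @param instance a [ppe_instance()].
#' @param plan an [allocation_plan()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flows <- function(instance, plan, path) {
  stopifnot(inherits(plan, "allocation_plan"))
  yi <- arrayInd(seq_len(length(plan$shipped)), dim(plan$shipped))
  xv <- plan$vehicles[yi[, c(1L, 2L, 3L, 5L), drop = FALSE]]
  kg <- as.vector(plan$shipped)
  keep <- kg > 0 | xv > 0
  df <- data.frame(reserve = instance$reserve_ids[yi[keep, 1L]],
                   dc = instance$dc_ids[yi[keep, 2L]],
                   area = instance$area_ids[yi[keep, 3L]],
                   ppe = instance$ppe_ids[yi[keep, 4L]],
                   vehicle = instance$vehicle_ids[yi[keep, 5L]],
                   vehicles = xv[keep], kg = kg[keep])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# open_dc: %s", paste(
    instance$dc_ids[plan$open_dc > 0], collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a flow CSV back into an allocation plan
#'
#' @param instance the [ppe_instance()] the flows refer to.
#' @param path path to a CSV written by [write_flows()].
#' @return An [allocation_plan()].
#' @export
read_flows <- function(instance, path) {
  first <- readLines(path, n = 1L)
  open_ids <- character()
  if (startsWith(first, "# open_dc:")) {
    lst <- trimws(sub("# open_dc:", "", first))
    if (nzchar(lst)) open_ids <- trimws(strsplit(lst, ",")[[1L]])
  }
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  nH <- length(instance$reserve_ids); nI <- length(instance$dc_ids)
  nJ <- length(instance$area_ids); nK <- length(instance$ppe_ids)
  nM <- length(instance$vehicle_ids)
  x <- array(0, c(nH, nI, nJ, nM))
  y <- array(0, c(nH, nI, nJ, nK, nM))
  if (nrow(df)) {
    h <- resolve_index(df$reserve, instance$reserve_ids, "reserve")
    i <- resolve_index(df$dc, instance$dc_ids, "dc")
    j <- resolve_index(df$area, instance$area_ids, "area")
    k <- resolve_index(df$ppe, instance$ppe_ids, "ppe")
    m <- resolve_index(df$vehicle, instance$vehicle_ids, "vehicle")
    y[cbind(h, i, j, k, m)] <- df$kg
    # vehicle counts repeat across the PPE rows of one path; last write wins
    for (r in seq_len(nrow(df))) x[h[r], i[r], j[r], m[r]] <- df$vehicles[r]
  }
  z <- as.numeric(instance$dc_ids %in% open_ids)
  allocation_plan(instance, z, x, y)
}
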