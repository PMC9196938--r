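test_that("the case fixture carries the reference table values", {
  inst <- wenzhou_case(seed = 1)
  # demands (1,000 kg): masks then protective clothing per area
  demand_tab <- 1000 * rbind(c(146, 0), c(150, 0), c(165, 0.16),
                             c(150, 11.4), c(320, 3.04))
  expect_equal(unname(inst$demand), demand_tab)
  expect_equal(sum(inst$demand[, "masks"]), 931000)
  expect_equal(sum(inst$demand[, "protective_clothing"]), 14600)
  # supplies: stocks (1,000 kg) and fleets per reserve center
  expect_equal(unname(inst$ppe_supply),
               1000 * rbind(c(500, 6), c(150, 2), c(300, 4)))
  expect_equal(unname(inst$vehicle_supply["Shiqu", ]), c(30, 15, 10))
  # DC capacities and rents
  expect_equal(unname(inst$dc_ppe_cap),
               1000 * rbind(c(800, 10), c(600, 8)))
  expect_equal(unname(inst$dc_ppe_cap["DC2", "masks"]), 600000)
  expect_equal(unname(inst$dc_vehicle_cap["DC2", ]), c(40, 20, 10))
  expect_equal(unname(inst$rent), c(800000, 600000))
  # vehicle parameters and the rest
  expect_equal(unname(inst$vehicle_capacity), c(5000, 10000, 20000))
  expect_equal(unname(inst$unit_cost), c(0.1, 0.2, 0.3))
  expect_equal(unname(inst$unit_time), c(0.06, 0.07, 0.09))
  expect_equal(unname(inst$ppe_weight), c(0.6, 0.4))
  expect_equal(inst$coverage, 150000)
  crv <- inst$curves[["masks"]]
  expect_equal(crv$quad_coeff, 1 / 7315661)
  expect_equal(crv$breakpoint, 604800)
  expect_equal(crv$plateau, 50000)
})

test_that("seeded case distances are admissible and reproducible", {
  a <- wenzhou_case(seed = 42)
  b <- wenzhou_case(seed = 42)
  expect_identical(a$distance, b$distance)
  expect_true(all(a$distance > 0))
  # every area reachable within coverage through some reserve-DC path
  expect_true(all(apply(a$distance <= a$coverage, 3L, any)))
  expect_error(wenzhou_case(array(0, c(3, 2, 5))), "positive")
  expect_error(wenzhou_case(), "seed")
})

test_that("synthetic instances are deterministic and honor the shortage ratio", {
  cfg <- tiny_config(9, rho = 0.5)
  a <- synthetic_instance(cfg)
  b <- synthetic_instance(cfg)
  expect_equal(a$distance, b$distance)
  expect_equal(a$demand, b$demand)
  expect_equal(a$ppe_supply, b$ppe_supply)
  # per-PPE supply = rho * demand, exact to the kg by construction
  expect_equal(unname(colSums(a$ppe_supply)),
               unname(round(0.5 * colSums(a$demand))))
  # zero plan always feasible
  expect_identical(nrow(check_feasibility(a, zero_plan(a))), 0L)
  # region much smaller than coverage: no coverage-fixed vehicle bound
  cfg2 <- synthetic_config(n_reserve = 2, n_dc = 1, n_area = 2, n_ppe = 1,
                           n_vehicle = 1, region = 10000, coverage = 1e6,
                           seed = 3)
  inst2 <- synthetic_instance(cfg2)
  f2 <- build_formulation(inst2)
  expect_true(all(f2$catalog$ub[f2$catalog$kind == "integer"] > 0))
})

test_that("under shortage the loss optimum still leaves demand unmet", {
  inst <- tiny_instance(8, rho = 0.6)
  res <- improved_solve(build_formulation(inst), "G1")
  delivered <- sum(res$plan$shipped)
  expect_lt(delivered, sum(inst$demand))
  expect_gt(res$objective, 0)
})

test_that("instances round-trip through the YAML document", {
  inst <- wenzhou_case(seed = 1)
  p <- withr::local_tempfile(fileext = ".yaml")
  save_instance(inst, p)
  back <- load_instance(p)
  expect_identical(back$reserve_ids, inst$reserve_ids)
  expect_identical(back$ppe_ids, inst$ppe_ids)
  expect_equal(back$distance, inst$distance, tolerance = 1e-12)
  expect_equal(back$demand, inst$demand)
  expect_equal(back$ppe_supply, inst$ppe_supply)
  expect_equal(back$vehicle_capacity, inst$vehicle_capacity)
  expect_equal(back$curves[["masks"]]$quad_coeff,
               inst$curves[["masks"]]$quad_coeff)
  # and the round trip is stable
  p2 <- withr::local_tempfile(fileext = ".yaml")
  save_instance(back, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("the declared mass unit converts stock tables on load", {
  inst <- toy_instance()
  p <- withr::local_tempfile(fileext = ".yaml")
  save_instance(inst, p)
  doc <- yaml::read_yaml(p)
  doc$units$mass <- "1000 kg"
  doc$parameters$demand$A1$P1 <- 146       # as printed in kilo-kg tables
  yaml::write_yaml(doc, p)
  back <- load_instance(p)
  expect_equal(unname(back$demand[1, 1]), 146000)
  # supplies and DC stock caps scale too, fleet counts do not
  expect_equal(unname(back$ppe_supply[1, 1]),
               1000 * inst$ppe_supply[1, 1])
  expect_equal(back$vehicle_supply, inst$vehicle_supply)
})

test_that("schema and referential violations are reported by path", {
  inst <- toy_instance()
  p <- withr::local_tempfile(fileext = ".yaml")
  save_instance(inst, p)
  doc <- yaml::read_yaml(p)
  doc$parameters$demand <- NULL
  yaml::write_yaml(doc, p)
  expect_error(load_instance(p), "demand")

  save_instance(inst, p)
  doc <- yaml::read_yaml(p)
  doc$parameters$demand$A1 <- NULL
  yaml::write_yaml(doc, p)
  expect_error(load_instance(p), "missing row 'A1'")

  save_instance(inst, p)
  doc <- yaml::read_yaml(p)
  doc$parameters$rent$DC9 <- 1
  yaml::write_yaml(doc, p)
  expect_error(load_instance(p), "dangling id 'DC9'")
})

test_that("flow CSVs round-trip plans and objective values", {
  inst <- tiny_instance(2)
  res <- improved_solve(build_formulation(inst), "G1")
  p <- withr::local_tempfile(fileext = ".csv")
  write_flows(inst, res$plan, p)
  back <- read_flows(inst, p)
  o1 <- objective_values(inst, res$plan)
  o2 <- objective_values(inst, back)
  expect_equal(o2$total_loss, o1$total_loss,
               tolerance = 1e-9)
  expect_equal(o2$logistics_cost, o1$logistics_cost,
               tolerance = 1e-9)
  expect_equal(back$open_dc, res$plan$open_dc)
  # zero rows are omitted
  df <- utils::read.csv(p, comment.char = "#")
  expect_true(all(df$kg > 0 | df$vehicles > 0))
})
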