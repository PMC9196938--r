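test_that("area loss charges unmet demand at the plateau and deliveries at route cost", {
  # no delivery: d * plateau
  inst <- toy_instance(demand = 1000)
  expect_equal(area_loss(inst, zero_plan(inst), 1, 1), 1000 * 50000)
  expect_equal(area_loss(inst, zero_plan(inst), 1, 1), 5e7)

  # full delivery at t = 0: loss vanishes
  inst0 <- toy_instance(distance = 0, demand = 1000, supply = 1500,
                        u = 2, vcap = 600)
  plan <- allocation_plan(inst0, 1, array(2, c(1, 1, 1, 1)),
                          array(1000, c(1, 1, 1, 1, 1)))
  expect_equal(area_loss(inst0, plan, 1, 1), 0)

  # partial delivery at a route where lambda = 100 exactly:
  # curve a = 100 / 9000^2, breakpoint 9000 * sqrt(500), plateau 50000
  crv <- waiting_cost_curve(100 / 9000^2, 9000 * sqrt(500), 50000)
  inst2 <- toy_instance(distance = 150000, demand = 1000, supply = 1500,
                        u = 2, vcap = 600, curve = crv)  # t = 0.06*150000 = 9000 s
  plan2 <- allocation_plan(inst2, 1, array(1, c(1, 1, 1, 1)),
                           array(400, c(1, 1, 1, 1, 1)))
  expect_equal(area_loss(inst2, plan2, 1, 1), 600 * 50000 + 400 * 100)
  expect_equal(area_loss(inst2, plan2, 1, 1), 3.004e7)
})

test_that("over-delivery is rejected", {
  inst <- toy_instance(demand = 100, supply = 1500, vcap = 600)
  plan <- allocation_plan(inst, 1, array(1, c(1, 1, 1, 1)),
                          array(150, c(1, 1, 1, 1, 1)))
  expect_error(area_loss(inst, plan, 1, 1), "over-delivery")
  expect_error(total_loss(inst, plan), "over-delivery")
})

test_that("total loss of the undelivered case study is the closed form", {
  inst <- wenzhou_case(seed = 1)
  # (931000 * 0.6 + 14600 * 0.4) * 50000
  expect_equal(total_loss(inst, zero_plan(inst)), 2.8222e10)
  # two-area toy: d = (100, 200) kg, w = 1, no delivery
  inst2 <- ppe_instance("R1", "DC1", c("A1", "A2"), "P1", "V1",
                        array(1000, c(1, 1, 2)), 1e5, 1, 500,
                        matrix(1), matrix(300), matrix(2), matrix(300),
                        matrix(c(100, 200), 2, 1), 0.1, 0.06, 1e5,
                        wenzhou_curve())
  expect_equal(total_loss(inst2, zero_plan(inst2)), 1.5e7)
})

test_that("total loss is non-increasing in deliveries and bounded", {
  for (s in 1:5) {
    inst <- tiny_instance(s)
    plan <- random_feasible_plan(inst, seed = 100 + s)
    ub <- sum(sweep(inst$demand, 2L,
                    vapply(inst$curves, `[[`, 0, "plateau") *
                      inst$ppe_weight, `*`))
    tl <- total_loss(inst, plan)
    expect_gte(tl, 0)
    expect_lte(tl, ub + 1e-6 * ub)
    # adding delta kg on an admissible loaded route reduces the loss by
    # delta * (plateau - lambda(t_route)) * w
    idx <- which(plan$vehicles > 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    b <- idx[1L, ]
    k <- 1L
    room <- min(inst$demand[b[3L], k] - sum(plan$shipped[, , b[3L], k, ]),
                inst$ppe_supply[b[1L], k] - sum(plan$shipped[b[1L], , , k, ]),
                inst$dc_ppe_cap[b[2L], k] - sum(plan$shipped[, b[2L], , k, ]),
                inst$vehicle_capacity[b[4L]] * plan$vehicles[b[1L], b[2L],
                                                             b[3L], b[4L]] -
                  sum(plan$shipped[b[1L], b[2L], b[3L], , b[4L]]))
    if (room <= 0) next
    delta <- room / 2
    plan2 <- plan
    plan2$shipped[b[1L], b[2L], b[3L], k, b[4L]] <-
      plan2$shipped[b[1L], b[2L], b[3L], k, b[4L]] + delta
    lam <- waiting_cost(inst$curves[[k]],
                        route_time(inst, b[1L], b[2L], b[3L], b[4L]))
    expected_drop <- unname(delta * (inst$curves[[k]]$plateau - lam) *
                              inst$ppe_weight[k])
    expect_equal(total_loss(inst, plan) - total_loss(inst, plan2),
                 expected_drop, tolerance = 1e-9)
    expect_lte(total_loss(inst, plan2), tl + 1e-9 * max(1, tl))
  }
})

test_that("logistics cost sums rents and distance-proportional transport", {
  inst <- wenzhou_case(seed = 1)
  expect_equal(logistics_cost(inst, zero_plan(inst)), 0)
  # one heavy vehicle on a 100 km path from an open DC1
  inst$distance[1, 1, 1] <- 100000
  plan <- zero_plan(inst)
  plan$open_dc[1] <- 1
  plan$vehicles[1, 1, 1, 3] <- 1
  expect_equal(logistics_cost(inst, plan), 800000 + 100000 * 0.3)
  expect_equal(logistics_cost(inst, plan), 830000)
  # both DCs open, nothing moved
  plan2 <- zero_plan(inst)
  plan2$open_dc[] <- 1
  expect_equal(logistics_cost(inst, plan2), 1.4e6)
})

test_that("the constraint checker reports tagged violations with slack", {
  inst <- toy_instance(distance = 200000, coverage = 150000)
  expect_identical(nrow(check_feasibility(inst, zero_plan(inst))), 0L)

  # vehicles on a path beyond coverage: constraint (5)
  plan <- zero_plan(inst)
  plan$vehicles[1, 1, 1, 1] <- 1
  plan$open_dc[1] <- 1
  viol <- check_feasibility(inst, plan)
  expect_true("(5)" %in% viol$constraint)

  # load above vehicle capacity: constraint (10)
  inst2 <- toy_instance(demand = 1000, supply = 1500, u = 2, vcap = 600)
  plan2 <- allocation_plan(inst2, 1, array(1, c(1, 1, 1, 1)),
                           array(800, c(1, 1, 1, 1, 1)))
  viol2 <- check_feasibility(inst2, plan2)
  expect_true("(10)" %in% viol2$constraint)
  expect_lt(viol2$slack[viol2$constraint == "(10)"], 0)

  # flows through a closed DC: (8) and (9)
  plan3 <- allocation_plan(inst2, 0, array(1, c(1, 1, 1, 1)),
                           array(500, c(1, 1, 1, 1, 1)))
  viol3 <- check_feasibility(inst2, plan3)
  expect_true(all(c("(8)", "(9)") %in% viol3$constraint))
})

test_that("every random feasible plan passes the checker", {
  for (s in 1:6) {
    inst <- tiny_instance(s)
    plan <- random_feasible_plan(inst, seed = s)
    expect_identical(nrow(check_feasibility(inst, plan)), 0L)
  }
})
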