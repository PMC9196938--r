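test_that("the cost ideal is zero and the loss ideal matches the oracle", {
  for (s in c(2, 4)) {
    inst <- tiny_instance(s)
    lv <- ideal_levels(inst)
    expect_equal(lv$R2, 0)
    o <- enumerate_oracle(inst, "G1", cap = 1e5)
    expect_equal(lv$R1, o$objective, tolerance = 1e-6)
  }
  # supply >= demand over zero-length paths: everything arrives at t = 0
  inst0 <- toy_instance(distance = 1e-9, demand = 1000, supply = 1500,
                        u = 2, vcap = 600)
  lv0 <- ideal_levels(inst0)
  expect_equal(lv0$R1, 0, tolerance = 1e-6)
})

test_that("worst-case loss matches the closed form and the solver", {
  inst <- wenzhou_case(seed = 1)
  wv <- worst_values(inst)
  expect_equal(wv$max_G1, 2.8222e10)
  expect_equal(wv$max_G1, (931000 * 0.6 + 14600 * 0.4) * 50000)

  # zero demand: nothing to lose
  inst0 <- toy_instance(demand = 0)
  expect_equal(worst_values(inst0)$max_G1, 0)

  # closed form equals the maximization solve on enumerable instances
  for (s in c(1, 3)) {
    ti <- tiny_instance(s)
    wvt <- worst_values(ti, cross_check = TRUE)
    expect_equal(wvt$max_G1, wvt$max_G1_solved, tolerance = 1e-9)
  }
})

test_that("percentage deviation reproduces the case-study compromise", {
  # printed bounds of the cost objective and the achieved deviation
  expect_equal(percentage_deviation(3.1975e6, 0, 3.7105e6), 0.8617,
               tolerance = 1e-4)
  expect_identical(percentage_deviation(5, 5, 9), 0)
  expect_identical(percentage_deviation(9, 5, 9), 1)
  expect_error(percentage_deviation(1, 3, 2), "upper")
  expect_warning(dv <- percentage_deviation(4, 4, 4), "degenerate")
  expect_identical(dv, 0)
  expect_warning(percentage_deviation(10, 0, 5), "outside")
  # affine invariance under positive rescaling
  set.seed(1)
  for (i in 1:20) {
    lo <- runif(1, 0, 10); hi <- lo + runif(1, 0.1, 10)
    cur <- runif(1, lo, hi); a <- runif(1, 0.01, 100)
    expect_equal(percentage_deviation(cur, lo, hi),
                 percentage_deviation(a * cur, a * lo, a * hi))
  }
})

test_that("the tradeoff trace is non-increasing in the loss multiplier", {
  for (s in c(3, 6)) {
    inst <- tiny_instance(s)
    pt <- pareto_trace(inst, c(1, 2, 4, 10))
    expect_identical(nrow(pt), 4L)
    expect_true(all(diff(pt$min_G2) <= 1e-6 * pmax(1, pt$min_G2[-4])))
    # once the ceiling is slack everywhere, the cost reaches its own ideal
    expect_equal(pt$min_G2[4], 0, tolerance = 1e-6)
    # at multiplier 1 the base compromise is reproduced
    lv <- ideal_levels(inst)
    base <- lexicographic_solve(inst, goal_spec(c(lv$R1, lv$R2)))
    expect_equal(pt$min_G2[1], base$objectives$logistics_cost,
                 tolerance = 1e-9)
  }
})

test_that("the robustness scan shows zero solution error on tiny instances", {
  inst <- tiny_instance(5)
  sc <- sensitivity_scan(inst, c(1, 2, 5), reference = "oracle",
                         oracle_cap = 1e5)
  expect_identical(nrow(sc), 3L)
  expect_true(all(sc$error <= 1e-6))
  sc1 <- sensitivity_scan(inst, 1, reference = "plain")
  expect_identical(nrow(sc1), 1L)
  expect_true(all(sc1$error <= 1e-6))
})
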