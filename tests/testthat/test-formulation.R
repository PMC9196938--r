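test_that("variable catalog matches the network combinatorics", {
  f <- build_formulation(wenzhou_case(seed = 1))
  expect_identical(sum(f$catalog$kind == "binary"), 2L)
  expect_identical(sum(f$catalog$kind == "integer"), 90L)     # 3*2*5*3
  expect_identical(sum(f$catalog$kind == "continuous"), 180L) # 3*2*5*2*3

  # 1x1x1x1x1 toy: one row per constraint family (6)-(11)
  ft <- build_formulation(toy_instance())
  expect_identical(length(ft$rhs), 6L)
  expect_setequal(ft$tag, c("(6)", "(7)", "(8)", "(9)", "(10)", "(11)"))
})

test_that("paths beyond coverage get zero vehicle bounds", {
  inst <- toy_instance(distance = 200000, coverage = 150000)
  f <- build_formulation(inst)
  xub <- f$catalog$ub[f$catalog$kind == "integer"]
  expect_true(all(xub == 0))
  # at the coverage radius exactly, the path is allowed (<=)
  inst2 <- toy_instance(distance = 150000, coverage = 150000)
  f2 <- build_formulation(inst2)
  expect_true(all(f2$catalog$ub[f2$catalog$kind == "integer"] > 0))
})

test_that("objective vectors linearize the direct evaluators", {
  # on random feasible plans of random instances, the coefficient-vector
  # objectives must agree with the array-based evaluators to 1e-9 relative
  for (s in 1:10) {
    inst <- synthetic_instance(small_config(s))
    f <- build_formulation(inst)
    for (ps in 1:10) {
      plan <- random_feasible_plan(inst, seed = 1000 * s + ps)
      v <- embed_plan(f, plan)
      g1_lin <- eval_objective(f, v, "G1")
      g2_lin <- eval_objective(f, v, "G2")
      expect_equal(g1_lin, total_loss(inst, plan),
                   tolerance = 1e-9)
      expect_equal(g2_lin, logistics_cost(inst, plan),
                   tolerance = 1e-9)
    }
  }
})

test_that("plans round-trip through the catalog vector", {
  inst <- tiny_instance(1)
  f <- build_formulation(inst)
  plan <- random_feasible_plan(inst, seed = 5)
  v <- embed_plan(f, plan)
  back <- extract_plan(f, v)
  expect_equal(back$open_dc, plan$open_dc)
  expect_equal(back$vehicles, plan$vehicles)
  expect_equal(back$shipped, plan$shipped)

  # zero vector -> zero plan
  z <- extract_plan(f, numeric(f$nvar))
  expect_true(all(z$open_dc == 0) && all(z$vehicles == 0) &&
                all(z$shipped == 0))

  # near-integers round, genuine fractions error
  v2 <- v
  xi <- which(f$catalog$kind == "integer" & v > 0)[1L]
  v2[xi] <- v[xi] - 1e-9
  expect_equal(extract_plan(f, v2)$vehicles, plan$vehicles)
  v2[xi] <- v[xi] + 0.5
  expect_error(extract_plan(f, v2), "fractional")
})

test_that("goal rows encode G_n + theta_n^- - theta_n^+ = R_n", {
  inst <- tiny_instance(2)
  f <- build_formulation(inst)
  spec <- goal_spec(c(1e7, 1e5))
  g <- attach_goal(f, spec)
  expect_identical(g$nvar, f$nvar + 4L)
  expect_identical(tail(g$sense, 2L), c("=", "="))

  # a feasible plan extends to a feasible goal point via the definition of
  # the deviations
  plan <- random_feasible_plan(inst, seed = 9)
  v <- embed_plan(f, plan)
  G1 <- eval_objective(f, v, "G1"); G2 <- eval_objective(f, v, "G2")
  th <- c(max(spec$ideals[1] - G1, 0), max(G1 - spec$ideals[1], 0),
          max(spec$ideals[2] - G2, 0), max(G2 - spec$ideals[2], 0))
  vg <- c(v, th)
  resid <- g$A %*% vg - g$rhs
  ok <- ifelse(g$sense == "<=", resid <= 1e-6 * pmax(1, abs(g$rhs)),
               abs(resid) <= 1e-6 * pmax(1, abs(g$rhs)))
  expect_true(all(ok))

  # weighted mode demands a large priority ratio
  expect_error(goal_spec(c(1, 1), priorities = c(2, 1), mode = "weighted"),
               "ratio|>=")
  expect_error(attach_goal(g, spec), "already")
})

test_that("the LP-format export lists variables, rows and integrality", {
  f <- build_formulation(toy_instance())
  p <- withr::local_tempfile(fileext = ".lp")
  write_lp_format(f, p)
  txt <- readLines(p)
  expect_true(any(grepl("^Minimize", txt)))
  expect_identical(sum(grepl("^ c[0-9]+:", txt)), 6L)
  expect_true(any(grepl("^General", txt)) && any(grepl("^Binary", txt)))
})
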