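# Solver correctness is anchored to the exhaustive enumeration oracle on
# instances small enough to enumerate, plus structural bound properties.

test_that("relaxation bounds the integer optimum from below", {
  for (s in 1:4) {
    inst <- tiny_instance(s)
    f <- build_formulation(inst)
    for (obj in c("G1", "G2")) {
      rel <- solve_lp_relaxation(f, obj)
      res <- branch_and_bound(f, obj)
      expect_identical(rel$status, "optimal")
      expect_lte(rel$objective,
                 res$objective + 1e-6 * max(1, abs(res$objective)))
    }
  }
})

test_that("plain and improved B&B match the enumeration oracle", {
  rel_err <- function(u, v) abs(u - v) / max(1, abs(v))
  n_better <- 0L; n_cases <- 0L
  for (s in 1:20) {
    inst <- tiny_instance(s)
    f <- build_formulation(inst)
    for (obj in c("G1", "G2")) {
      a <- branch_and_bound(f, obj)
      b <- improved_solve(f, obj)
      o <- enumerate_oracle(inst, obj, cap = 1e5)
      expect_identical(a$status, "optimal")
      expect_identical(b$status, "optimal")
      expect_lt(rel_err(a$objective, o$objective), 1e-6)
      # improved and plain agree exactly on every instance
      expect_lt(rel_err(b$objective, a$objective), 1e-9)
      expect_identical(a$gap, 0); expect_identical(b$gap, 0)
      # returned plans satisfy every constraint
      expect_identical(nrow(check_feasibility(inst, a$plan)), 0L)
      expect_identical(nrow(check_feasibility(inst, b$plan)), 0L)
      n_cases <- n_cases + 1L
      if (b$stats$nodes <= a$stats$nodes) n_better <- n_better + 1L
    }
  }
  # the warm-start cutoff should not enlarge the tree in most cases
  expect_gte(n_better, n_cases * 0.5)
})

test_that("an integral relaxation is recognized at the root", {
  # zero objective: the zero plan is relaxation-optimal and integral
  inst <- tiny_instance(3)
  f <- build_formulation(inst)
  res <- branch_and_bound(f, numeric(f$nvar))
  expect_identical(res$status, "optimal")
  expect_equal(res$objective, 0)
  expect_identical(res$stats$nodes, 1L)

  # min G2 has the empty plan as an integral relaxation optimum
  r2 <- improved_solve(f, "G2")
  expect_equal(r2$objective, 0)
})

test_that("zero-supply instances are solved by the zero plan", {
  inst <- toy_instance(supply = 0)
  o <- enumerate_oracle(inst, "G1", cap = 100)
  expect_equal(o$objective,
               sum(inst$demand) * inst$curves[[1]]$plateau)
  f <- build_formulation(inst)
  expect_equal(branch_and_bound(f, "G1")$objective, o$objective)
})

test_that("solves are deterministic including tree statistics", {
  inst <- tiny_instance(4)
  f <- build_formulation(inst)
  r1 <- improved_solve(f, "G1")
  r2 <- improved_solve(f, "G1")
  expect_identical(r1$objective, r2$objective)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$x, r2$x)
})

test_that("the oracle refuses oversized enumeration", {
  expect_error(enumerate_oracle(wenzhou_case(seed = 1), "G2", cap = 1e5),
               "cap")
})

test_that("lexicographic staging reaches the ideal loss level first", {
  for (s in c(1, 5, 7)) {
    inst <- tiny_instance(s)
    lv <- ideal_levels(inst)
    expect_equal(lv$R2, 0)
    lex <- lexicographic_solve(inst, goal_spec(c(lv$R1, lv$R2)))
    # R1 is attainable, so the dominant deviation vanishes
    expect_lte(lex$theta[["theta1_plus"]], 1e-6 * max(1, lv$R1))
    # stage 2 matches the two-stage enumeration oracle
    og <- oracle_goal(inst, c(lv$R1, lv$R2), cap = 1e5)
    expect_equal(lex$theta[["theta2_plus"]], og$theta2_plus,
                 tolerance = 1e-6)
    expect_true(lex$complementarity_ok)
    expect_identical(nrow(check_feasibility(inst, lex$plan)), 0L)
    # deliveries never pay rent for closed DCs: the renting term equals the
    # sum over DCs carrying flow (solver never opens an unused DC here)
    used <- apply(lex$plan$vehicles, 2L, sum) > 0
    expect_true(all(lex$plan$open_dc[used] == 1))
  }
})

test_that("relaxing the loss ceiling cannot increase the minimum cost", {
  inst <- tiny_instance(2)
  lv <- ideal_levels(inst)
  costs <- vapply(c(1, 3, 10), function(k) {
    lexicographic_solve(inst,
                        goal_spec(c(k * lv$R1, lv$R2)))$objectives$logistics_cost
  }, 0)
  expect_true(all(diff(costs) <= 1e-6 * pmax(1, costs[-length(costs)])))
})

test_that("weighted goal mode agrees with staging when priorities dominate", {
  inst <- tiny_instance(6)
  lv <- ideal_levels(inst)
  lex <- lexicographic_solve(inst, goal_spec(c(lv$R1, lv$R2)))
  wt <- goal_solve(inst, goal_spec(c(lv$R1, lv$R2),
                                   priorities = c(1e8, 1),
                                   mode = "weighted"))
  expect_identical(wt$status, "optimal")
  expect_equal(wt$objectives$logistics_cost,
               lex$objectives$logistics_cost,
               tolerance = 1e-5)
})

test_that("tree statistics export as structured JSON", {
  inst <- tiny_instance(1)
  f <- build_formulation(inst)
  res <- branch_and_bound(f, "G1")
  js <- jsonlite::fromJSON(tree_stats_json(res))
  expect_identical(js$status, "optimal")
  expect_identical(js$nodes, res$stats$nodes)
  expect_true(is.data.frame(js$log) || length(js$log) == 0)
})
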