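test_that("degenerate noise reproduces the deterministic optimum exactly", {
  prob <- population_problem(floor = 12836)
  mc <- run_monte_carlo(prob, ec_cv = 0, cost_band = 0, n_sims = 5, seed = 3)
  expect_equal(mc$n_infeasible, 0L)
  point <- solve_problem(prob)
  expect_true(all(mc$inclusion_freq[c("OIL_ENHANCED", "BOUILLON")] == 100))
  expect_true(all(mc$inclusion_freq[c("OIL_44", "MAIZE_BIOFORT", "VAS_SOUTH",
                                      "VAS_CITIES")] == 0))
  expect_equal(mc$totals$lo, mc$totals$hi, tolerance = 1e-9)
  expect_equal(mc$totals$point[2], point$total_cost)
})

test_that("inclusion frequencies are reproducible and stable across halves", {
  prob <- population_problem(floor = 12836)
  a <- run_monte_carlo(prob, n_sims = 150, seed = 21)
  a2 <- run_monte_carlo(prob, n_sims = 150, seed = 21)
  expect_identical(a$inclusion_freq, a2$inclusion_freq)
  b <- run_monte_carlo(prob, n_sims = 150, seed = 22)
  expect_true(all(abs(a$inclusion_freq - b$inclusion_freq) < 5 + 1e-9))
})

test_that("widening the cost band never narrows the total-cost interval", {
  prob <- population_problem(floor = 12836)
  narrow <- run_monte_carlo(prob, cost_band = 0.05, n_sims = 120, seed = 31)
  wide <- run_monte_carlo(prob, cost_band = 0.30, n_sims = 120, seed = 31)
  width <- function(x) {
    r <- x$totals[x$totals$measure == "cost", ]
    r$hi - r$lo
  }
  expect_gte(width(wide), width(narrow))
})

test_that("infeasible replicates are counted, not dropped", {
  prob <- population_problem()
  too_high <- solve_problem(prob, floor = 1e6)
  expect_equal(too_high$status, "infeasible")
  mc <- run_monte_carlo(build_problem(population_coverage_table(),
                                      floor = 1e6),
                        n_sims = 4, seed = 5)
  expect_equal(mc$n_infeasible, 4L)
})
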