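pc_tbl <- population_coverage_table()
profiles <- default_region_profiles()
cm <- default_cost_model()

test_that("trivial floors give trivial solutions", {
  prob <- population_problem(floor = 0)
  res <- solve_problem(prob)
  expect_equal(res$status, "optimal")
  expect_equal(res$total_cost, 0)
  expect_equal(nrow(res$activations), 0L)

  res_inf <- solve_problem(prob, floor = 99999)
  expect_equal(res_inf$status, "infeasible")
  expect_true(is.finite(res_inf$max_attainable))
  expect_lt(res_inf$max_attainable, 99999)
})

test_that("a missing program combination is reported", {
  broken <- pc_tbl[!(pc_tbl$region == "SOUTH" & pc_tbl$bouillon == 1), ]
  expect_error(build_problem(broken, cm, profiles), "missing")
})

test_that("the solver agrees with brute-force enumeration on reduced instances", {
  regions <- c("NORTH", "SOUTH")
  H <- 3L
  cfg <- default_config()
  pop <- sapply(profiles[regions], project_child_population, years = H)

  # independent oracle: enumerate every (oil start, bouillon start, VAS set)
  ecf <- function(r, o, b, v) {
    pc_tbl$ec_frac[pc_tbl$region == r & pc_tbl$oil_level == o &
                     pc_tbl$bouillon == b & pc_tbl$maize == 0 & pc_tbl$vas == v]
  }
  oracle <- function(floor) {
    best <- Inf
    for (oil_start in 0:H) for (bou_start in 0:H) {
      for (vas_mask in 0:(2^(2 * H) - 1)) {
        vas <- matrix(bitwAnd(vas_mask, 2^(0:(2 * H - 1))) > 0, H, 2)
        cov <- 0; cost <- 0
        for (ri in 1:2) for (y in 1:H) {
          o <- if (oil_start > 0 && y >= oil_start) 0.44 else 0
          b <- as.integer(bou_start > 0 &&
                            y >= bou_start + cfg$programs$bouillon_startup_years)
          cov <- cov + ecf(regions[ri], o, b, as.integer(vas[y, ri])) * pop[y, ri]
          if (vas[y, ri]) {
            cost <- cost + annual_cost(cm, "VAS", regions[ri], y, pop[y, ri])
          }
        }
        share <- function(k) sum(unlist(cm$costs[[k]]$region_share[regions]))
        if (oil_start > 0) {
          cost <- cost + sum(sapply(oil_start:H, function(y)
            (cm$costs$OIL_44$operating_annual + cm$costs$OIL_44$me_annual))) *
            share("OIL_44")
        }
        if (bou_start > 0) {
          cost <- cost + sum(sapply(bou_start:H, function(y) {
            op <- y - bou_start + 1
            (if (op <= cm$costs$BOUILLON$startup_years)
              cm$costs$BOUILLON$startup_annual else
                cm$costs$BOUILLON$operating_annual) + cm$costs$BOUILLON$me_annual
          })) * share("BOUILLON")
        }
        if (cov >= floor - 1e-9 && cost < best) best <- cost
      }
    }
    best
  }

  prob <- build_problem(pc_tbl, cm, profiles, floor = NULL, horizon = H,
                        regions = regions,
                        programs = c("OIL_44", "BOUILLON", "VAS"))
  for (floor in c(200, 600, 1200, 2000)) {
    res <- solve_problem(prob, floor = floor)
    expect_equal(res$total_cost, unname(oracle(floor)), tolerance = 1e-8,
                 label = paste("floor", floor))
  }
})

test_that("optimal cost is monotone nondecreasing in the coverage floor", {
  prob <- population_problem()
  floors <- seq(2000, 14000, by = 2000)
  costs <- sapply(floors, function(f) solve_problem(prob, floor = f)$total_cost)
  expect_true(all(diff(costs) >= -1e-9))
})

test_that("scaling every cost leaves the chosen activations unchanged", {
  prob <- population_problem(floor = 12836)
  base <- solve_problem(prob)
  doubled <- solve_problem(prob, cost_multipliers = c(
    OIL_44 = 2, OIL_ENHANCED = 2, BOUILLON = 2, MAIZE_BIOFORT = 2, VAS = 2))
  expect_equal(doubled$activations, base$activations)
  expect_equal(doubled$total_cost, 2 * base$total_cost, tolerance = 1e-9)
})

test_that("the solution never costs more than business-as-usual when BAU is feasible", {
  prob <- population_problem()   # default floor = BAU coverage
  res <- solve_problem(prob)
  expect_equal(res$status, "optimal")
  expect_lte(res$total_cost, prob$bau$cost + 1e-6)
})

test_that("a single-program universe is forced to take every year", {
  prob <- build_problem(pc_tbl, cm, profiles, horizon = 10,
                        regions = "NORTH", programs = "VAS")
  max_cov <- prob$bau$coverage   # BAU here is just VAS (no oil available)
  ec_vas <- pc_tbl$ec_frac[pc_tbl$region == "NORTH" & pc_tbl$oil_level == 0 &
                             pc_tbl$bouillon == 0 & pc_tbl$maize == 0 &
                             pc_tbl$vas == 1]
  pop <- project_child_population(profiles$NORTH, 10)
  full_cov <- ec_vas * sum(pop)
  res <- solve_problem(prob, floor = full_cov - 1e-6)
  expect_equal(sort(res$activations$year), 1:10)
  expect_equal(res$total_cost,
               sum(sapply(1:10, function(y)
                 annual_cost(cm, "VAS", "NORTH", y, pop[y]))),
               tolerance = 1e-8)
})
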