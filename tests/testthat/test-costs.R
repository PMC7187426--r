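cm <- default_cost_model()
profiles <- default_region_profiles()

test_that("annual costs hit the printed per-year anchors", {
  popS <- project_child_population(profiles$SOUTH, 10)
  # South supplementation runs about $1.3m per year when mature
  expect_lt(abs(annual_cost(cm, "VAS", "SOUTH", 5, popS[5]) / 1300 - 1), 0.02)
  # mature South oil + bouillon fortification ~ $336k/yr including M&E
  mature <- annual_cost(cm, "OIL_ENHANCED", "SOUTH", 5, popS[5], op_year = 5) +
    annual_cost(cm, "BOUILLON", "SOUTH", 5, popS[5], op_year = 5)
  expect_lt(abs(mature / 336 - 1), 0.02)
  # variable term vanishes with no children
  v0 <- annual_cost(cm, "VAS", "NORTH", 1, 0)
  v1 <- annual_cost(cm, "VAS", "NORTH", 1, 1000)
  expect_equal(v0, cm$costs$VAS$fixed_annual$NORTH)
  expect_gt(v1, v0)
})

test_that("ten-year scenario totals match the printed program totals", {
  bau <- horizon_cost(cm, bau_spec(), profiles)
  expect_lt(abs(bau$cost[bau$region == "NATIONAL"] / 30051 - 1), 0.02)
  opt <- horizon_cost(cm, optimal_spec(), profiles)
  expect_lt(abs(opt$cost[opt$region == "NATIONAL"] / 9537 - 1), 0.02)

  empty <- scenario_spec(tibble::tibble(program = character(),
                                        region = character(), year = integer()))
  e <- horizon_cost(cm, empty, profiles)
  expect_equal(e$cost[e$region == "NATIONAL"], 0)
})

test_that("regional totals add exactly to the national total", {
  for (spec in list(bau_spec(), optimal_spec())) {
    hc <- horizon_cost(cm, spec, profiles)
    expect_equal(sum(hc$cost[hc$region != "NATIONAL"]),
                 hc$cost[hc$region == "NATIONAL"])
  }
})

test_that("cost is additive over disjoint activation sets", {
  a <- scenario_spec(expand.grid(program = "OIL_44", region = REGIONS,
                                 year = 1:10, stringsAsFactors = FALSE))
  b <- scenario_spec(expand.grid(program = "VAS", region = "NORTH",
                                 year = 1:4, stringsAsFactors = FALSE))
  u <- scenario_spec(rbind(as.data.frame(a), as.data.frame(b)))
  tot <- function(s) {
    hc <- horizon_cost(cm, s, profiles)
    hc$cost[hc$region == "NATIONAL"]
  }
  expect_equal(tot(u), tot(a) + tot(b), tolerance = 1e-10)
})

test_that("supplementation cost rises strictly with the child population", {
  costs <- sapply(c(500, 1000, 1500),
                  function(p) annual_cost(cm, "VAS", "CITIES", 1, p))
  expect_true(all(diff(costs) > 0))
})

test_that("cost-effectiveness ratios follow the reporting conventions", {
  expect_equal(cost_effectiveness(2657, 5075), 0.52)     # USD/CY, cents
  expect_equal(cost_effectiveness(26923, 8586), 3.14)
  expect_equal(cost_effectiveness(7, 7), 1.00)
  expect_equal(cost_effectiveness(2657, 9724, per = "death"), 273)
  expect_error(cost_effectiveness(100, 0), "undefined")
})
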