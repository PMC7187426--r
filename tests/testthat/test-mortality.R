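test_that("deaths averted scale with coverage inside the regional envelope", {
  mort <- default_mortality_profiles()
  s <- mort$SOUTH
  expect_equal(deaths_averted(s, 0, 1), 0)
  # the full resolvable burden saves the whole envelope (~780/yr printed)
  expect_equal(deaths_averted(s, s$baseline_prev, 4), 780)
  # default map is linear: halving coverage halves deaths averted
  expect_equal(deaths_averted(s, s$baseline_prev / 2, 4),
               deaths_averted(s, s$baseline_prev, 4) / 2)
  expect_error(deaths_averted(s, 1.2, 1), "\\[0, 1\\]")
})

test_that("deaths averted never exceed the vitamin-A-preventable envelope", {
  mort <- default_mortality_profiles()
  for (r in REGIONS) {
    prof <- mort[[r]]
    for (cv in seq(0, 1, by = 0.1)) {
      for (y in c(1, 5, 10)) {
        expect_lte(deaths_averted(prof, cv, y),
                   prof$va_preventable_deaths * (1 + prof$growth_rate)^(y - 1) + 1e-9)
      }
    }
  }
})

test_that("supplementation adds little mortality benefit once fortification matures", {
  pc <- population_coverage_table()
  mort <- default_mortality_profiles()$SOUTH
  ec <- function(b, v) pc$ec_frac[pc$region == "SOUTH" & pc$oil_level == 1 &
                                    pc$bouillon == b & pc$maize == 0 & pc$vas == v]
  marginal_mature <- deaths_averted(mort, ec(1, 1), 5) - deaths_averted(mort, ec(1, 0), 5)
  solo_vas <- pc$ec_frac[pc$region == "SOUTH" & pc$oil_level == 0 &
                           pc$bouillon == 0 & pc$maize == 0 & pc$vas == 1]
  solo_deaths <- deaths_averted(mort, solo_vas, 5)
  expect_lt(marginal_mature, 0.15 * solo_deaths)
})

test_that("the North envelope reproduces the supplementation deaths-averted total", {
  pc <- population_coverage_table()
  mort <- default_mortality_profiles()$NORTH
  ec_vas <- pc$ec_frac[pc$region == "NORTH" & pc$oil_level == 0 &
                         pc$bouillon == 0 & pc$maize == 0 & pc$vas == 1]
  total <- sum(deaths_averted(mort, ec_vas, 1:10))
  expect_lt(abs(total / 13630 - 1), 0.02)
})
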