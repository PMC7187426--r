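test_that("program dose arithmetic follows the fortification contents", {
  rec <- tibble::tibble(oil_g_day = 10, bouillon_g_day = 2, maize_kcal_day = 100,
                        vas_received = FALSE)
  expect_equal(added_intake(rec, program("OIL_44"), year = 5), 10 * 12 * 0.44)
  # bouillon delivers nothing during its startup years
  expect_equal(added_intake(rec, program("BOUILLON", start_year = 1), year = 2), 0)
  expect_equal(added_intake(rec, program("BOUILLON", start_year = 1), year = 4),
               2 * 80)
  expect_equal(added_intake(rec, program("MAIZE_BIOFORT", start_year = 1), year = 7),
               100 * 0.34)
  # supplementation only reaches recorded recipients
  expect_equal(added_intake(rec, program("VAS", scope = "NORTH"), year = 1), 0)
  rec$vas_received <- TRUE
  expect_equal(added_intake(rec, program("VAS", scope = "NORTH"), year = 1), 167)
  # enhanced oil ramps 44 / 72 / 100% of the 12 ug/g target
  expect_equal(added_intake(rec, program("OIL_ENHANCED"), year = 2), 10 * 12 * 0.72)
  expect_equal(added_intake(rec, program("OIL_ENHANCED"), year = 9), 10 * 12)
  rec$oil_g_day <- -1
  expect_error(added_intake(rec, program("OIL_44"), year = 1), "negative")
})

test_that("scenario specifications are validated structurally", {
  # national program active in one region only
  expect_error(scenario_spec(data.frame(program = "BOUILLON", region = "NORTH",
                                        year = 1)), "only some regions")
  # the two oil programs are mutually exclusive
  both <- rbind(expand.grid(program = "OIL_44", region = REGIONS, year = 1),
                expand.grid(program = "OIL_ENHANCED", region = REGIONS, year = 1))
  expect_error(scenario_spec(both), "both active")
  # sunk-capital programs cannot be interrupted
  gap <- expand.grid(program = "BOUILLON", region = REGIONS, year = c(1, 2, 5))
  expect_error(scenario_spec(gap), "not contiguous")
  expect_error(scenario_spec(data.frame(program = "X", region = "NORTH", year = 1)),
               "unknown program")
  expect_s3_class(bau_spec(), "scenario_spec")
})

test_that("the empty scenario is the identity and saturation covers everything", {
  sm <- small_pipeline()
  empty <- scenario_spec(tibble::tibble(program = character(),
                                        region = character(), year = integer()))
  oc <- run_scenario(sm$surveys, sm$fits, empty, profiles = sm$profiles)
  expect_equal(oc$prevalence, oc$baseline_prevalence)
  expect_true(all(oc$effective_coverage_frac == 0))

  # an enormous universal dose removes all inadequacy
  fit <- sm$fits$NORTH
  sv <- sm$surveys$NORTH
  expect_equal(prevalence_inadequate(fit, records = sv, added = 1e4), 0)
})

test_that("coverage is monotone in the program set (superadditivity floor)", {
  st <- coverage_state_table(small_pipeline()$surveys, small_pipeline()$fits)
  key <- function(d) split(d$ec_frac, d$region)
  for (r in unique(st$region)) {
    sub <- st[st$region == r, ]
    for (i in seq_len(nrow(sub))) {
      dominated <- sub$oil_level <= sub$oil_level[i] &
        sub$bouillon <= sub$bouillon[i] & sub$maize <= sub$maize[i] &
        sub$vas <= sub$vas[i]
      expect_true(all(sub$ec_frac[dominated] <= sub$ec_frac[i] + 1e-9))
    }
  }
})

test_that("fortification reach equals the vehicle consumer fraction", {
  sm <- small_pipeline()
  spec <- scenario_spec(expand.grid(program = "BOUILLON", region = REGIONS,
                                    year = 1:10, stringsAsFactors = FALSE))
  oc <- run_scenario(sm$surveys, sm$fits, spec, profiles = sm$profiles)
  for (r in REGIONS) {
    frac <- sm$profiles[[r]]$bouillon_consumer_frac
    got <- oc$reach_frac[oc$region == r & oc$year == 5]
    bound <- qnorm(0.995) * sqrt(frac * (1 - frac) / nrow(sm$surveys[[r]]))
    expect_lt(abs(got - frac), bound + 1e-9)
  }
})

test_that("coverage in child-years scales linearly with population", {
  sm <- small_pipeline()
  profiles2 <- sm$profiles
  profiles2$NORTH$base_child_population <- 2 * profiles2$NORTH$base_child_population
  spec <- bau_spec()
  oc1 <- run_scenario(sm$surveys, sm$fits, spec, profiles = sm$profiles)
  oc2 <- run_scenario(sm$surveys, sm$fits, spec, profiles = profiles2)
  n1 <- oc1$effective_coverage_cy[oc1$region == "NORTH"]
  n2 <- oc2$effective_coverage_cy[oc2$region == "NORTH"]
  expect_equal(n2, 2 * n1, tolerance = 1e-10)
})

test_that("bouillon alone in the North covers about a quarter of child-years", {
  fp <- full_pipeline()
  spec <- scenario_spec(expand.grid(program = "BOUILLON", region = REGIONS,
                                    year = 1:10, stringsAsFactors = FALSE))
  oc <- run_scenario(fp$surveys, fp$fits, spec, profiles = fp$profiles)
  avg_frac <- sum(oc$effective_coverage_cy[oc$region == "NORTH"]) / 12700
  expect_lt(abs(avg_frac - 3300 / 12700), 0.05)
})

test_that("shift-based and refit scenario prevalences agree at moderate doses", {
  sm <- small_pipeline()
  spec <- scenario_spec(expand.grid(program = "OIL_44", region = REGIONS,
                                    year = 1:2, stringsAsFactors = FALSE))
  oc_shift <- run_scenario(sm$surveys["SOUTH"], sm$fits["SOUTH"], spec,
                           profiles = sm$profiles, horizon = 2)
  oc_refit <- run_scenario(sm$surveys["SOUTH"], sm$fits["SOUTH"], spec,
                           profiles = sm$profiles, horizon = 2, refit = TRUE)
  expect_lt(max(abs(oc_shift$prevalence - oc_refit$prevalence)), 0.08)
})

test_that("population and survey coverage tables agree", {
  fp <- full_pipeline()
  pop <- population_coverage_table()
  svy <- coverage_state_table(fp$surveys, fp$fits)
  m <- dplyr::inner_join(pop, svy, by = c("region", "oil_level", "bouillon",
                                          "maize", "vas"),
                         suffix = c("_pop", "_svy"))
  expect_lt(max(abs(m$ec_frac_pop - m$ec_frac_svy)), 0.10)
  expect_lt(mean(abs(m$ec_frac_pop - m$ec_frac_svy)), 0.03)
})
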