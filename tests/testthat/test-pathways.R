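test_that("a degenerate threshold triggers immediately and withdraws earliest", {
  sm <- small_pipeline()
  one <- run_pathway("SOUTH", sm$surveys$SOUTH, sm$fits$SOUTH,
                     mode = "one_study", threshold = 1.0,
                     profiles = sm$profiles, scenario_method = "shift")
  expect_equal(one$trigger_year, 1L)
  expect_equal(one$validation_years, 1L)
  expect_equal(one$vas_off_year, 2L)
  two <- run_pathway("SOUTH", sm$surveys$SOUTH, sm$fits$SOUTH,
                     mode = "two_study", threshold = 1.0,
                     profiles = sm$profiles, scenario_method = "shift")
  expect_equal(two$validation_years, c(1L, 3L))   # nonconsecutive years
  expect_equal(two$vas_off_year, 4L)
  expect_error(run_pathway("SOUTH", sm$surveys$SOUTH, sm$fits$SOUTH,
                           threshold = 0), "threshold")
})

test_that("two-study validations always fall in nonconsecutive years", {
  sm <- small_pipeline()
  for (th in c(0.05, 0.2, 0.6)) {
    pw <- run_pathway("CITIES", sm$surveys$CITIES, sm$fits$CITIES,
                      mode = "two_study", threshold = th,
                      profiles = sm$profiles, scenario_method = "shift")
    if (length(pw$validation_years) == 2) {
      expect_gte(diff(pw$validation_years), 2)
    }
    expect_true(all(pw$table$cost_validation[pw$table$validation_study] > 0))
    expect_true(all(pw$table$cost_validation[!pw$table$validation_study] == 0))
  }
})

test_that("fortification prevalence never rises while doses ramp up", {
  sm <- small_pipeline()
  for (r in REGIONS) {
    pw <- run_pathway(r, sm$surveys[[r]], sm$fits[[r]], profiles = sm$profiles)
    expect_true(all(diff(pw$table$prevalence) <= 1e-9))
    # supplementation is present every year before withdrawal
    if (!is.na(pw$vas_off_year)) {
      expect_true(all(pw$table$vas_active[seq_len(pw$vas_off_year - 1)]))
      expect_false(any(pw$table$vas_active[pw$vas_off_year:10]))
    } else {
      expect_true(all(pw$table$vas_active))
    }
  }
})

test_that("never-triggering regions still undertake exactly one study", {
  sm <- small_pipeline()
  pw <- run_pathway("NORTH", sm$surveys$NORTH, sm$fits$NORTH,
                    mode = "two_study", profiles = sm$profiles)
  expect_true(is.na(pw$trigger_year))
  expect_equal(pw$validation_years, 4)
  expect_equal(sum(pw$table$validation_study), 1L)
  expect_true(all(pw$table$vas_active))
})

test_that("a failed validation keeps supplementation in place", {
  sm <- small_pipeline()
  cfg <- default_config()
  cfg$pathways$validation_confirms <- FALSE
  pw <- run_pathway("CITIES", sm$surveys$CITIES, sm$fits$CITIES,
                    mode = "one_study", config = cfg, profiles = sm$profiles)
  expect_true(all(pw$table$vas_active))
  expect_true(is.na(pw$vas_off_year))
})

test_that("scenario cost ordering: one-study cheapest, BAU dearest nationally", {
  sm <- small_pipeline()
  cs <- compare_scenarios(sm$surveys, sm$fits, profiles = sm$profiles)
  expect_true(all(cs$one_study <= cs$two_study + 1e-9))
  nat <- cs[cs$region == "NATIONAL", ]
  expect_lte(nat$two_study, nat$bau)
  expect_lte(nat$one_study, nat$two_study)
  # regions where both modes collapse (no trigger) differ by nothing
  north <- cs[cs$region == "NORTH", ]
  expect_equal(north$two_minus_one, 0)
})
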