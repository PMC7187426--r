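test_that("identical seeds reproduce the dataset bit for bit", {
  p <- default_region_profiles()$NORTH
  a <- generate_survey(p, 300, seed = 42)
  b <- generate_survey(p, 300, seed = 42)
  expect_identical(a, b)
  c <- generate_survey(p, 300, seed = 43)
  expect_false(isTRUE(all.equal(a$day1_intake, c$day1_intake)))
})

test_that("generator-known prevalence is calibrated to the regional target", {
  profiles <- default_region_profiles()
  sv <- generate_survey(profiles$NORTH, 2000, seed = 1)
  true_prev <- mean(attr(sv, "usual_true") < ear_for(sv$age_months, sv$sex))
  expect_lt(abs(true_prev - 0.73), 0.01)

  # different seeds stay within Monte Carlo range of the target
  for (s in 2:4) {
    sv <- generate_survey(profiles$SOUTH, 1000, seed = s)
    tp <- mean(attr(sv, "usual_true") < ear_for(sv$age_months, sv$sex))
    se <- sqrt(0.35 * 0.65 / 1000)
    expect_lt(abs(tp - 0.35), 0.01 + 3 * se)
  }
})

test_that("degenerate settings behave as their definitions require", {
  p0 <- toy_profile(within_cv = 0)
  sv <- generate_survey(p0, 200, seed = 3)
  expect_equal(sv$day1_intake, attr(sv, "usual_true"))

  p1 <- toy_profile(oil_consumer_frac = 0)
  sv1 <- generate_survey(p1, 200, seed = 3)
  expect_true(all(sv1$oil_g_day == 0))

  expect_error(generate_survey(toy_profile(), 10), "n_children")
  expect_error(generate_survey(toy_profile(), 100, repeat_frac = 0), "repeat_frac")
})

test_that("empirical consumer fractions match the profile within binomial bounds", {
  p <- default_region_profiles()$SOUTH
  sv <- generate_survey(p, 4000, seed = 5)
  n <- nrow(sv)
  chk <- function(x, frac) {
    bound <- qnorm(0.995) * sqrt(frac * (1 - frac) / n)
    expect_lt(abs(mean(x) - frac), bound + 1e-9)
  }
  chk(sv$oil_g_day > 0, p$oil_consumer_frac)
  chk(sv$bouillon_g_day > 0, p$bouillon_consumer_frac)
  chk(sv$maize_kcal_day > 0, p$maize_consumer_frac)
  chk(sv$vas_received, p$vas_reach)
})

test_that("oil-consumer correlation preserves the marginal and tilts the joint", {
  p <- toy_profile(oil_consumer_frac = 0.5, oil_consumer_z_slope = 0.8)
  sv <- generate_survey(p, 6000, seed = 9)
  expect_lt(abs(mean(sv$oil_g_day > 0) - 0.5), 0.025)
  u <- attr(sv, "usual_true")
  # consumers should have systematically lower usual intake
  expect_lt(median(u[sv$oil_g_day > 0]), median(u[sv$oil_g_day == 0]))
})

test_that("raising the target prevalence lowers the calibrated median", {
  p_lo <- toy_profile(baseline_inadequate_prev = 0.3)
  p_hi <- toy_profile(baseline_inadequate_prev = 0.6)
  m_lo <- attr(generate_survey(p_lo, 1500, seed = 12), "intake_median_used")
  m_hi <- attr(generate_survey(p_hi, 1500, seed = 12), "intake_median_used")
  expect_gt(m_lo, m_hi)
})

test_that("population projections reproduce the ten-year child-year totals", {
  profiles <- default_region_profiles()
  sums <- sapply(profiles, function(p) sum(project_child_population(p, 10)))
  expect_lt(abs(sums[["NORTH"]] / 12700 - 1), 0.01)
  expect_lt(abs(sums[["SOUTH"]] / 13900 - 1), 0.01)
  expect_lt(abs(sums[["CITIES"]] / 5800 - 1), 0.01)
  expect_lt(abs(sum(sums) / 32500 - 1), 0.01)

  flat <- toy_profile(pop_growth_rate = 0)
  expect_equal(project_child_population(flat, 5), rep(1000, 5))
  geo <- toy_profile(base_child_population = 1000, pop_growth_rate = 0.02)
  expect_equal(project_child_population(geo, 2), c(1000, 1020))
})

test_that("survey CSV round-trips", {
  sv <- generate_survey(toy_profile(), 120, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(sv, path)
  back <- read_survey_csv(path)
  expect_equal(back$day1_intake, sv$day1_intake)
  expect_equal(back$vas_received, sv$vas_received)
})
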