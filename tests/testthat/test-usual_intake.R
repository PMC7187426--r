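test_that("estimated prevalence recovers the generator truth", {
  p <- default_region_profiles()$NORTH
  p$within_cv <- 0.5
  sv <- generate_survey(p, 2000, seed = 1)
  true_prev <- mean(attr(sv, "usual_true") < ear_for(sv$age_months, sv$sex))
  fit <- fit_usual_intake(sv)
  expect_lt(abs(prevalence_inadequate(fit, records = sv) - true_prev), 0.02)
})

test_that("recovery bias stays under 0.02 across the within-person CV grid", {
  profiles <- default_region_profiles()
  for (r in c("NORTH", "SOUTH")) {
    for (cv in c(0.4, 0.8)) {
      p <- profiles[[r]]
      p$within_cv <- cv
      errs <- sapply(1:4, function(s) {
        sv <- generate_survey(p, 1500, seed = 100 + s)
        tp <- mean(attr(sv, "usual_true") < ear_for(sv$age_months, sv$sex))
        prevalence_inadequate(fit_usual_intake(sv), records = sv) - tp
      })
      expect_lt(abs(mean(errs)), 0.02)
    }
  }
})

test_that("no measurement error collapses usual intake to the day mean", {
  sv <- generate_survey(toy_profile(within_cv = 0.4), 400, seed = 6)
  sv$day2_intake <- sv$day1_intake        # repeats identical to day 1
  fit <- fit_usual_intake(sv)
  expect_lt(fit$var_within, 1e-4)
  expect_equal(usual_intakes(fit), sv$day1_intake, tolerance = 0.02)
})

test_that("prevalence is scale-equivariant", {
  sv <- generate_survey(toy_profile(), 800, seed = 8)
  k <- 2.7
  sc <- sv
  sc$day1_intake <- sc$day1_intake * k
  sc$day2_intake <- sc$day2_intake * k
  ears <- default_ear_table()
  ears_over_k <- default_ear_table(190 / k, 210 / k, 275 / k)
  p_scaled <- prevalence_inadequate(fit_usual_intake(sc), ears, sc)
  p_orig <- prevalence_inadequate(fit_usual_intake(sv), ears_over_k, sv)
  expect_lt(abs(p_scaled - p_orig), 0.015)
})

test_that("variance-component separation requires repeat days", {
  sv <- generate_survey(toy_profile(), 200, seed = 4)
  sv$day2_intake <- NA_real_
  expect_error(fit_usual_intake(sv), "second recall")
  expect_error(fit_usual_intake(sv[1:20, ]), "at least 30")
})

test_that("estimated usual intakes are less dispersed than single days", {
  sm <- small_pipeline()
  for (r in names(sm$fits)) {
    expect_lte(var(usual_intakes(sm$fits[[r]])),
               var(sm$surveys[[r]]$day1_intake))
  }
})

test_that("adding intake never increases prevalence", {
  sm <- small_pipeline()
  fit <- sm$fits$SOUTH
  sv <- sm$surveys$SOUTH
  prevs <- sapply(c(0, 10, 50, 100, 250, 1000),
                  function(d) prevalence_inadequate(fit, records = sv, added = d))
  expect_true(all(diff(prevs) <= 1e-12))
})

test_that("degenerate EAR cut-offs give degenerate prevalences", {
  sm <- small_pipeline()
  sv <- sm$surveys$NORTH
  fit <- sm$fits$NORTH
  lo <- default_ear_table(1e-9, 1e-9, 1e-9)
  hi <- default_ear_table(1e9, 1e9, 1e9)
  expect_equal(prevalence_inadequate(fit, lo, sv), 0)
  expect_equal(prevalence_inadequate(fit, hi, sv), 1)
})

test_that("a missing EAR bracket is reported by name", {
  ears <- tibble::tibble(age_min = 12L, age_max = 47L, sex = "any", ear = 210)
  expect_error(ear_for(c(24, 50), "F", ears), "50")
})

test_that("calibrated SOUTH baseline prevalence is estimated near 0.35", {
  fp <- full_pipeline()
  est <- prevalence_inadequate(fp$fits$SOUTH, records = fp$surveys$SOUTH)
  expect_lt(abs(est - 0.35), 0.02)
})

test_that("the model does not cover foreign records", {
  sm <- small_pipeline()
  other <- sm$surveys$SOUTH
  expect_error(prevalence_inadequate(sm$fits$NORTH, records = other),
               "does not cover")
})
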