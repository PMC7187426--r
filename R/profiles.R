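#' Macroregion profile
#'
#' Bundles everything the synthetic-survey generator needs to emulate one
#' macroregion of the 2009-style dietary survey: the usual-intake
#' distribution (lognormal median and between-person CV), the within-person
#' recall error CV, fortification-vehicle consumption (consumer fraction plus
#' a lognormal amount distribution per vehicle), supplementation reach, and
#' the child population trajectory.
#'
#' @param region one of `"NORTH"`, `"SOUTH"`, `"CITIES"`.
#' @param baseline_inadequate_prev target fraction of children with usual
#'   intake below their EAR before any intervention.
#' @param intake_median median usual vitamin A intake, ug RAE/day.
#' @param between_cv between-person CV of usual intake.
#' @param within_cv within-person (day-to-day) CV of a single recall.
#' @param oil_consumer_frac,bouillon_consumer_frac,maize_consumer_frac
#'   fraction of children consuming each fortification vehicle.
#' @param oil_g_day_dist,bouillon_g_day_dist,maize_kcal_day_dist named numeric
#'   vectors `c(median =, cv =)` describing consumption amounts among
#'   consumers (grams/day for oil and bouillon, kcal/day for maize).
#' @param vas_reach fraction of children receiving high-dose supplements.
#' @param oil_consumer_z_slope probit slope linking oil-consumer status to
#'   the child's usual-intake z-score (0 = independent; positive values mean
#'   oil consumers have poorer baseline vitamin A intake, as when fortifiable
#'   refined oil substitutes for provitamin-A-rich red palm oil). The
#'   marginal consumer fraction is unchanged by the slope.
#' @param base_child_population year-1 child population ('000s).
#' @param pop_growth_rate annual growth rate of the child population.
#' @return an object of class `"region_profile"`.
#' @export
region_profile <- function(region,
                           baseline_inadequate_prev,
                           intake_median,
                           between_cv,
                           within_cv,
                           oil_consumer_frac, oil_g_day_dist,
                           bouillon_consumer_frac, bouillon_g_day_dist,
                           maize_consumer_frac, maize_kcal_day_dist,
                           vas_reach,
                           base_child_population,
                           pop_growth_rate,
                           oil_consumer_z_slope = 0) {
  region <- match.arg(region, REGIONS)
  fracs <- c(baseline_inadequate_prev, oil_consumer_frac,
             bouillon_consumer_frac, maize_consumer_frac, vas_reach)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (oil_consumer_z_slope < -0.99 || oil_consumer_z_slope > 0.99) {
    stop("oil_consumer_z_slope must be in (-0.99, 0.99)", call. = FALSE)
  }
  if (between_cv < 0 || within_cv < 0) stop("CVs must be >= 0", call. = FALSE)
  if (intake_median <= 0) stop("intake_median must be > 0", call. = FALSE)
  if (base_child_population <= 0) stop("population must be > 0", call. = FALSE)
  for (d in list(oil_g_day_dist, bouillon_g_day_dist, maize_kcal_day_dist)) {
    if (!all(c("median", "cv") %in% names(d)) || d[["median"]] < 0 || d[["cv"]] < 0) {
      stop("amount distributions need nonnegative 'median' and 'cv'", call. = FALSE)
    }
  }
  structure(list(
    region = region,
    baseline_inadequate_prev = baseline_inadequate_prev,
    intake_median = intake_median,
    between_cv = between_cv,
    within_cv = within_cv,
    oil_consumer_frac = oil_consumer_frac,
    oil_g_day_dist = oil_g_day_dist,
    bouillon_consumer_frac = bouillon_consumer_frac,
    bouillon_g_day_dist = bouillon_g_day_dist,
    maize_consumer_frac = maize_consumer_frac,
    maize_kcal_day_dist = maize_kcal_day_dist,
    vas_reach = vas_reach,
    base_child_population = base_child_population,
    pop_growth_rate = pop_growth_rate,
    oil_consumer_z_slope = oil_consumer_z_slope
  ), class = "region_profile")
}

#' @export
print.region_profile <- function(x, ...) {
  cat("<region_profile>", x$region,
      sprintf("| baseline prev %.2f | intake median %.0f ug RAE/d (CV %.2f)\n",
              x$baseline_inadequate_prev, x$intake_median, x$between_cv))
  invisible(x)
}

#' Default macroregion profiles
#'
#' Builds the three calibrated macroregion profiles from a configuration.
#' The intake and consumption parameters stored in the packaged
#' configuration were solved by [calibrate_region_profiles()] against the
#' printed planning anchors and are reproduced by that function.
#'
#' @param config configuration list, see [load_config()].
#' @return named list of [region_profile()] objects.
#' @export
default_region_profiles <- function(config = default_config()) {
  g <- config$pop_growth_rate
  horizon <- config$horizon_years
  growth_sum <- sum((1 + g)^(seq_len(horizon) - 1))
  out <- lapply(REGIONS, function(r) {
    rc <- config$regions[[r]]
    region_profile(
      region = r,
      baseline_inadequate_prev = rc$baseline_inadequate_prev,
      intake_median = rc$intake_median,
      between_cv = rc$between_cv,
      within_cv = rc$within_cv,
      oil_consumer_frac = rc$oil_consumer_frac,
      oil_g_day_dist = c(median = rc$oil_g_day$median, cv = rc$oil_g_day$cv),
      bouillon_consumer_frac = rc$bouillon_consumer_frac,
      bouillon_g_day_dist = c(median = rc$bouillon_g_day$median,
                              cv = rc$bouillon_g_day$cv),
      maize_consumer_frac = rc$maize_consumer_frac,
      maize_kcal_day_dist = c(median = rc$maize_kcal_day$median,
                              cv = rc$maize_kcal_day$cv),
      vas_reach = rc$vas_reach,
      base_child_population = rc$cy_10yr / growth_sum,
      pop_growth_rate = g,
      oil_consumer_z_slope = rc$oil_consumer_z_slope %||% 0
    )
  })
  names(out) <- REGIONS
  out
}

#' Project the child population of a region
#'
#' Geometric growth from the profile's base population. Default profiles are
#' scaled so the ten-year sums reproduce the printed child-year totals
#' (12.7m North, 13.9m South, 5.8m Cities; 32.5m nationally, within 1%).
#'
#' @param profile a [region_profile()].
#' @param years number of years to project (>= 1).
#' @return numeric vector of per-year child populations ('000s).
#' @export
project_child_population <- function(profile, years) {
  stopifnot(inherits(profile, "region_profile"))
  if (!is.numeric(years) || years < 1) stop("years must be >= 1", call. = FALSE)
  profile$base_child_population * (1 + profile$pop_growth_rate)^(seq_len(years) - 1)
}

# populations as a years x regions matrix ('000s)
population_matrix <- function(profiles, years = 10) {
  sapply(profiles, project_child_population, years = years)
}
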