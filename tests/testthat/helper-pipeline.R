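# Shared fixtures, built once per test session. The "small" pipeline keeps
# unit tests fast; the "full" pipeline (survey sizes used by the analysis
# scripts) backs the acceptance checks.
pipeline_cache <- new.env(parent = emptyenv())

small_pipeline <- function() {
  if (is.null(pipeline_cache$small)) {
    profiles <- default_region_profiles()
    surveys <- generate_surveys(profiles, n_children = 1200, seed = 11)
    fits <- lapply(surveys, fit_usual_intake)
    pipeline_cache$small <- list(profiles = profiles, surveys = surveys,
                                 fits = fits)
  }
  pipeline_cache$small
}

full_pipeline <- function() {
  if (is.null(pipeline_cache$full)) {
    profiles <- default_region_profiles()
    surveys <- generate_surveys(profiles, n_children = 4000, seed = 7)
    fits <- lapply(surveys, fit_usual_intake)
    pipeline_cache$full <- list(profiles = profiles, surveys = surveys,
                                fits = fits)
  }
  pipeline_cache$full
}

population_problem <- function(floor = NULL) {
  if (is.null(pipeline_cache$pop_table)) {
    pipeline_cache$pop_table <- population_coverage_table()
  }
  build_problem(pipeline_cache$pop_table, floor = floor)
}

# a deliberately small profile for targeted generator tests
toy_profile <- function(...) {
  args <- list(
    region = "NORTH", baseline_inadequate_prev = 0.5, intake_median = 200,
    between_cv = 0.6, within_cv = 0.5,
    oil_consumer_frac = 0.5, oil_g_day_dist = c(median = 10, cv = 0.4),
    bouillon_consumer_frac = 0.8, bouillon_g_day_dist = c(median = 2, cv = 0.4),
    maize_consumer_frac = 0.4, maize_kcal_day_dist = c(median = 100, cv = 0.4),
    vas_reach = 0.7, base_child_population = 1000, pop_growth_rate = 0.014)
  do.call(region_profile, utils::modifyList(args, list(...)))
}
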