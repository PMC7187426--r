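#' Mortality profiles: vitamin-A-preventable deaths by macroregion
#'
#' A simplified stand-in for a full cause-of-death projection: each region
#' carries an annual envelope of vitamin-A-preventable child deaths, and
#' deaths averted scale with effective coverage expressed as a fraction of
#' the resolvable burden (the baseline prevalence of inadequate intake).
#' The South (~780/yr) and Cities (~355/yr) envelopes are printed planning
#' anchors; the North envelope is derived so the ten-year supplementation
#' deaths-averted total for the North is reproduced by the calibrated
#' coverage stream.
#'
#' @param region macroregion id.
#' @param va_preventable_deaths annual envelope, deaths/year in year 1.
#' @param growth_rate annual growth of the envelope (default 0: flat).
#' @param baseline_prev baseline prevalence of inadequate intake used to
#'   normalise coverage into a fraction of the resolvable burden.
#' @return a `"mortality_profile"` object.
#' @export
mortality_profile <- function(region, va_preventable_deaths, growth_rate = 0,
                              baseline_prev) {
  region <- match.arg(region, REGIONS)
  stopifnot(va_preventable_deaths >= 0, baseline_prev > 0, baseline_prev <= 1)
  structure(list(region = region,
                 va_preventable_deaths = va_preventable_deaths,
                 growth_rate = growth_rate,
                 baseline_prev = baseline_prev),
            class = "mortality_profile")
}

#' @rdname mortality_profile
#' @param config configuration list.
#' @return `default_mortality_profiles()`: named list of profiles.
#' @export
default_mortality_profiles <- function(config = default_config()) {
  out <- lapply(REGIONS, function(r) {
    mortality_profile(
      region = r,
      va_preventable_deaths = config$mortality$va_preventable_deaths[[r]],
      growth_rate = config$mortality$growth_rate,
      baseline_prev = config$regions[[r]]$baseline_inadequate_prev)
  })
  names(out) <- REGIONS
  out
}

#' Child deaths averted by effective coverage
#'
#' `deaths = envelope(year) * g(coverage)`, with the effectiveness map `g`
#' monotone, `g(0) = 0` and `g(1) = 1`. The default `g` is proportional
#' scaling of coverage by the resolvable burden
#' (`coverage / baseline_prev`, capped at 1), so deaths averted can never
#' exceed the region-year envelope — the largest number of lives any program
#' combination can save.
#'
#' @param profile a [mortality_profile()].
#' @param effective_coverage_frac effective coverage as a prevalence-point
#'   fraction of all children, in \[0, 1\].
#' @param year calendar year (1-based) for the envelope trajectory.
#' @return deaths averted (children/year).
#' @export
deaths_averted <- function(profile, effective_coverage_frac, year = 1) {
  stopifnot(inherits(profile, "mortality_profile"))
  if (any(effective_coverage_frac < 0 | effective_coverage_frac > 1)) {
    stop("effective_coverage_frac must be in [0, 1]", call. = FALSE)
  }
  envelope <- profile$va_preventable_deaths *
    (1 + profile$growth_rate)^(year - 1)
  g <- pmin(1, effective_coverage_frac / profile$baseline_prev)
  envelope * g
}
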