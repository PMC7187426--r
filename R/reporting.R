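#' Per-program impact and cost-effectiveness table
#'
#' Runs each candidate program alone over the horizon and tabulates, per
#' macroregion and nationally: reach and effective coverage ('000s of
#' child-years), child deaths averted, total cost ('000s USD), and the three
#' cost-effectiveness ratios (per child reached, per child-year effectively
#' covered — dollars and cents — and per death averted — whole dollars).
#'
#' @param surveys,fits named lists per region.
#' @param config configuration list.
#' @param profiles region profiles.
#' @param programs program kinds to tabulate.
#' @return tibble, one row per program x region (plus NATIONAL rows).
#' @export
impact_table <- function(surveys, fits, config = default_config(),
                         profiles = default_region_profiles(config),
                         programs = PROGRAM_KINDS) {
  H <- config$horizon_years
  pop <- population_matrix(profiles, H)
  out <- list()
  for (kind in programs) {
    spec <- scenario_spec(spec_from_years(kind, seq_len(H)))
    oc <- run_scenario(surveys, fits, spec, config, profiles)
    oc$reach_cy <- oc$reach_frac * pop[cbind(oc$year, match(oc$region, colnames(pop)))]
    by <- dplyr::summarise(
      dplyr::group_by(oc, .data$region),
      reach_cy = sum(.data$reach_cy),
      effective_coverage_cy = sum(.data$effective_coverage_cy),
      deaths_averted = sum(.data$deaths_averted),
      cost = sum(.data$cost), .groups = "drop")
    nat <- dplyr::summarise(
      by, region = "NATIONAL", reach_cy = sum(.data$reach_cy),
      effective_coverage_cy = sum(.data$effective_coverage_cy),
      deaths_averted = sum(.data$deaths_averted), cost = sum(.data$cost))
    tab <- dplyr::bind_rows(nat, by)
    tab$program <- kind
    out[[kind]] <- tab
  }
  tab <- dplyr::bind_rows(out)
  tab$cost_per_child_reached <- mapply(cost_effectiveness, tab$cost, tab$reach_cy,
                                       MoreArgs = list(per = "child"))
  tab$cost_per_cy_covered <- mapply(cost_effectiveness, tab$cost,
                                    tab$effective_coverage_cy,
                                    MoreArgs = list(per = "cy"))
  tab$cost_per_death_averted <- mapply(cost_effectiveness, tab$cost,
                                       tab$deaths_averted,
                                       MoreArgs = list(per = "death"))
  tab[, c("program", "region", "reach_cy", "effective_coverage_cy",
          "deaths_averted", "cost", "cost_per_child_reached",
          "cost_per_cy_covered", "cost_per_death_averted")]
}

#' Scenario summary in the planning-table layout
#'
#' Ten-year child-years effectively covered, total cost and cost per
#' child-year, nationally and by macroregion, for a given scenario.
#'
#' @param surveys,fits named lists per region.
#' @param spec a [scenario_spec()].
#' @param config configuration list.
#' @param profiles region profiles.
#' @return tibble with columns `region`, `effective_coverage_cy`, `cost`,
#'   `cost_per_cy`.
#' @export
scenario_summary <- function(surveys, fits, spec, config = default_config(),
                             profiles = default_region_profiles(config)) {
  oc <- run_scenario(surveys, fits, spec, config, profiles)
  tot <- scenario_totals(oc)
  tot$cost_per_cy <- mapply(cost_effectiveness, tot$cost,
                            tot$effective_coverage_cy,
                            MoreArgs = list(per = "cy"))
  tot
}
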