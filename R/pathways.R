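#' Policy pathway for one macroregion
#'
#' Simulates the staged transition from business-as-usual toward the
#' cost-effective program set under the supplementation-withdrawal protocol:
#' the fixed fortification build-out runs from year 1 (enhanced oil ramping
#' 44/72/100% of target by year 3; bouillon benefits from year 4) with
#' supplementation retained. The first year the fortification-only
#' prevalence of inadequate intake falls below `threshold` triggers a
#' biomarker validation study; in `"one_study"` mode supplementation is
#' withdrawn the following year, in `"two_study"` mode a second study is
#' scheduled two years after the first (a nonconsecutive year) and
#' supplementation is withdrawn the year after that. In regions that never
#' cross the threshold supplementation runs the whole horizon and a single
#' validation study is still charged (it confirms that withdrawal is not yet
#' warranted).
#'
#' The trigger tracks dietary intake including fortification but excluding
#' the supplementation equivalent: the protocol asks whether the *diet* has
#' become adequate enough to withdraw supplements.
#'
#' Prevalences are estimated by refitting the usual-intake model on the
#' program-shifted recall days (`scenario_method = "refit"`, the default for
#' pathways): the far-tail prevalence the 2.5% trigger reads is sensitive to
#' the joint distribution of habitual intake and the child's own vehicle
#' consumption, which per-child point-estimate shifting attenuates. The
#' transform power is kept at the value chosen on the observed data.
#'
#' @param region macroregion id.
#' @param survey,fit that region's survey and fitted intake model.
#' @param mode `"two_study"` (default) or `"one_study"`.
#' @param threshold prevalence trigger (default 0.025).
#' @param config configuration list.
#' @param profiles region profiles.
#' @param scenario_method `"refit"` (default) or `"shift"` (reuse the
#'   baseline fit and shift person-level usual intakes).
#' @param state_prevs optional precomputed state-prevalence lookup from
#'   [pathway_state_prevalences()] (reused across modes).
#' @return a `"pathway_result"`: per-year tibble (`prevalence`, program
#'   flags, lives saved by fortification alone and in total, cost
#'   components), plus `trigger_year`, `validation_years`, `vas_off_year`.
#' @export
run_pathway <- function(region, survey, fit,
                        mode = c("two_study", "one_study"),
                        threshold = NULL,
                        config = default_config(),
                        profiles = default_region_profiles(config),
                        scenario_method = c("refit", "shift"),
                        state_prevs = NULL) {
  region <- match.arg(region, REGIONS)
  mode <- match.arg(mode)
  scenario_method <- match.arg(scenario_method)
  if (is.null(threshold)) threshold <- config$pathways$threshold
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  H <- config$horizon_years
  ears <- config_ear_table(config)
  cost_model <- default_cost_model(config)
  mort <- default_mortality_profiles(config)[[region]]
  pop <- project_child_population(profiles[[region]], H)
  lag2 <- config$pathways$second_study_lag
  confirms <- isTRUE(config$pathways$validation_confirms)

  ramp <- config$programs$oil_enhanced_ramp
  oil_factor <- function(y) if (y <= length(ramp)) ramp[y] else ramp[length(ramp)]
  bou_su <- config$programs$bouillon_startup_years

  if (is.null(state_prevs)) {
    state_prevs <- pathway_state_prevalences(survey, fit, config,
                                             method = scenario_method)
  }
  prev_state <- function(of, bou_on, vas_on) {
    state_prevs[[state_key(of, bou_on, vas_on)]]
  }
  prev0 <- prevalence_inadequate(fit, ears, survey)

  phase <- "VAS_ON"
  trigger_year <- NA_integer_
  validation_years <- integer(0)
  vas_off_year <- NA_integer_
  rows <- list()
  for (y in seq_len(H)) {
    prev_fort <- prev_state(oil_factor(y), y > bou_su, FALSE)
    vas_on <- is.na(vas_off_year) || y < vas_off_year
    validation <- FALSE

    if (vas_on && phase %in% c("VAS_ON", "TRIGGERED") && is.na(trigger_year) &&
        prev_fort < threshold) {
      trigger_year <- y
      phase <- "TRIGGERED"
    }
    if (!is.na(trigger_year) && y == trigger_year) {
      validation <- TRUE
      validation_years <- c(validation_years, y)
      if (confirms) {
        phase <- "VALIDATION_DONE_1"
        if (mode == "one_study") vas_off_year <- y + 1L
      } else {
        phase <- "VAS_ON"; trigger_year <- NA_integer_
      }
    } else if (mode == "two_study" && phase == "VALIDATION_DONE_1" &&
               !is.na(trigger_year) && y == trigger_year + lag2) {
      validation <- TRUE
      validation_years <- c(validation_years, y)
      phase <- "VALIDATION_DONE_2"
      vas_off_year <- y + 1L
    }
    if (!is.na(vas_off_year) && y >= vas_off_year) phase <- "VAS_OFF"

    ec_fort <- max(0, prev0 - prev_fort)
    prev_total <- if (vas_on) {
      prev_state(oil_factor(y), y > bou_su, TRUE)
    } else prev_fort
    ec_total <- max(0, prev0 - prev_total)

    cost_fort <-
      annual_cost(cost_model, "OIL_ENHANCED", region, y, pop[y], op_year = y) +
      annual_cost(cost_model, "BOUILLON", region, y, pop[y], op_year = y)
    cost_vas <- if (vas_on) {
      annual_cost(cost_model, "VAS", region, y, pop[y], op_year = y)
    } else 0
    cost_validation <- if (validation) validation_cost(cost_model, region) else 0

    rows[[y]] <- tibble::tibble(
      region = region, year = y,
      oil_factor = oil_factor(y), bouillon_active = y > bou_su,
      vas_active = vas_on, validation_study = validation,
      phase = phase,
      prevalence = prev_fort, prevalence_with_vas = prev_total,
      lives_fortification = deaths_averted(mort, ec_fort, y),
      lives_total = deaths_averted(mort, ec_total, y),
      cost_fortification = cost_fort, cost_vas = cost_vas,
      cost_validation = cost_validation,
      cost_total = cost_fort + cost_vas + cost_validation)
  }

  # never-triggering regions still undertake one study to document status
  if (!length(validation_years)) {
    vy <- config$pathways$default_validation_year
    rows[[vy]]$validation_study <- TRUE
    rows[[vy]]$cost_validation <- validation_cost(cost_model, region)
    rows[[vy]]$cost_total <- rows[[vy]]$cost_total + rows[[vy]]$cost_validation
    validation_years <- vy
  }

  structure(list(
    table = dplyr::bind_rows(rows),
    region = region, mode = mode, threshold = threshold,
    trigger_year = trigger_year,
    validation_years = validation_years,
    vas_off_year = vas_off_year
  ), class = "pathway_result")
}

state_key <- function(oil_factor, bou_on, vas_on) {
  sprintf("o%.2f_b%d_v%d", oil_factor, as.integer(bou_on), as.integer(vas_on))
}

#' Prevalence of inadequate intake for every pathway program state
#'
#' The pathway build-out visits a small set of dose states (oil at each ramp
#' level, bouillon off/on, supplementation off/on). This helper computes the
#' prevalence for each state once, either by refitting the usual-intake
#' model on shifted recall days (`"refit"`) or by shifting person-level
#' usual intakes under the baseline fit (`"shift"`).
#'
#' @param survey,fit one region's survey and baseline fitted model.
#' @param config configuration list.
#' @param method `"refit"` or `"shift"`.
#' @return named list of prevalences keyed by state.
#' @export
pathway_state_prevalences <- function(survey, fit, config = default_config(),
                                      method = c("refit", "shift")) {
  method <- match.arg(method)
  ears <- config_ear_table(config)
  ramp <- config$programs$oil_enhanced_ramp
  oil_levels <- unique(c(ramp, ramp[length(ramp)]))
  oil_add1 <- survey$oil_g_day * config$programs$oil_target_ug_per_g
  bou_add1 <- survey$bouillon_g_day * config$programs$bouillon_ug_per_g
  vas_add <- as.numeric(survey$vas_received) * config$programs$vas_daily_equivalent

  out <- list()
  for (of in oil_levels) for (b in c(FALSE, TRUE)) for (v in c(FALSE, TRUE)) {
    added <- of * oil_add1 + as.numeric(b) * bou_add1 + as.numeric(v) * vas_add
    prev <- if (method == "refit") {
      shifted <- survey
      shifted$day1_intake <- shifted$day1_intake + added
      shifted$day2_intake <- shifted$day2_intake + added
      refit <- fit_usual_intake(shifted, lambda_grid = fit$transform_lambda,
                                method = fit$method)
      prevalence_inadequate(refit, ears, shifted)
    } else {
      prevalence_inadequate(fit, ears, survey, added = added)
    }
    out[[state_key(of, b, v)]] <- prev
  }
  out
}

#' @export
print.pathway_result <- function(x, ...) {
  cat(sprintf("<pathway_result> %s (%s): trigger %s, validations [%s], VAS off %s\n",
              x$region, x$mode,
              ifelse(is.na(x$trigger_year), "never", x$trigger_year),
              paste(x$validation_years, collapse = ", "),
              ifelse(is.na(x$vas_off_year), "never", x$vas_off_year)))
  invisible(x)
}

#' Compare ten-year scenario costs: BAU vs one- vs two-study pathways
#'
#' For each region, the cost of (a) continuing business-as-usual (44%-target
#' oil plus supplementation, no validation studies), (b) the pathway with a
#' single validation study, and (c) the pathway with two studies in
#' nonconsecutive years. Also reports the incremental cost of the
#' two-study over the one-study pathway (the extra supplementation years
#' plus one extra study).
#'
#' @param surveys,fits named lists per region.
#' @param config configuration list.
#' @param profiles region profiles.
#' @param regions regions to include.
#' @return tibble with columns `region`, `bau`, `one_study`, `two_study`,
#'   `two_minus_one` ('000s USD), including a `NATIONAL` row.
#' @export
compare_scenarios <- function(surveys, fits, config = default_config(),
                              profiles = default_region_profiles(config),
                              regions = REGIONS) {
  cost_model <- default_cost_model(config)
  H <- config$horizon_years
  rows <- lapply(regions, function(r) {
    pop <- project_child_population(profiles[[r]], H)
    bau <- sum(vapply(seq_len(H), function(y) {
      annual_cost(cost_model, "OIL_44", r, y, pop[y], op_year = y) +
        annual_cost(cost_model, "VAS", r, y, pop[y], op_year = y)
    }, numeric(1)))
    sp <- pathway_state_prevalences(surveys[[r]], fits[[r]], config)
    one <- sum(run_pathway(r, surveys[[r]], fits[[r]], mode = "one_study",
                           config = config, profiles = profiles,
                           state_prevs = sp)$table$cost_total)
    two <- sum(run_pathway(r, surveys[[r]], fits[[r]], mode = "two_study",
                           config = config, profiles = profiles,
                           state_prevs = sp)$table$cost_total)
    tibble::tibble(region = r, bau = bau, one_study = one, two_study = two,
                   two_minus_one = two - one)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_rows(out, dplyr::summarise(
    out, region = "NATIONAL", bau = sum(.data$bau),
    one_study = sum(.data$one_study), two_study = sum(.data$two_study),
    two_minus_one = sum(.data$two_minus_one)))
}
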