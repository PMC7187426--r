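#' Intervention programs
#'
#' Five program kinds are modelled. `OIL_44`: the existing edible-oil
#' fortification program running at 44% of the 12 mg/kg target.
#' `OIL_ENHANCED`: the strengthened oil program whose compliance ramps
#' 44% / 72% / 100% of target over its first three years. `BOUILLON`:
#' bouillon-cube fortification at 80 mg/kg with a three-year start-up during
#' which costs accrue but no vitamin A is delivered. `MAIZE_BIOFORT`:
#' provitamin-A maize at 0.34 ug RAE/kcal after a three-year phase-in.
#' `VAS`: twice-annual high-dose supplementation, modelled as a constant
#' 167 ug RAE/day intake equivalent for children reached by the campaigns.
#'
#' @name programs
NULL

PROGRAM_KINDS <- c("OIL_44", "OIL_ENHANCED", "BOUILLON", "MAIZE_BIOFORT", "VAS")
NATIONAL_PROGRAMS <- c("OIL_44", "OIL_ENHANCED", "BOUILLON", "MAIZE_BIOFORT")

#' Define a program
#'
#' @param kind one of `r paste(PROGRAM_KINDS, collapse = ", ")`.
#' @param scope regions the program covers (national programs must cover all
#'   regions; supplementation may be deployed per macroregion).
#' @param start_year first calendar year of operation (1-based).
#' @return a `"program"` object.
#' @export
program <- function(kind, scope = REGIONS, start_year = 1L) {
  kind <- match.arg(kind, PROGRAM_KINDS)
  scope <- match.arg(scope, REGIONS, several.ok = TRUE)
  if (kind %in% NATIONAL_PROGRAMS && !setequal(scope, REGIONS)) {
    stop(kind, " is a national program and must cover all regions", call. = FALSE)
  }
  stopifnot(start_year >= 1)
  structure(list(kind = kind, scope = scope, start_year = as.integer(start_year),
                 startup_years = startup_years(kind)),
            class = "program")
}

startup_years <- function(kind, config = default_config()) {
  switch(kind,
    BOUILLON = config$programs$bouillon_startup_years,
    MAIZE_BIOFORT = config$programs$maize_startup_years,
    OIL_ENHANCED = 0L,  # benefits from day one, at ramped compliance
    0L)
}

#' Dose factor of a program in a given operating year
#'
#' Fraction of the full fortification target delivered: oil programs express
#' compliance with the 12 mg/kg target; bouillon and maize are 0 during
#' start-up and 1 afterwards; supplementation is 0/1 availability.
#'
#' @param kind program kind.
#' @param op_year operating year (1 = first year the program runs).
#' @param config configuration list.
#' @return dose factor in \[0, 1\].
#' @export
dose_factor <- function(kind, op_year, config = default_config()) {
  if (op_year < 1) return(0)
  switch(kind,
    OIL_44 = config$programs$oil_44_factor,
    OIL_ENHANCED = {
      ramp <- config$programs$oil_enhanced_ramp
      if (op_year <= length(ramp)) ramp[op_year] else ramp[length(ramp)]
    },
    BOUILLON = as.numeric(op_year > config$programs$bouillon_startup_years),
    MAIZE_BIOFORT = as.numeric(op_year > config$programs$maize_startup_years),
    VAS = 1
  )
}

#' Additional vitamin A intake contributed by one program
#'
#' Vehicle consumption times fortification content times the dose factor:
#' oil `g/day x 12 ug/g x factor`, bouillon `g/day x 80 ug/g x factor`,
#' maize `kcal/day x 0.34 ug/kcal x factor`; supplementation contributes the
#' daily equivalent to children recorded as reached, and nothing otherwise.
#'
#' @param records survey records (rows are children).
#' @param prog a [program()] object.
#' @param year calendar year (1-based); the operating year is
#'   `year - start_year + 1`.
#' @param config configuration list.
#' @return numeric vector of ug RAE/day, one per record.
#' @export
added_intake <- function(records, prog, year, config = default_config()) {
  stopifnot(inherits(prog, "program"))
  op_year <- year - prog$start_year + 1L
  if (op_year < 1) {
    stop("program ", prog$kind, " is not active in year ", year, call. = FALSE)
  }
  f <- dose_factor(prog$kind, op_year, config)
  vehicle <- switch(prog$kind,
    OIL_44 = records$oil_g_day * config$programs$oil_target_ug_per_g,
    OIL_ENHANCED = records$oil_g_day * config$programs$oil_target_ug_per_g,
    BOUILLON = records$bouillon_g_day * config$programs$bouillon_ug_per_g,
    MAIZE_BIOFORT = records$maize_kcal_day * config$programs$maize_ug_per_kcal,
    VAS = as.numeric(records$vas_received) * config$programs$vas_daily_equivalent
  )
  if (any(vehicle < 0, na.rm = TRUE)) {
    stop("negative vehicle amounts in records (", prog$kind, ")", call. = FALSE)
  }
  vehicle * f
}

#' Scenario specification
#'
#' A scenario is a set of `(program, region, year)` activations. National
#' fortification programs must be active in all regions or none in a given
#' year; the two oil programs are mutually exclusive; activations for
#' programs with sunk start-up capital must be contiguous.
#'
#' @param activations tibble/data.frame with columns `program`, `region`,
#'   `year`.
#' @return a validated `"scenario_spec"` (tibble with the same columns).
#' @export
scenario_spec <- function(activations) {
  act <- tibble::as_tibble(activations)
  need <- c("program", "region", "year")
  if (!all(need %in% names(act))) {
    stop("activations need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  act <- dplyr::distinct(act[, need])
  problems <- character()
  bad_kind <- setdiff(unique(act$program), PROGRAM_KINDS)
  if (length(bad_kind)) {
    problems <- c(problems, paste("unknown program:", paste(bad_kind, collapse = ", ")))
  }
  bad_region <- setdiff(unique(act$region), REGIONS)
  if (length(bad_region)) {
    problems <- c(problems, paste("unknown region:", paste(bad_region, collapse = ", ")))
  }
  if (!length(problems)) {
    for (kind in intersect(unique(act$program), NATIONAL_PROGRAMS)) {
      tab <- table(act$year[act$program == kind])
      partial <- names(tab)[tab != length(REGIONS)]
      if (length(partial)) {
        problems <- c(problems, paste0(kind, " active in only some regions in year(s) ",
                                       paste(partial, collapse = ", ")))
      }
    }
    oil_years <- intersect(act$year[act$program == "OIL_44"],
                           act$year[act$program == "OIL_ENHANCED"])
    if (length(oil_years)) {
      problems <- c(problems, paste("OIL_44 and OIL_ENHANCED both active in year(s)",
                                    paste(sort(unique(oil_years)), collapse = ", ")))
    }
    for (kind in c("OIL_ENHANCED", "BOUILLON", "MAIZE_BIOFORT")) {
      for (r in unique(act$region[act$program == kind])) {
        ys <- sort(unique(act$year[act$program == kind & act$region == r]))
        if (length(ys) && !identical(ys, seq(min(ys), max(ys)))) {
          problems <- c(problems, paste0(kind, " activation not contiguous in ", r))
        }
      }
    }
  }
  if (length(problems)) {
    stop("invalid scenario specification:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  class(act) <- c("scenario_spec", class(act))
  act
}

spec_from_years <- function(kind, years, regions = REGIONS) {
  expand.grid(program = kind, region = regions, year = years,
              stringsAsFactors = FALSE)
}

#' Built-in scenario specifications
#'
#' `bau_spec()` is the business-as-usual pair: national 44%-target oil
#' fortification plus national supplementation, all years. `optimal_spec()`
#' is the cost-minimising sequence found by the optimizer on calibrated
#' defaults: enhanced oil + bouillon nationally all years, supplementation in
#' the North in years 1-2 only.
#'
#' @param horizon number of years.
#' @return a [scenario_spec()].
#' @export
bau_spec <- function(horizon = 10) {
  scenario_spec(rbind(
    spec_from_years("OIL_44", seq_len(horizon)),
    spec_from_years("VAS", seq_len(horizon))
  ))
}

#' @rdname bau_spec
#' @param vas_north_years years with supplementation in the North.
#' @export
optimal_spec <- function(horizon = 10, vas_north_years = 1:2) {
  scenario_spec(rbind(
    spec_from_years("OIL_ENHANCED", seq_len(horizon)),
    spec_from_years("BOUILLON", seq_len(horizon)),
    spec_from_years("VAS", vas_north_years, regions = "NORTH")
  ))
}

# serialize / read a scenario spec as CSV (activation matrix)
#' @rdname scenario_spec
#' @param spec a scenario spec; `path` a CSV path.
#' @param path file path.
#' @export
write_scenario_spec <- function(spec, path) {
  utils::write.csv(spec, path, row.names = FALSE)
  invisible(path)
}

#' @rdname scenario_spec
#' @export
read_scenario_spec <- function(path) {
  scenario_spec(utils::read.csv(path, stringsAsFactors = FALSE))
}
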