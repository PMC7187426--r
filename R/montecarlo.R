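#' Monte Carlo robustness analysis of the optimization
#'
#' Re-solves the portfolio optimization under benefit and cost uncertainty:
#' each replicate perturbs every program-region effective-coverage stream by
#' an independent normal multiplier (mean 1, CV `ec_cv`, truncated at zero)
#' and every program's costs by an independent uniform multiplier in
#' `[1 - cost_band, 1 + cost_band]`, then records which programs the
#' re-solved optimum includes. Supplementation is counted as included in a
#' region when it is active at least `vas_min_years` years of the horizon.
#' Infeasible replicates are counted and reported, never dropped silently.
#'
#' @param problem an [build_problem()] object.
#' @param ec_cv coefficient of variation of the coverage perturbation.
#' @param cost_band half-width of the uniform cost perturbation.
#' @param n_sims number of replicates.
#' @param seed RNG seed (replicates are reproducible given the seed).
#' @param vas_min_years inclusion rule for supplementation.
#' @return a `"monte_carlo_summary"`: `inclusion_freq` (percent of
#'   replicates), `totals` (point estimate and 2.5/97.5 percentiles of
#'   coverage, cost and cost per child-year), `n_sims`, `n_infeasible`.
#' @export
run_monte_carlo <- function(problem, ec_cv = 0.05, cost_band = 0.2,
                            n_sims = 1000, seed = 1L, vas_min_years = 3L) {
  stopifnot(inherits(problem, "optimization_problem"))
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  R <- length(problem$regions)
  set.seed(seed)

  point <- solve_problem(problem)
  progs <- c("OIL_44", "OIL_ENHANCED", "BOUILLON", "MAIZE_BIOFORT")
  vas_keys <- paste0("VAS_", problem$regions)
  counts <- stats::setNames(numeric(length(progs) + R), c(progs, vas_keys))
  cov <- cost <- rep(NA_real_, n_sims)
  n_infeasible <- 0L

  for (s in seq_len(n_sims)) {
    ecm <- matrix(pmax(0, stats::rnorm(4 * R, mean = 1, sd = ec_cv)), 4, R)
    # one cost multiplier per program family: the enhanced oil program shares
    # the oil program's cost base, as it shares its coverage stream
    u <- stats::runif(4, 1 - cost_band, 1 + cost_band)
    cmv <- c(OIL_44 = u[1], OIL_ENHANCED = u[1], BOUILLON = u[2],
             MAIZE_BIOFORT = u[3], VAS = u[4])
    res <- solve_problem(problem, ec_multipliers = ecm, cost_multipliers = cmv)
    if (res$status != "optimal") {
      n_infeasible <- n_infeasible + 1L
      next
    }
    cov[s] <- res$total_coverage
    cost[s] <- res$total_cost
    if (res$plan$oil_kind == 1L) counts["OIL_44"] <- counts["OIL_44"] + 1
    if (res$plan$oil_kind == 2L) counts["OIL_ENHANCED"] <- counts["OIL_ENHANCED"] + 1
    if (res$plan$bou_start > 0) counts["BOUILLON"] <- counts["BOUILLON"] + 1
    if (res$plan$mai_start > 0) counts["MAIZE_BIOFORT"] <- counts["MAIZE_BIOFORT"] + 1
    if (nrow(res$activations)) {
      vas_years <- table(res$activations$region[res$activations$program == "VAS"])
      for (r in names(vas_years)) {
        if (vas_years[[r]] >= vas_min_years) {
          counts[paste0("VAS_", r)] <- counts[paste0("VAS_", r)] + 1
        }
      }
    }
  }

  n_ok <- n_sims - n_infeasible
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  totals <- tibble::tibble(
    measure = c("coverage_cy", "cost", "cost_per_cy"),
    point = c(point$total_coverage, point$total_cost,
              point$total_cost / point$total_coverage),
    lo = c(qs(cov)[1], qs(cost)[1], qs(cost / cov)[1]),
    hi = c(qs(cov)[2], qs(cost)[2], qs(cost / cov)[2]))

  structure(list(
    inclusion_freq = 100 * counts / max(1L, n_ok),
    totals = totals,
    n_sims = n_sims,
    n_infeasible = n_infeasible,
    seed = seed,
    noise = list(ec_cv = ec_cv, cost_band = cost_band,
                 vas_min_years = vas_min_years)
  ), class = "monte_carlo_summary")
}

#' @export
print.monte_carlo_summary <- function(x, ...) {
  cat(sprintf("<monte_carlo_summary> %d replicates (%d infeasible)\n",
              x$n_sims, x$n_infeasible))
  print(round(x$inclusion_freq, 1))
  print(as.data.frame(x$totals))
  invisible(x)
}

#' Write a Monte Carlo summary to JSON + CSV
#' @param x a summary from [run_monte_carlo()].
#' @param json_path,csv_path output paths (either may be NULL).
#' @return x, invisibly.
#' @export
write_monte_carlo <- function(x, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(x, "monte_carlo_summary"))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      inclusion_freq = as.list(x$inclusion_freq),
      totals = x$totals, n_sims = x$n_sims, n_infeasible = x$n_infeasible,
      seed = x$seed, noise = x$noise
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(tibble::tibble(program = names(x$inclusion_freq),
                                    inclusion_pct = unname(x$inclusion_freq)),
                     csv_path, row.names = FALSE)
  }
  invisible(x)
}
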