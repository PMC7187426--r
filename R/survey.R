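#' Generate a synthetic dietary survey for one macroregion
#'
#' Emulates the structure of a national 24-hour-recall micronutrient survey:
#' every child contributes one recall day and a random subsample contributes
#' a second day, enabling separation of within- and between-person variance.
#' Usual intake is drawn lognormal (median `intake_median`, CV `between_cv`);
#' an observed day is the child's usual intake times a mean-one lognormal
#' within-person error (CV `within_cv`). Vehicle consumption and supplement
#' receipt are drawn independently of intake from the profile's consumer
#' fractions and amount distributions.
#'
#' Unless `calibrate = FALSE`, the generator adjusts the intake median by
#' bisection so the realised (generator-known) prevalence of usual intake
#' below the EAR matches `baseline_inadequate_prev` within `tol` — the
#' sample, not just the population, is on target.
#'
#' @param profile a [region_profile()].
#' @param n_children number of children (>= 50).
#' @param repeat_frac fraction with a second recall day (0 < f <= 1).
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param ears EAR table used for calibration.
#' @param calibrate adjust the intake median to hit the target prevalence?
#' @param tol calibration tolerance on the prevalence scale.
#' @param max_iter bisection iteration cap.
#' @return a tibble of child records (one row per child) with columns
#'   `child_id`, `region`, `age_months`, `sex`, `day1_intake`, `day2_intake`
#'   (NA outside the repeat subsample), `oil_g_day`, `bouillon_g_day`,
#'   `maize_kcal_day`, `vas_received`, `weight`; attributes `usual_true`
#'   (generator-known usual intakes), `intake_median_used` and `seed`.
#' @export
generate_survey <- function(profile, n_children, repeat_frac = 0.3, seed = 1L,
                            ears = default_ear_table(), calibrate = TRUE,
                            tol = 0.01, max_iter = 80L) {
  stopifnot(inherits(profile, "region_profile"))
  if (n_children < 50) stop("n_children must be >= 50", call. = FALSE)
  if (repeat_frac <= 0 || repeat_frac > 1) {
    stop("repeat_frac must be in (0, 1]", call. = FALSE)
  }
  set.seed(seed)
  n <- as.integer(n_children)

  age_months <- sample(6:59, n, replace = TRUE)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  ear <- ear_for(age_months, sex, ears)

  sb <- lnorm_sdlog(profile$between_cv)
  sw <- lnorm_sdlog(profile$within_cv)
  z <- stats::rnorm(n)

  median_used <- profile$intake_median
  if (calibrate) {
    median_used <- calibrate_sample_median(z, sb, ear,
                                           target = profile$baseline_inadequate_prev,
                                           start = profile$intake_median,
                                           tol = tol, max_iter = max_iter)
  }
  usual <- median_used * exp(sb * z)

  # mean-one multiplicative recall error: a child's expected recall equals
  # the usual intake, and within_cv = 0 collapses to the usual intake itself
  day_error <- function() exp(sw * stats::rnorm(n) - sw^2 / 2)
  day1 <- usual * day_error()
  n_rep <- max(1L, ceiling(repeat_frac * n))
  repeat_ids <- sort(sample.int(n, n_rep))
  day2 <- rep(NA_real_, n)
  day2_all <- usual * day_error()
  day2[repeat_ids] <- day2_all[repeat_ids]

  draw_amount <- function(consumer, dist) {
    amt <- dist[["median"]] * exp(lnorm_sdlog(dist[["cv"]]) * stats::rnorm(n))
    ifelse(consumer, amt, 0)
  }
  # oil-consumer status may be correlated with the intake z-score (probit
  # link, marginal fraction preserved); other vehicles are independent
  a <- profile$oil_consumer_z_slope
  oil_consumer <- if (profile$oil_consumer_frac <= 0) rep(FALSE, n) else {
    a * z + sqrt(1 - a^2) * stats::rnorm(n) <
      stats::qnorm(profile$oil_consumer_frac)
  }
  oil <- draw_amount(oil_consumer, profile$oil_g_day_dist)
  bouillon <- draw_amount(stats::runif(n) < profile$bouillon_consumer_frac,
                          profile$bouillon_g_day_dist)
  maize <- draw_amount(stats::runif(n) < profile$maize_consumer_frac,
                       profile$maize_kcal_day_dist)
  vas <- stats::runif(n) < profile$vas_reach

  out <- tibble::tibble(
    child_id = sprintf("%s-%05d", substr(profile$region, 1, 1), seq_len(n)),
    region = profile$region,
    age_months = age_months,
    sex = sex,
    day1_intake = day1,
    day2_intake = day2,
    oil_g_day = oil,
    bouillon_g_day = bouillon,
    maize_kcal_day = maize,
    vas_received = vas,
    weight = 1
  )
  attr(out, "usual_true") <- usual
  attr(out, "intake_median_used") <- median_used
  attr(out, "seed") <- as.integer(seed)
  out
}

# Bisection on the log of the intake median so that the share of drawn usual
# intakes below the child-specific EAR hits the target. Monotone: a larger
# median can only lower the prevalence.
calibrate_sample_median <- function(z, sb, ear, target, start, tol, max_iter) {
  prev_at <- function(log_m) mean(exp(log_m + sb * z) < ear)
  lo <- log(start) - 6
  hi <- log(start) + 6
  if (prev_at(lo) < target) lo <- log(1e-3)
  if (prev_at(hi) > target) hi <- log(1e6)
  best <- log(start); best_err <- abs(prev_at(best) - target)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    p <- prev_at(mid)
    if (abs(p - target) < best_err) {
      best <- mid; best_err <- abs(p - target)
    }
    if (best_err <= tol / 2) break
    if (p > target) lo <- mid else hi <- mid
  }
  achieved <- prev_at(best)
  if (abs(achieved - target) > tol) {
    stop(sprintf(
      "intake-median calibration did not converge: achieved prevalence %.4f, target %.4f (tolerance %.3f)",
      achieved, target, tol), call. = FALSE)
  }
  exp(best)
}

#' Generate surveys for all macroregions
#'
#' @param profiles named list of profiles (default calibrated set).
#' @param n_children children per region (recycled).
#' @param seed base seed; region r uses `seed + 1000 * index(r)`.
#' @param ... passed to [generate_survey()].
#' @return named list of survey tibbles.
#' @export
generate_surveys <- function(profiles = default_region_profiles(),
                             n_children = 4000, seed = 1L, ...) {
  n_children <- rep_len(n_children, length(profiles))
  out <- Map(function(p, n, i) generate_survey(p, n, seed = seed + 1000L * i, ...),
             profiles, n_children, seq_along(profiles))
  names(out) <- names(profiles)
  out
}

#' Write / read a survey as CSV
#'
#' Plain-CSV persistence for survey datasets; the column dictionary is the
#' [generate_survey()] return schema. The generator-known usual intakes are
#' not written (they are unobservable in a real survey).
#'
#' @param survey survey tibble.
#' @param path CSV path.
#' @return `read_survey_csv()` returns a tibble.
#' @export
write_survey_csv <- function(survey, path) {
  utils::write.csv(survey, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$vas_received <- as.logical(df$vas_received)
  tibble::as_tibble(df)
}
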