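# Printed calibration anchors for the three Cameroon macroregions.
#
# These constants summarise the published national planning tables the
# package is calibrated against: ten-year child-years by macroregion,
# baseline prevalence of inadequate vitamin A intake, per-program reach
# (which fixes the vehicle consumer fractions) and effective coverage in
# child-years, supplementation reach from the dietary survey, and the
# prevalence floors reached once the fortification programs mature.
#
# Cities notes: the baseline prevalence is not printed for the Cities
# macroregion; 0.42 is derived from the business-as-usual coverage total for
# Cities (2417k CY over 5800k CY -- coverage cannot exceed baseline
# prevalence) and is consistent with the printed "roughly half" national
# figure under the regional child-year weights. Flagged as derived, not
# printed.

REGIONS <- c("NORTH", "SOUTH", "CITIES")

# ten-year child-years ('000s) and annual growth implied by the printed
# year-by-year coverage rows (constant coverage fraction => ~1.4%/year)
REGION_CY_10YR <- c(NORTH = 12700, SOUTH = 13900, CITIES = 5800)
POP_GROWTH_RATE <- 0.014

#' Region calibration anchors
#'
#' Returns the per-region anchor sets used to calibrate the synthetic-survey
#' generator: baseline prevalence, vehicle consumer fractions (reach /
#' child-years), per-program effective-coverage fractions, supplementation
#' reach, and mature-fortification prevalence floors. All fractions are of
#' ten-year child-years unless noted.
#'
#' @return named list of anchor lists, one per macroregion.
#' @export
region_anchors <- function() {
  cy <- REGION_CY_10YR
  g <- POP_GROWTH_RATE
  # share of child-years falling in years 4-10, when bouillon and maize
  # benefits are active
  yr <- (1 + g)^(0:9)
  active_share <- sum(yr[4:10]) / sum(yr)

  mk <- function(region, p0, floor_prev, reach_oil, reach_bou, reach_mai,
                 reach_vas, ec_oil44, ec_oilenh, ec_bou, ec_mai, ec_vas,
                 vas_weight, sigma_b_start,
                 bouillon_weight = 2, oil44_weight = 10, oil_z_slope_start = 0.3,
                 oil_mature_diff = 0.05) {
    list(
      region = region,
      baseline_inadequate_prev = p0,
      floor_prev = floor_prev,
      oil_consumer_frac = reach_oil / cy[region],
      bouillon_consumer_frac = reach_bou / cy[region],
      maize_consumer_frac = reach_mai / cy[region],
      vas_reach = reach_vas / cy[region],
      oil44_frac = ec_oil44 / cy[region],
      oilenh_frac = ec_oilenh / cy[region],
      bouillon_frac = ec_bou / (cy[region] * active_share),
      maize_frac = ec_mai / (cy[region] * active_share),
      vas_frac = ec_vas / cy[region],
      vas_weight = vas_weight,
      bouillon_weight = bouillon_weight,
      oil44_weight = oil44_weight,
      maize_weight = 2,
      oil_cv = 0.3, bouillon_cv = 0.5, maize_cv = 0.6,
      oil_mature_diff = oil_mature_diff,
      pop_growth_rate = g,
      cy_10yr = unname(cy[region]),
      base_child_population = unname(cy[region] / sum(yr)),
      sigma_b_start = sigma_b_start,
      oil_z_slope_start = oil_z_slope_start,
      oil_start = 12, bouillon_start = 1.8, maize_start = 95
    )
  }

  list(
    NORTH = mk("NORTH", 0.73, 0.167,
               reach_oil = 7135, reach_bou = 10958, reach_mai = 5734,
               reach_vas = 11340,
               ec_oil44 = 1459, ec_oilenh = 2669, ec_bou = 3300,
               ec_mai = 1512, ec_vas = 5201,
               vas_weight = 30, sigma_b_start = 1.03,
               bouillon_weight = 3, oil44_weight = 2, oil_z_slope_start = 0.48,
               oil_mature_diff = 0.105),
    SOUTH = mk("SOUTH", 0.35, 0.008,
               reach_oil = 5435, reach_bou = 12820, reach_mai = 5713,
               reach_vas = 8918,
               ec_oil44 = 1960, ec_oilenh = 3141, ec_bou = 2940,
               ec_mai = 808, ec_vas = 2131,
               vas_weight = 0.5, sigma_b_start = 0.85, oil_z_slope_start = 0.55,
               oil_mature_diff = 0.025),
    CITIES = mk("CITIES", 0.42, 0.009,
                reach_oil = 4618, reach_bou = 5261, reach_mai = 1988,
                reach_vas = 3391,
                ec_oil44 = 1657, ec_oilenh = 2246, ec_bou = 1491,
                ec_mai = 192, ec_vas = 1253,
                vas_weight = 1, sigma_b_start = 1.0, oil_z_slope_start = 0.45,
                oil_mature_diff = 0.030)
  )
}
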