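# Portfolio optimization: minimum-cost program activations subject to a
# national effective-coverage floor over the horizon.
#
# The discrete decision space follows the program structure: each national
# fortification program is characterised by a start year (or never) and runs
# uninterrupted to the horizon (start-up capital is sunk); the two oil
# programs are mutually exclusive; supplementation is a free 0/1 choice per
# region-year. For any fortification plan the coverage of every region-year
# is a table lookup into the dietary model's state coverage (combinations
# are computed by the dietary model, not assumed additive), so the search
# decomposes into (i) a vectorised sweep over all fortification plans in
# ascending cost order and (ii) an exact branch-and-bound covering knapsack
# over the supplementation items for the residual coverage gap. Both parts
# are exact; the incumbent is provably optimal at termination.

OIL_LEVELS <- c(0, 0.44, 0.72, 1)

state_index <- function(oil_idx, bouillon, maize, vas) {
  1L + oil_idx + 4L * bouillon + 8L * maize + 16L * vas
}

#' Build an optimization problem
#'
#' Assembles the coverage lookup tables, candidate fortification plans,
#' supplementation items and cost streams into a solvable problem object.
#'
#' @param coverage a state coverage table ([population_coverage_table()] by
#'   default, or [coverage_state_table()] for the survey-estimated route).
#' @param cost_model a [default_cost_model()].
#' @param profiles region profiles (population trajectories).
#' @param config configuration list.
#' @param floor national coverage floor over the horizon ('000s child-years).
#'   Default: the business-as-usual coverage computed from the same tables,
#'   so the BAU bundle is always feasible.
#' @param horizon years.
#' @param regions regions included (reduced instances for testing).
#' @param programs program kinds available to the optimizer.
#' @return an `"optimization_problem"` object.
#' @export
build_problem <- function(coverage, cost_model = default_cost_model(),
                          profiles = default_region_profiles(),
                          config = default_config(),
                          floor = NULL,
                          horizon = config$horizon_years,
                          regions = REGIONS,
                          programs = PROGRAM_KINDS) {
  regions <- match.arg(regions, REGIONS, several.ok = TRUE)
  programs <- match.arg(programs, PROGRAM_KINDS, several.ok = TRUE)
  R <- length(regions); H <- as.integer(horizon)

  # coverage lookup: ec[state, region]
  ec <- matrix(NA_real_, 32, R, dimnames = list(NULL, regions))
  for (ri in seq_len(R)) {
    sub <- coverage[coverage$region == regions[ri], ]
    oil_idx <- match(sub$oil_level, OIL_LEVELS) - 1L
    if (anyNA(oil_idx)) stop("coverage table has oil levels outside ",
                             paste(OIL_LEVELS, collapse = "/"), call. = FALSE)
    ec[state_index(oil_idx, sub$bouillon, sub$maize, sub$vas), ri] <- sub$ec_frac
  }
  if (anyNA(ec)) {
    miss <- which(is.na(ec), arr.ind = TRUE)
    stop("coverage table is missing ", nrow(miss), " program combination(s); ",
         "first missing state index ", miss[1, 1], " in region ",
         regions[miss[1, 2]], call. = FALSE)
  }

  pop <- population_matrix(profiles[regions], H)      # H x R
  pop_vec <- as.vector(pop)                           # cell = (year, region)
  cell_region <- rep(seq_len(R), each = H)
  cell_year <- rep(seq_len(H), R)

  # candidate fortification plans ------------------------------------------
  oil_opts <- data.frame(kind = 0L, start = 0L)
  if ("OIL_44" %in% programs) {
    oil_opts <- rbind(oil_opts, data.frame(kind = 1L, start = seq_len(H)))
  }
  if ("OIL_ENHANCED" %in% programs) {
    oil_opts <- rbind(oil_opts, data.frame(kind = 2L, start = seq_len(H)))
  }
  bou_starts <- if ("BOUILLON" %in% programs) 0:H else 0L
  mai_starts <- if ("MAIZE_BIOFORT" %in% programs) 0:H else 0L
  plans <- expand.grid(oil_opt = seq_len(nrow(oil_opts)),
                       bou_start = bou_starts, mai_start = mai_starts)
  np <- nrow(plans)

  # per plan-cell state indices, without and with supplementation
  oil_kind <- oil_opts$kind[plans$oil_opt]
  oil_start <- oil_opts$start[plans$oil_opt]
  ramp_len <- length(config$programs$oil_enhanced_ramp)
  bou_su <- config$programs$bouillon_startup_years
  mai_su <- config$programs$maize_startup_years

  idx_fort <- matrix(0L, np, H * R)
  for (cell in seq_len(H * R)) {
    y <- cell_year[cell]
    op_oil <- y - oil_start + 1L
    oil_idx <- integer(np)
    on44 <- oil_kind == 1L & op_oil >= 1L
    oil_idx[on44] <- 1L
    onenh <- oil_kind == 2L & op_oil >= 1L
    oil_idx[onenh] <- pmin(op_oil[onenh], ramp_len) + 0L  # 1->0.44, 2->0.72, 3->1.0
    bou_on <- as.integer(plans$bou_start > 0 & y >= plans$bou_start + bou_su)
    mai_on <- as.integer(plans$mai_start > 0 & y >= plans$mai_start + mai_su)
    idx_fort[, cell] <- state_index(oil_idx, bou_on, mai_on, 0L)
  }
  idx_vas <- idx_fort + 16L

  # flat coverage lookup offsets per cell's region
  region_offset <- (cell_region - 1L) * 32L

  # cost decomposition ------------------------------------------------------
  prog_horizon_cost <- function(kind, start) {
    if (start == 0L) return(0)
    sum(vapply(start:H, function(y) {
      cc <- cost_model$costs[[kind]]
      op <- y - start + 1L
      (if (op <= cc$startup_years) cc$startup_annual else cc$operating_annual) +
        cc$me_annual
    }, numeric(1)))
  }
  # national streams are charged only for the share of included regions
  region_share_sum <- function(kind) {
    sum(unlist(cost_model$costs[[kind]]$region_share[regions]))
  }
  oil_cost <- vapply(seq_len(nrow(oil_opts)), function(i) {
    if (oil_opts$kind[i] == 0L) 0
    else if (oil_opts$kind[i] == 1L) {
      prog_horizon_cost("OIL_44", oil_opts$start[i]) * region_share_sum("OIL_44")
    } else {
      prog_horizon_cost("OIL_ENHANCED", oil_opts$start[i]) * region_share_sum("OIL_ENHANCED")
    }
  }, numeric(1))
  bou_cost <- vapply(bou_starts, function(s)
    prog_horizon_cost("BOUILLON", s) * region_share_sum("BOUILLON"), numeric(1))
  names(bou_cost) <- bou_starts
  mai_cost <- vapply(mai_starts, function(s)
    prog_horizon_cost("MAIZE_BIOFORT", s) * region_share_sum("MAIZE_BIOFORT"), numeric(1))
  names(mai_cost) <- mai_starts

  vas_allowed <- "VAS" %in% programs
  vas_item_cost <- vapply(seq_len(H * R), function(cell) {
    cc <- cost_model$costs$VAS
    r <- regions[cell_region[cell]]
    cc$fixed_annual[[r]] + cc$variable_per_child[[r]] * pop_vec[cell]
  }, numeric(1))

  # per-stream share of each state's coverage, for stream-wise perturbation:
  # a state's coverage is allocated to its member programs proportionally to
  # their solo coverage at the state's dose level
  share <- array(0, c(32, R, 4), dimnames = list(NULL, regions,
                                                 c("oil", "bouillon", "maize", "vas")))
  for (ri in seq_len(R)) {
    solo_oil <- unname(ec[state_index(0:3, 0L, 0L, 0L), ri])  # by oil level
    solo <- c(bouillon = unname(ec[state_index(0L, 1L, 0L, 0L), ri]),
              maize = unname(ec[state_index(0L, 0L, 1L, 0L), ri]),
              vas = unname(ec[state_index(0L, 0L, 0L, 1L), ri]))
    for (o in 0:3) for (b in 0:1) for (m in 0:1) for (v in 0:1) {
      s <- state_index(o, b, m, v)
      parts <- c(oil = if (o > 0) solo_oil[o + 1] else 0,
                 bouillon = if (b > 0) solo[["bouillon"]] else 0,
                 maize = if (m > 0) solo[["maize"]] else 0,
                 vas = if (v > 0) solo[["vas"]] else 0)
      tot <- sum(parts)
      if (tot > 0) share[s, ri, ] <- parts / tot
    }
  }

  # BAU reference (always a feasible candidate when its programs exist)
  bau_state <- state_index(1L, 0L, 0L, 1L)
  bau_cov <- sum(ec[bau_state, cell_region] * pop_vec)
  bau_cost <- prog_horizon_cost("OIL_44", 1L) * region_share_sum("OIL_44") +
    sum(vas_item_cost)
  if (is.null(floor)) floor <- bau_cov

  structure(list(
    regions = regions, horizon = H, programs = programs,
    ec = ec, share = share, pop_vec = pop_vec,
    cell_region = cell_region, cell_year = cell_year,
    region_offset = region_offset,
    plans = plans, oil_opts = oil_opts, oil_kind = oil_kind,
    oil_start = oil_start,
    idx_fort = idx_fort, idx_vas = idx_vas,
    oil_cost = oil_cost, bou_cost = bou_cost, mai_cost = mai_cost,
    vas_item_cost = vas_item_cost, vas_allowed = vas_allowed,
    floor = floor, bau = list(coverage = bau_cov, cost = bau_cost)
  ), class = "optimization_problem")
}

# exact min-cost covering knapsack over supplementation items --------------
# minimise sum(cost[chosen]) s.t. sum(delta[chosen]) >= need, cost < budget.
knapsack_cover <- function(need, delta, cost, budget) {
  keep <- delta > 1e-9
  if (!any(keep)) return(NULL)
  idx <- which(keep)
  o <- order(cost[idx] / delta[idx], idx)
  d <- delta[idx][o]; cst <- cost[idx][o]; ids <- idx[o]
  n <- length(d)
  suffix_delta <- rev(cumsum(rev(d)))
  best <- list(cost = budget, sel = NULL)

  lower_bound <- function(i, need) {
    # fractional greedy completion from item i
    lb <- 0
    while (i <= n && need > 1e-9) {
      take <- min(1, need / d[i])
      lb <- lb + take * cst[i]
      need <- need - take * d[i]
      i <- i + 1L
    }
    if (need > 1e-9) Inf else lb
  }

  rec <- function(i, need, acc, sel) {
    if (need <= 1e-9) {
      if (acc < best$cost - 1e-9) best <<- list(cost = acc, sel = sel)
      return(invisible())
    }
    if (i > n || suffix_delta[i] < need - 1e-9) return(invisible())
    if (acc + lower_bound(i, need) >= best$cost - 1e-9) return(invisible())
    rec(i + 1L, need - d[i], acc + cst[i], c(sel, ids[i]))  # take
    rec(i + 1L, need, acc, sel)                             # skip
  }
  rec(1L, need, 0, integer(0))
  if (is.null(best$sel) && need > 1e-9) return(NULL)
  best
}

#' Solve an optimization problem
#'
#' Exact search over the discrete decision space: ascending-cost sweep over
#' fortification plans with an exact covering knapsack for supplementation,
#' pruned by the incumbent (zero optimality gap). Deterministic; among
#' equal-cost optima the plan earliest in the canonical enumeration order
#' (and the earliest supplementation years) is returned.
#'
#' @param problem an [build_problem()] object.
#' @param ec_multipliers optional `4 x R` matrix (rows oil, bouillon, maize,
#'   vas) of coverage-stream multipliers (Monte Carlo perturbation).
#' @param cost_multipliers optional named vector of per-program cost
#'   multipliers (`OIL_44`, `OIL_ENHANCED`, `BOUILLON`, `MAIZE_BIOFORT`,
#'   `VAS`).
#' @param floor override the problem's coverage floor.
#' @return an `"optimization_result"`: `status` (`"optimal"` or
#'   `"infeasible"`), `activations` tibble, `total_cost`, `total_coverage`,
#'   `slack`, `max_attainable`.
#' @export
solve_problem <- function(problem, ec_multipliers = NULL,
                          cost_multipliers = NULL, floor = NULL) {
  stopifnot(inherits(problem, "optimization_problem"))
  p <- problem
  if (is.null(floor)) floor <- p$floor
  R <- length(p$regions); H <- p$horizon

  ec <- p$ec
  if (!is.null(ec_multipliers)) {
    stopifnot(nrow(ec_multipliers) == 4, ncol(ec_multipliers) == R)
    mult <- matrix(1, 32, R)
    for (ri in seq_len(R)) {
      mult[, ri] <- p$share[, ri, 1] * ec_multipliers[1, ri] +
        p$share[, ri, 2] * ec_multipliers[2, ri] +
        p$share[, ri, 3] * ec_multipliers[3, ri] +
        p$share[, ri, 4] * ec_multipliers[4, ri] +
        (rowSums(p$share[, ri, ]) == 0)   # baseline state: no members
    }
    ec <- pmax(0, ec * mult)
  }
  cm <- function(kind) {
    if (is.null(cost_multipliers) || is.na(cost_multipliers[kind])) 1
    else unname(cost_multipliers[kind])
  }

  ec_flat <- as.vector(ec)                      # (state, region) flattened
  offs <- matrix(rep(p$region_offset, each = nrow(p$plans)),
                 nrow(p$plans), H * R)
  EF <- matrix(ec_flat[p$idx_fort + offs], nrow(p$plans), H * R)
  EV <- matrix(ec_flat[p$idx_vas + offs], nrow(p$plans), H * R)
  fort_cov <- as.vector(EF %*% p$pop_vec)
  DV <- sweep(EV - EF, 2, p$pop_vec, `*`)       # supplementation marginals

  oil_cost_kind <- ifelse(p$oil_opts$kind == 1L, cm("OIL_44"),
                          ifelse(p$oil_opts$kind == 2L, cm("OIL_ENHANCED"), 1))
  plan_cost <- unname(p$oil_cost[p$plans$oil_opt] * oil_cost_kind[p$plans$oil_opt] +
    p$bou_cost[as.character(p$plans$bou_start)] * cm("BOUILLON") +
    p$mai_cost[as.character(p$plans$mai_start)] * cm("MAIZE_BIOFORT"))
  vas_cost <- if (p$vas_allowed) p$vas_item_cost * cm("VAS") else
    rep(Inf, H * R)

  max_attainable <- max(fort_cov + if (p$vas_allowed) rowSums(DV) else 0)

  ord <- order(plan_cost, seq_along(plan_cost))
  best_cost <- Inf; best_plan <- NA_integer_; best_vas <- integer(0)
  for (pi in ord) {
    if (plan_cost[pi] >= best_cost - 1e-9) break
    gap <- floor - fort_cov[pi]
    if (gap <= 1e-9) {
      best_cost <- plan_cost[pi]; best_plan <- pi; best_vas <- integer(0)
      next
    }
    if (!p$vas_allowed) next
    dv <- DV[pi, ]
    if (gap > sum(dv) + 1e-9) next
    sol <- knapsack_cover(gap, dv, vas_cost, budget = best_cost - plan_cost[pi])
    if (!is.null(sol) && !is.null(sol$sel)) {
      total <- plan_cost[pi] + sol$cost
      if (total < best_cost - 1e-9) {
        best_cost <- total; best_plan <- pi; best_vas <- sort(sol$sel)
      }
    }
  }

  if (!is.finite(best_cost)) {
    return(structure(list(status = "infeasible", floor = floor,
                          max_attainable = max_attainable,
                          activations = tibble::tibble(),
                          total_cost = NA_real_, total_coverage = NA_real_,
                          slack = NA_real_), class = "optimization_result"))
  }

  acts <- list()
  ok <- p$oil_kind[best_plan]
  if (ok > 0) {
    kind <- if (ok == 1L) "OIL_44" else "OIL_ENHANCED"
    acts[[length(acts) + 1L]] <- spec_from_years(
      kind, seq(p$oil_start[best_plan], H), p$regions)
  }
  if (p$plans$bou_start[best_plan] > 0) {
    acts[[length(acts) + 1L]] <- spec_from_years(
      "BOUILLON", seq(p$plans$bou_start[best_plan], H), p$regions)
  }
  if (p$plans$mai_start[best_plan] > 0) {
    acts[[length(acts) + 1L]] <- spec_from_years(
      "MAIZE_BIOFORT", seq(p$plans$mai_start[best_plan], H), p$regions)
  }
  if (length(best_vas)) {
    acts[[length(acts) + 1L]] <- data.frame(
      program = "VAS",
      region = p$regions[p$cell_region[best_vas]],
      year = p$cell_year[best_vas])
  }
  activations <- if (length(acts)) tibble::as_tibble(do.call(rbind, acts))
                 else tibble::tibble(program = character(), region = character(),
                                     year = integer())
  total_cov <- fort_cov[best_plan] + sum(DV[best_plan, best_vas])
  structure(list(
    status = "optimal",
    activations = activations,
    total_cost = best_cost,
    total_coverage = total_cov,
    floor = floor,
    slack = total_cov - floor,
    max_attainable = max_attainable,
    plan = list(oil_kind = ok, oil_start = p$oil_start[best_plan],
                bou_start = p$plans$bou_start[best_plan],
                mai_start = p$plans$mai_start[best_plan],
                vas_cells = best_vas)
  ), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  if (x$status != "optimal") {
    cat("<optimization_result> INFEASIBLE; max attainable coverage",
        sprintf("%.0f", x$max_attainable), "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<optimization_result> cost %.0f ('000s USD), coverage %.0f ('000s CY, floor %.0f)\n",
    x$total_cost, x$total_coverage, x$floor))
  if (nrow(x$activations)) {
    s <- dplyr::summarise(dplyr::group_by(x$activations, .data$program),
                          years = paste(sort(unique(.data$year)), collapse = ","),
                          regions = paste(sort(unique(.data$region)), collapse = ","),
                          .groups = "drop")
    print(as.data.frame(s))
  }
  invisible(x)
}
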