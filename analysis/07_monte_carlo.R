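#!/usr/bin/env Rscript
# Robustness of the optimal program sequence to benefit and cost uncertainty:
# 1000 re-solves with per-stream coverage noise (5% CV, truncated normal)
# and +/-20% uniform cost noise per program family.
#
# Expect: enhanced oil and bouillon in essentially all replicates,
# supplementation in the South in none, maize in a small minority.
# Outputs: results/monte_carlo.json, results/monte_carlo_inclusion.csv

library(vaplan)

cfg <- default_config()
prob <- build_problem(population_coverage_table(cfg),
                      floor = cfg$optimizer$coverage_floor)
mc <- run_monte_carlo(prob,
                      ec_cv = cfg$monte_carlo$ec_cv,
                      cost_band = cfg$monte_carlo$cost_band,
                      n_sims = cfg$monte_carlo$n_sims,
                      seed = 20L,
                      vas_min_years = cfg$monte_carlo$vas_min_years)
print(mc)
write_monte_carlo(mc, "results/monte_carlo.json",
                  "results/monte_carlo_inclusion.csv")
cat("wrote results/monte_carlo.json and results/monte_carlo_inclusion.csv\n")
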