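#!/usr/bin/env Rscript
# Stage 5: resampling uncertainty — percentile-bootstrap intervals for each
# arm's variable cost and permutation tests of cost differences vs the
# apprenticeship arm.
suppressPackageStartupMessages(library(pbpcost))

if (!file.exists("results/cohorts.csv")) {
  stop("run analysis/01_simulate_cohorts.R first")
}
cohorts <- read_records("results/cohorts.csv")
rates <- cost_rates()
seed <- 20260921

cat("95% percentile-bootstrap intervals, per-trainee variable cost (EUR):\n")
ci_rows <- do.call(rbind, lapply(pbp_groups(), function(g) {
  ci <- bootstrap_ci(trainee_cost(cohorts[cohorts$group == g, ], rates),
                     n_boot = 10000, seed = seed)
  cat(sprintf("  %-18s ", g)); print(ci)
  data.frame(group = g, point = ci$point, lo = ci$lo, hi = ci$hi,
             n_boot = ci$n_boot, seed = ci$seed)
}))
utils::write.csv(ci_rows, "results/bootstrap_intervals.csv", row.names = FALSE)

cat("\nPermutation tests of mean cost difference vs apprenticeship:\n")
perm_rows <- do.call(rbind, lapply(setdiff(pbp_groups(), "G4_apprenticeship"),
  function(g) {
    pt <- permutation_test(
      trainee_cost(cohorts[cohorts$group == g, ], rates),
      trainee_cost(cohorts[cohorts$group == "G4_apprenticeship", ], rates),
      n_perm = 9999, seed = seed)
    cat(sprintf("  %-18s ", g)); print(pt)
    data.frame(group_a = g, group_b = "G4_apprenticeship",
               mean_difference = pt$statistic, p_value = pt$p_value,
               n_perm = pt$n_perm)
  }))
utils::write.csv(perm_rows, "results/permutation_tests.csv", row.names = FALSE)
cat("\nTables -> results/bootstrap_intervals.csv, results/permutation_tests.csv\n")
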