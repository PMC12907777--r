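# Deterministic 47-trainee fixture matching the trial's published group
# statistics: per-group n 12/12/11/12, mean trials 71/12, 81/12, 12, 15,
# mean days 1.17, 1.29, 1.5, 2.67 (approx. on the half-day grid), and 7 of 12
# apprenticeship trainees proficient. Built in code; hours follow the
# 0.5 h-per-trial slot and nights the max(1, round_half_up(days)) policy.
osset_fixture_records <- function() {
  mk <- function(group, trials, days, proficient) {
    data.frame(
      trainee_id = sprintf("%s_%02d", group, seq_along(trials)),
      group = group,
      trials = trials,
      hands_on_hours = trials / 2,
      billed_days = days,
      nights = pmax(1, round_half_up(days)),
      proficient = proficient,
      stringsAsFactors = FALSE
    )
  }
  g1 <- mk("G1_full_pbp",
           c(3, 4, 4, 5, 5, 5, 6, 6, 7, 7, 9, 10),        # sum 71
           c(rep(1, 8), rep(1.5, 4)),                      # mean 7/6 ~ 1.17
           rep(TRUE, 12))
  g2 <- mk("G2_elearning",
           c(4, 5, 5, 6, 6, 6, 7, 7, 7, 8, 9, 11),        # sum 81
           c(rep(1, 7), rep(1.5, 3), 2, 2),                # mean 1.2917
           rep(TRUE, 12))
  g3 <- mk("G3_traditional",
           c(8, 9, 10, 11, 11, 12, 12, 13, 13, 16, 17),   # sum 132, n = 11
           c(1, 1, 1, rep(1.5, 5), 2, 2, 2),               # mean 1.5
           rep(TRUE, 11))
  g4 <- mk("G4_apprenticeship",
           c(2, 3, 4, 4, 5, 5, 7, rep(30, 5)),            # sum 180
           c(1.5, 2, 2, 2, 2, 2.5, 2.5, rep(3.5, 5)),      # mean 8/3 ~ 2.67
           c(rep(TRUE, 7), rep(FALSE, 5)))
  trainee_records(rbind(g1, g2, g3, g4))
}

# Brute-force group summary recomputed with naive loops, independent of
# summarize_group's implementation.
brute_force_summary <- function(records, group) {
  df <- as.data.frame(records)
  keep <- df$group == group
  trials <- df$trials[keep]; hours <- df$hands_on_hours[keep]
  days <- df$billed_days[keep]; nights <- df$nights[keep]
  prof <- df$proficient[keep]
  list(
    n = sum(keep),
    prop_proficient = sum(prof) / sum(keep),
    mean_trials = sum(trials) / length(trials),
    mean_hours = sum(hours) / length(hours),
    mean_days = sum(days) / length(days),
    median_days = stats::median(days),
    mean_nights = sum(nights) / length(nights)
  )
}

# Exact censored-geometric mean by direct pmf summation (independent oracle
# for the closed form).
pmf_mean_oracle <- function(p, cap) {
  k <- seq_len(cap)
  pmf <- (1 - p)^(k - 1) * p
  pmf[cap] <- (1 - p)^(cap - 1)
  sum(k * pmf)
}

# Exhaustive two-sample permutation p-value (two-sided, mean difference) over
# all assignment vectors, independent of permutation_test.
enumeration_p_value <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  tol <- 1e-9 * (max(abs(pooled)) + 1)
  hits <- 0; total <- 0
  idx_sets <- utils::combn(length(pooled), na)
  for (j in seq_len(ncol(idx_sets))) {
    ia <- idx_sets[, j]
    d <- abs(mean(pooled[ia]) - mean(pooled[-ia]))
    hits <- hits + (d >= obs - tol)
    total <- total + 1
  }
  hits / total
}
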