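test_that("generation is deterministic given (params, n, seed)", {
  p <- osset_params()[["G1_full_pbp"]]
  a <- generate_cohort(p, 12, seed = 5)
  b <- generate_cohort(p, 12, seed = 5)
  expect_identical(a, b)
  c <- generate_cohort(p, 12, seed = 6)
  expect_false(identical(a$trials, c$trials))
  expect_error(generate_cohort(p, 12, seed = "x"), "seed")
  expect_error(generate_cohort(p, 12, seed = c(1, 2)), "seed")
})

test_that("calibration solves the censored-geometric mean (pmf-summation oracle)", {
  # degenerate: one trial, all proficient -> certain success
  p1 <- calibrate_params(list(group = "G1_full_pbp", mean_trials = 1,
                              mean_days = 1, prop_proficient = 1))
  expect_equal(p1$p_success_per_trial, 1)

  p <- calibrate_params(list(group = "G1_full_pbp", mean_trials = 5.92,
                             mean_days = 1.17, prop_proficient = 1),
                        max_trials = 30)
  expect_equal(pmf_mean_oracle(p$p_success_per_trial, 30), 5.92, tolerance = 1e-9)
  expect_equal(censored_geometric_mean(p$p_success_per_trial, 30), 5.92,
               tolerance = 1e-9)

  # whole-group mean with non-proficient trainees parked at the cap
  p4 <- calibrate_params(list(group = "G4_apprenticeship", mean_trials = 15,
                              mean_days = 2.67, prop_proficient = 7 / 12),
                         max_trials = 30)
  implied <- 7 / 12 * pmf_mean_oracle(p4$p_success_per_trial, 30) + 5 / 12 * 30
  expect_equal(implied, 15, tolerance = 1e-9)

  expect_error(calibrate_params(list(group = "G1_full_pbp", mean_trials = 35,
                                     mean_days = 1, prop_proficient = 1),
                                max_trials = 30),
               "exceeds the trial cap")
})

test_that("calibrated days weights reproduce the target group mean", {
  tg <- osset_group_targets()
  params <- osset_params()
  for (g in pbp_groups()) {
    pr <- params[[g]]
    w <- pr$days_distribution
    expect_equal(sum(w), 1)
    weights_mean <- sum(as.numeric(names(w)) * w)
    rate <- pr$proficiency_rate
    implied_group_mean <- rate * weights_mean + (1 - rate) * 3.5
    expect_equal(implied_group_mean, tg$mean_days[tg$group == g],
                 tolerance = 0.01)
  }
})

test_that("large-cohort empirical means recover published group statistics", {
  params <- osset_params()
  g1 <- generate_cohort(params[["G1_full_pbp"]], 10000, seed = 401)
  expect_equal(mean(g1$trials), 5.92, tolerance = 0.02)
  expect_equal(mean(g1$hands_on_hours), 2.96, tolerance = 0.02)
  g4 <- generate_cohort(params[["G4_apprenticeship"]], 10000, seed = 402)
  expect_lt(abs(mean(g4$proficient) - 0.58), 0.02)
})

test_that("parameter recovery: calibrate -> generate -> summarize round-trips", {
  targets <- osset_group_targets()
  params <- osset_params()
  for (g in pbp_groups()) {
    cohort <- generate_cohort(params[[g]], 10000, seed = 500 + match(g, pbp_groups()))
    s <- summarize_group(cohort, g)
    tg <- targets[targets$group == g, ]
    expect_equal(s$mean_trials, tg$mean_trials, tolerance = 0.02)
    expect_equal(s$mean_days, tg$mean_days, tolerance = 0.02)
    expect_equal(s$prop_proficient, tg$prop_proficient, tolerance = 0.02)
    # hours follow the 0.5 h/trial slot exactly
    expect_equal(s$mean_hours, 0.5 * s$mean_trials)
  }
})

test_that("generated records satisfy the record invariants", {
  params <- osset_params()
  for (g in pbp_groups()) {
    for (seed in 1:3) {
      cohort <- generate_cohort(params[[g]], 200, seed = seed)
      expect_s3_class(cohort, "trainee_records")  # constructor enforces invariants
      expect_true(all(cohort$billed_days * 2 == round(cohort$billed_days * 2)))
      expect_true(all(cohort$billed_days <= 3.5))
      expect_true(all(!cohort$proficient | cohort$trials <= 30))
    }
  }
})

test_that("lower per-trial success probability gives stochastically more trials", {
  base <- osset_params()[["G1_full_pbp"]]
  ps <- c(0.4, 0.2, 0.1, 0.05)
  means <- vapply(ps, function(p) {
    pars <- group_params("G1_full_pbp", p, max_trials = 30,
                         days_distribution = base$days_distribution)
    mean(generate_cohort(pars, 5000, seed = 77)$trials)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("infeasible calibration targets raise errors", {
  expect_error(calibrate_params(list(group = "G4_apprenticeship",
                                     mean_trials = 10, mean_days = 2.67,
                                     prop_proficient = 7 / 12),
                                max_trials = 30),
               "unreachable")
  expect_error(calibrate_params(list(group = "G4_apprenticeship",
                                     mean_trials = 15, mean_days = 1.0,
                                     prop_proficient = 7 / 12),
                                max_trials = 30),
               "infeasible")
  expect_error(group_params("G1_full_pbp", 0.5,
                            days_distribution = c(`1` = 0.7, `1.5` = 0.7)),
               "sum to 1")
  expect_error(group_params("G1_full_pbp", 1.2,
                            days_distribution = c(`1` = 1)),
               "p_success_per_trial")
})

test_that("generator params serialize to YAML with the cohort CSV schema intact", {
  params <- osset_params()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params_yaml(params, path)
  back <- yaml::read_yaml(path)
  expect_length(back, 4)
  expect_equal(back[[1]]$group, "G1_full_pbp")
  expect_equal(back[[1]]$p_success_per_trial,
               params[["G1_full_pbp"]]$p_success_per_trial)
  # generator output is readable by the records reader
  csv <- withr::local_tempfile(fileext = ".csv")
  write_records(generate_cohort(params[["G2_elearning"]], 12, seed = 3), csv)
  expect_equal(nrow(read_records(csv)), 12)
})
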