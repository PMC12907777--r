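#' Censored geometric mean number of trials
#'
#' Mean of `min(G, cap)` where `G` is geometric on \{1, 2, ...\} with
#' per-trial success probability `p`: the expected number of training trials
#' a trainee occupies when training stops either at first success or at the
#' trial cap. Equals `(1 - (1 - p)^cap) / p`, or `sum((1 - p)^(0:(cap - 1)))`.
#'
#' @param p Per-trial success probability in (0, 1].
#' @param cap Maximum number of trials (positive integer, may be `Inf`).
#' @return Expected number of trials, a value in \[1, cap\].
#' @export
censored_geometric_mean <- function(p, cap) {
  stopifnot(length(p) == 1, length(cap) == 1)
  if (!is.numeric(p) || p <= 0 || p > 1) stop("p must be in (0, 1]")
  if (p == 1) return(1)
  if (is.infinite(cap)) return(1 / p)
  stopifnot(cap >= 1, cap == round(cap))
  (1 - (1 - p)^cap) / p
}

#' Probability mass function of the censored geometric trials distribution
#'
#' @param p Per-trial success probability.
#' @param cap Trial cap (finite positive integer).
#' @return Numeric vector of length `cap`; element `k` is `P(T = k)`. The mass
#'   at `cap` pools all chains not absorbed earlier.
#' @export
censored_geometric_pmf <- function(p, cap) {
  stopifnot(is.finite(cap), cap >= 1, cap == round(cap), p > 0, p <= 1)
  k <- seq_len(cap)
  pmf <- (1 - p)^(k - 1) * p
  pmf[cap] <- (1 - p)^(cap - 1)
  pmf
}

#' Group generator parameters
#'
#' The tunable knobs of the synthetic-cohort generator for one curriculum:
#' a per-trial success probability driving a censored-geometric distribution
#' of trials to proficiency, the trial cap implied by the 3.5-day training
#' limit, the per-trial console slot (30 min), a probability distribution of
#' billed laboratory days on the half-day grid, the target fraction of
#' trainees reaching the benchmark, and the rule mapping billed days to hotel
#' nights.
#'
#' When `proficiency_rate < 1`, the days distribution applies to trainees who
#' reach the benchmark; non-proficient trainees are assigned the 3.5-day
#' maximum (they use the full laboratory allocation).
#'
#' @param group One of [pbp_groups()].
#' @param p_success_per_trial Probability in (0, 1].
#' @param max_trials Trial cap (default 30).
#' @param minutes_per_trial Console minutes per trial (default 30).
#' @param days_distribution Named numeric vector of probability weights; names
#'   are half-day grid values in \{0.5, ..., 3.5\}; weights must sum to 1.
#' @param proficiency_rate Fraction in (0, 1] flagged proficient.
#' @param nights_policy Rule mapping billed days to nights; currently
#'   `"max1_round_half_up"`: `nights = max(1, round_half_up(billed_days))`.
#' @return A `group_params` list.
#' @export
group_params <- function(group, p_success_per_trial, max_trials = 30,
                         minutes_per_trial = 30, days_distribution,
                         proficiency_rate = 1,
                         nights_policy = "max1_round_half_up") {
  group <- match.arg(group, pbp_groups())
  stopifnot(
    is.numeric(p_success_per_trial), length(p_success_per_trial) == 1,
    p_success_per_trial > 0, p_success_per_trial <= 1,
    max_trials >= 1, max_trials == round(max_trials),
    minutes_per_trial > 0,
    is.numeric(proficiency_rate), proficiency_rate > 0, proficiency_rate <= 1
  )
  nights_policy <- match.arg(nights_policy, "max1_round_half_up")
  grid_vals <- as.numeric(names(days_distribution))
  if (anyNA(grid_vals) || !all(on_half_day_grid(grid_vals)) ||
      any(grid_vals <= 0) || any(grid_vals > DAY_CAP)) {
    stop("days_distribution names must be half-day values in (0, 3.5]")
  }
  if (abs(sum(days_distribution) - 1) > 1e-8 || any(days_distribution < 0)) {
    stop("days_distribution weights must be non-negative and sum to 1")
  }
  structure(list(
    group = group,
    p_success_per_trial = p_success_per_trial,
    max_trials = as.integer(max_trials),
    minutes_per_trial = minutes_per_trial,
    days_distribution = days_distribution,
    proficiency_rate = proficiency_rate,
    nights_policy = nights_policy
  ), class = "group_params")
}

apply_nights_policy <- function(days, policy = "max1_round_half_up") {
  switch(policy,
    max1_round_half_up = pmax(1L, as.integer(round_half_up(days))),
    stop("unknown nights policy: ", policy)
  )
}

# Two-point distribution on the half-day grid with a given mean: mass on the
# grid values bracketing the target. Degenerate (single point) when the
# target lies on the grid.
days_weights_for_mean <- function(mean_days) {
  if (mean_days < 0.5 || mean_days > DAY_CAP) {
    stop("mean_days ", mean_days, " outside the feasible range [0.5, 3.5]")
  }
  lo <- floor(mean_days / 0.5) * 0.5
  if (abs(lo - mean_days) < 1e-12) {
    w <- stats::setNames(1, format(lo))
  } else {
    hi <- lo + 0.5
    w_hi <- (mean_days - lo) / 0.5
    w <- stats::setNames(c(1 - w_hi, w_hi), c(format(lo), format(hi)))
  }
  w
}

#' Calibrate generator parameters to target group statistics
#'
#' Inverts the generator: finds the per-trial success probability whose
#' implied whole-group mean trials equals the target, and the days
#' distribution whose implied whole-group mean billed days equals the target.
#'
#' The group mean trials under the generator is
#' `rate * E_cens(p) + (1 - rate) * cap`, where `E_cens` is the censored
#' geometric mean ([censored_geometric_mean()]) and non-proficient trainees
#' (a `1 - rate` fraction) sit at the cap. `p` is solved numerically
#' (monotone in the mean, so a root bracket always exists when feasible).
#' Likewise the days distribution is calibrated on the proficient subset so
#' that, with non-proficient trainees at 3.5 days, the whole-group mean
#' matches `mean_days`.
#'
#' @param target A `group_summary` or list with elements `group`,
#'   `mean_trials`, `mean_days`, `prop_proficient`.
#' @param max_trials Trial cap (default 30).
#' @param minutes_per_trial Console minutes per trial (default 30).
#' @return A `group_params` object.
#' @export
calibrate_params <- function(target, max_trials = 30, minutes_per_trial = 30) {
  req <- c("group", "mean_trials", "mean_days", "prop_proficient")
  if (!all(req %in% names(target))) {
    stop("target must provide: ", paste(req, collapse = ", "))
  }
  rate <- target$prop_proficient
  m <- target$mean_trials
  cap <- max_trials
  stopifnot(rate > 0, rate <= 1)
  if (m > cap) stop("target mean_trials ", m, " exceeds the trial cap ", cap)
  group_mean <- function(p) rate * censored_geometric_mean(p, cap) + (1 - rate) * cap
  min_mean <- group_mean(1)            # all proficient succeed first trial
  if (m < min_mean - 1e-9) {
    stop("target mean_trials ", m, " unreachable: minimum under rate ",
         signif(rate, 4), " and cap ", cap, " is ", signif(min_mean, 6))
  }
  if (abs(m - min_mean) < 1e-9) {
    p <- 1
  } else {
    if (m >= cap - 1e-9) stop("target mean_trials ", m, " requires p = 0 at cap ", cap)
    p <- stats::uniroot(function(p) group_mean(p) - m,
                        interval = c(1e-12, 1), tol = 1e-14)$root
  }

  if (rate < 1) {
    m_days_prof <- (target$mean_days - (1 - rate) * DAY_CAP) / rate
    if (m_days_prof < 0.5) {
      stop("target mean_days ", target$mean_days,
           " infeasible: non-proficient trainees at 3.5 days already exceed it")
    }
  } else {
    m_days_prof <- target$mean_days
  }

  group_params(
    group = target$group,
    p_success_per_trial = p,
    max_trials = cap,
    minutes_per_trial = minutes_per_trial,
    days_distribution = days_weights_for_mean(m_days_prof),
    proficiency_rate = rate
  )
}

#' Generate a synthetic cohort of trainee records
#'
#' Deterministic given `(params, n, seed)`. Trainees are flagged proficient
#' with probability `proficiency_rate`. Proficient trainees draw trials from
#' the censored geometric distribution (geometric first-success censored at
#' `max_trials`) and billed days from the calibrated half-day distribution;
#' non-proficient trainees sit at the trial cap and the 3.5-day maximum.
#' Hands-on hours are `trials * minutes_per_trial / 60`; hotel nights follow
#' the nights policy.
#'
#' @param params A `group_params` object.
#' @param n Cohort size (>= 1).
#' @param seed Integer seed.
#' @return A `trainee_records` data frame with `n` rows.
#' @export
generate_cohort <- function(params, n, seed) {
  stopifnot(inherits(params, "group_params"), n >= 1, n == round(n))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed) ||
      seed != round(seed)) {
    stop("seed must be a single integer")
  }
  withr::with_seed(as.integer(seed), {
    proficient <- stats::runif(n) < params$proficiency_rate
    trials <- rep.int(params$max_trials, n)
    days <- rep.int(DAY_CAP, n)
    k <- sum(proficient)
    if (k > 0) {
      g <- stats::rgeom(k, params$p_success_per_trial) + 1L
      trials[proficient] <- pmin(g, params$max_trials)
      grid <- as.numeric(names(params$days_distribution))
      # index-based draw: sample(x, ...) with length-1 x would sample 1:x
      days[proficient] <- grid[sample.int(length(grid), k, replace = TRUE,
                                          prob = params$days_distribution)]
    }
    trainee_records(data.frame(
      trainee_id = sprintf("%s_%04d", params$group, seq_len(n)),
      group = params$group,
      trials = trials,
      hands_on_hours = trials * params$minutes_per_trial / 60,
      billed_days = days,
      nights = apply_nights_policy(days, params$nights_policy),
      proficient = proficient,
      stringsAsFactors = FALSE
    ))
  })
}

#' Serialize generator parameters to YAML
#'
#' @param params A `group_params` object or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  if (inherits(params, "group_params")) params <- list(params)
  yaml::write_yaml(lapply(params, function(p) {
    p <- unclass(p)
    p$days_distribution <- as.list(p$days_distribution)
    p
  }), path, precision = 15)
  invisible(path)
}

#' Calibration targets of the four trial arms
#'
#' The published group-level statistics used to calibrate the generator:
#' mean training trials to proficiency, mean hands-on hours, mean and median
#' billed laboratory days, and the fraction reaching the proficiency
#' benchmark (7/12 for the apprenticeship arm, 100% elsewhere). The
#' e-learning arm's trial count was never published; it is derived from its
#' published 3.38 mean hands-on hours via the 0.5 h-per-trial slot.
#'
#' @return Data frame with one row per group.
#' @export
osset_group_targets <- function() {
  data.frame(
    group = pbp_groups(),
    mean_trials = c(5.92, 3.38 / HOURS_PER_TRIAL, 12, 15),
    mean_hours = c(2.96, 3.38, 6.00, 7.75),
    mean_days = c(1.17, 1.29, 1.50, 2.67),
    median_days = c(1, 1.25, 1.5, 2.5),
    prop_proficient = c(1, 1, 1, 7 / 12),
    n_observed = c(12L, 12L, 11L, 12L),
    stringsAsFactors = FALSE
  )
}

#' Calibrated generator parameters for the trial arms
#'
#' @param groups Groups to calibrate (default all four).
#' @param max_trials Trial cap (default 30).
#' @return Named list of `group_params`.
#' @export
osset_params <- function(groups = pbp_groups(), max_trials = 30) {
  targets <- osset_group_targets()
  stats::setNames(lapply(groups, function(g) {
    calibrate_params(as.list(targets[targets$group == g, ]),
                     max_trials = max_trials)
  }), groups)
}
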