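#' Absorbing-Markov model of training progression
#'
#' Training is modelled as an absorbing Markov chain over trial counts: at
#' each trial the trainee reaches the proficiency benchmark ("absorbs") with
#' a state-independent probability `p`, otherwise moves to the next trial.
#' Training stops at `max_trials` regardless, so the number of trials a
#' trainee occupies is a geometric first-success variable censored at the
#' cap.
#'
#' @param group One of [pbp_groups()].
#' @param p_success_per_trial Probability in (0, 1].
#' @param max_trials Trial cap; may be `Inf` for the uncensored chain.
#' @return A `progression_model` list.
#' @export
progression_model <- function(group, p_success_per_trial, max_trials = 30) {
  group <- match.arg(group, pbp_groups())
  if (!is.numeric(p_success_per_trial) || p_success_per_trial <= 0 ||
      p_success_per_trial > 1) {
    stop("p_success_per_trial must be in (0, 1]")
  }
  stopifnot(max_trials >= 1)
  structure(list(
    group = group,
    p_success_per_trial = p_success_per_trial,
    max_trials = max_trials
  ), class = "progression_model")
}

#' Transition matrix of the training progression chain
#'
#' States are the number of trials completed (0 to `max_trials - 1`) plus two
#' absorbing states, `proficient` and `not_proficient` (reached when the cap
#' is exhausted without success). Each transient row continues with
#' probability `1 - p` and absorbs into `proficient` with probability `p`.
#'
#' @param model A `progression_model` with finite `max_trials`.
#' @return Square stochastic matrix with named rows/columns.
#' @export
transition_matrix <- function(model) {
  stopifnot(inherits(model, "progression_model"), is.finite(model$max_trials))
  cap <- model$max_trials
  p <- model$p_success_per_trial
  states <- c(paste0("t", 0:(cap - 1)), "proficient", "not_proficient")
  m <- matrix(0, nrow = cap + 2, ncol = cap + 2,
              dimnames = list(states, states))
  for (k in seq_len(cap)) {
    m[k, "proficient"] <- p
    if (k < cap) m[k, k + 1] <- 1 - p else m[k, "not_proficient"] <- 1 - p
  }
  m["proficient", "proficient"] <- 1
  m["not_proficient", "not_proficient"] <- 1
  m
}

#' Expected trials to absorption
#'
#' Closed form for the expected number of trials a trainee occupies under the
#' progression chain, i.e. the mean of the censored geometric distribution:
#' `(1 - (1 - p)^cap) / p` (and `1/p` for the uncensored chain).
#'
#' @param model A `progression_model`.
#' @return Expected number of trials.
#' @export
#' @examples
#' expected_trials(progression_model("G1_full_pbp", 0.5, Inf))  # 2
expected_trials <- function(model) {
  stopifnot(inherits(model, "progression_model"))
  censored_geometric_mean(model$p_success_per_trial, model$max_trials)
}

#' Monte-Carlo simulation of trials to absorption
#'
#' Runs `n` independent chains and returns the trials each occupied; the
#' empirical mean cross-checks [expected_trials()].
#'
#' @param model A `progression_model`.
#' @param n Number of chains.
#' @param seed Integer seed.
#' @return Integer vector of length `n`.
#' @export
simulate_trials <- function(model, n, seed) {
  stopifnot(inherits(model, "progression_model"), n >= 1)
  withr::with_seed(as.integer(seed), {
    g <- stats::rgeom(n, model$p_success_per_trial) + 1L
    if (is.finite(model$max_trials)) pmin(g, as.integer(model$max_trials)) else g
  })
}

#' Default cohort-size grid
#'
#' @return `c(12, 50, 100, 200, 300, 400, 500)`.
#' @export
default_size_grid <- function() c(12, 50, 100, 200, 300, 400, 500)

#' Project costs across cohort sizes
#'
#' Populates a grid of per-trainee and total costs for each curriculum at
#' each cohort size. Per-trainee values are display-rounded to whole euros
#' ([per_trainee_cost()]); the grid's total column is `size * per-trainee`,
#' the convention behind the published cohort totals (e.g. 12 x 14139 =
#' 169668). The exact affine total `n * v_g + F` is available from
#' [total_cost()] and differs from the grid total by at most half a euro per
#' trainee.
#'
#' When per-group uncertainty intervals for the variable cost are supplied,
#' the grid carries per-trainee and total interval bounds: the fixed
#' amortized share is treated as known (zero variance) and total bounds scale
#' the per-trainee bounds by the cohort size.
#'
#' @param profiles Named list of `group_cost_profile` (one per group).
#' @param rates A `cost_rates` object.
#' @param sizes Cohort sizes (default [default_size_grid()]).
#' @param intervals Optional named list of `interval_estimate` objects for the
#'   per-trainee variable cost, keyed by group.
#' @return A `projection_grid` data frame: one row per (size, group) with
#'   columns `size`, `group`, `per_trainee`, `total` and, when intervals are
#'   given, `per_trainee_lo/hi` and `total_lo/hi`.
#' @export
project <- function(profiles, rates, sizes = default_size_grid(),
                    intervals = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1,
            inherits(rates, "cost_rates"))
  if (length(sizes) == 0) stop("sizes must be a non-empty cohort-size list")
  if (any(sizes < 1)) stop("cohort sizes must be at least 1")
  rows <- lapply(sizes, function(n) {
    do.call(rbind, lapply(names(profiles), function(g) {
      prof <- profiles[[g]]
      pt <- per_trainee_cost(prof, rates, n)
      row <- data.frame(size = n, group = g, per_trainee = pt,
                        total = n * pt, stringsAsFactors = FALSE)
      if (!is.null(intervals)) {
        if (is.null(intervals[[g]])) stop("no interval supplied for group ", g)
        ci <- intervals[[g]]
        share <- amortize_fixed(as_euros(fixed_cents_for(prof, rates)), n,
                                display = FALSE)
        row$per_trainee_lo <- round_half_up(ci$lo + share)
        row$per_trainee_hi <- round_half_up(ci$hi + share)
        row$total_lo <- n * row$per_trainee_lo
        row$total_hi <- n * row$per_trainee_hi
      }
      row
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("projection_grid", "data.frame")
  out
}

#' Cost-equivalence (break-even) point between two curricula
#'
#' Solves `v_a + F/N = v_b` for the cohort size at which a fixed-cost-bearing
#' curriculum's per-trainee cost equals a flat-cost curriculum's:
#' `N* = F / (v_b - v_a)`. Beyond `N*` the fixed-cost curriculum is cheaper.
#' Also reports the smallest integer cohort at which its total cost is
#' strictly lower.
#'
#' @param profile_a Fixed-cost-bearing `group_cost_profile`.
#' @param profile_b Flat-cost `group_cost_profile` (no fixed cost).
#' @param rates A `cost_rates` object.
#' @return An `equivalence_point` list: `crossing` (logical), `n_star` (real
#'   cohort size, `NA` when no crossing), `n_integer` (smallest integer `N`
#'   with `total_a(N) < total_b(N)`), and the variable-cost gap in euros.
#' @export
equivalence_point <- function(profile_a, profile_b, rates) {
  stopifnot(inherits(profile_a, "group_cost_profile"),
            inherits(profile_b, "group_cost_profile"),
            inherits(rates, "cost_rates"))
  if (!profile_a$carries_fixed_cost) {
    stop("profile_a must carry the fixed cost")
  }
  if (profile_b$carries_fixed_cost) {
    stop("profile_b must not carry the fixed cost")
  }
  gap_cents <- profile_b$variable_cents - profile_a$variable_cents
  fixed <- rates$fixed_metrics_cents
  if (gap_cents <= 0) {
    out <- list(crossing = FALSE, n_star = NA_real_, n_integer = NA_integer_,
                variable_gap = as_euros(gap_cents))
  } else {
    n_star <- fixed / gap_cents
    n_int <- if (n_star < 1) 1L else as.integer(floor(n_star)) + 1L
    # floor(n_star) + 1 is strict only when n_star is not itself an integer
    if (n_star >= 1 && abs(n_star - round(n_star)) < 1e-12) {
      n_int <- as.integer(round(n_star)) + 1L
    }
    out <- list(crossing = TRUE, n_star = n_star, n_integer = n_int,
                variable_gap = as_euros(gap_cents))
  }
  class(out) <- "equivalence_point"
  out
}

#' @export
print.equivalence_point <- function(x, ...) {
  if (!x$crossing) {
    cat("no cost-equivalence point: variable-cost gap", x$variable_gap,
        "EUR is not positive\n")
  } else {
    cat(sprintf(
      "cost equivalence at %.2f trainees (first strictly cheaper integer cohort: %d)\n",
      x$n_star, x$n_integer))
  }
  invisible(x)
}

#' Relative cost advantage, in percent
#'
#' `100 * (cost_ref - cost_alt) / cost_alt`, rounded half-up to the nearest
#' integer: how much more expensive the reference is than the alternative,
#' the convention behind statements like "a 110% cost advantage".
#'
#' @param cost_ref Reference cost (e.g. the conventional curriculum).
#' @param cost_alt Alternative cost (> 0).
#' @return Integer percent.
#' @export
#' @examples
#' relative_cost_advantage(7067, 3373)  # 110
relative_cost_advantage <- function(cost_ref, cost_alt) {
  stopifnot(is.numeric(cost_ref), is.numeric(cost_alt))
  if (any(cost_alt <= 0)) stop("cost_alt must be positive")
  round_half_up(100 * (cost_ref - cost_alt) / cost_alt)
}
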