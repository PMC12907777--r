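#' Unit cost rates
#'
#' The cost constants of the training programme: laboratory rate per person
#' per day (billed in full or half days), hotel rate per night, and the fixed
#' one-time cost of developing and validating the performance metrics and
#' e-learning content. The fixed cost is charged only to the PBP-derived
#' curricula (groups 1-3), never to the apprenticeship arm.
#'
#' @param lab_day_rate Euros per person-day (default 2450).
#' @param hotel_night_rate Euros per night (default 200).
#' @param fixed_metrics_cost Euros, one-time (default 132377).
#' @return A `cost_rates` list; amounts validated to whole cents.
#' @export
cost_rates <- function(lab_day_rate = 2450, hotel_night_rate = 200,
                       fixed_metrics_cost = 132377) {
  stopifnot(lab_day_rate >= 0, hotel_night_rate >= 0, fixed_metrics_cost >= 0)
  structure(list(
    lab_day_cents = as_cents(lab_day_rate),
    hotel_night_cents = as_cents(hotel_night_rate),
    fixed_metrics_cents = as_cents(fixed_metrics_cost)
  ), class = "cost_rates")
}

#' @export
print.cost_rates <- function(x, ...) {
  cat(sprintf("cost rates: lab %s/day, hotel %s/night, fixed metrics %s\n",
              format_eur(as_euros(x$lab_day_cents)),
              format_eur(as_euros(x$hotel_night_cents)),
              format_eur(as_euros(x$fixed_metrics_cents))))
  invisible(x)
}

#' A curriculum's cost profile
#'
#' The per-trainee variable cost `v_g` (laboratory days plus hotel nights
#' consumed until proficiency) and whether the curriculum carries a share of
#' the fixed metrics cost.
#'
#' @param group One of [pbp_groups()].
#' @param per_trainee_variable_cost Euros per trainee (> 0).
#' @param carries_fixed_cost Logical; `TRUE` for PBP-derived curricula.
#' @param calibration_source `"from_printed_per_trainee_at_12"` or
#'   `"from_records"`.
#' @return A `group_cost_profile` list; cost stored in exact cents.
#' @export
group_cost_profile <- function(group, per_trainee_variable_cost,
                               carries_fixed_cost,
                               calibration_source = c(
                                 "from_printed_per_trainee_at_12",
                                 "from_records")) {
  group <- match.arg(group, pbp_groups())
  calibration_source <- match.arg(calibration_source)
  stopifnot(is.numeric(per_trainee_variable_cost),
            per_trainee_variable_cost > 0,
            is.logical(carries_fixed_cost), length(carries_fixed_cost) == 1)
  if (group == "G4_apprenticeship" && carries_fixed_cost) {
    stop("the apprenticeship curriculum never carries the fixed metrics cost")
  }
  structure(list(
    group = group,
    variable_cents = as_cents(per_trainee_variable_cost),
    carries_fixed_cost = carries_fixed_cost,
    calibration_source = calibration_source
  ), class = "group_cost_profile")
}

#' Amortize the fixed metrics cost over a cohort
#'
#' Evenly distributes the one-time metrics development cost over
#' `n_trainees`, e.g. 132377 euros over 12 trainees is 11031 per trainee and
#' over 500 trainees is 265 per trainee.
#'
#' @param fixed_cost Euros (>= 0).
#' @param n_trainees Cohort size (>= 1).
#' @param display If `TRUE` (default), round half-up to whole euros; if
#'   `FALSE`, return the exact per-trainee share.
#' @return Euros per trainee.
#' @export
#' @examples
#' amortize_fixed(132377, 12)   # 11031
#' amortize_fixed(132377, 500)  # 265
amortize_fixed <- function(fixed_cost, n_trainees, display = TRUE) {
  stopifnot(is.numeric(fixed_cost), fixed_cost >= 0)
  if (!is.numeric(n_trainees) || any(n_trainees < 1)) {
    stop("n_trainees must be at least 1")
  }
  share <- as_euros(as_cents(fixed_cost)) / n_trainees
  if (display) round_half_up(share) else share
}

#' Variable cost of a single trainee
#'
#' `lab_day_rate * billed_days + hotel_night_rate * nights`; the fixed-cost
#' share is added separately at the cohort level.
#'
#' @param record One row of a `trainee_records` data frame (or the whole
#'   frame, vectorised).
#' @param rates A `cost_rates` object.
#' @return Euros (exact; lab and hotel rates are whole cents so no rounding
#'   occurs).
#' @export
trainee_cost <- function(record, rates) {
  stopifnot(inherits(rates, "cost_rates"),
            all(c("billed_days", "nights") %in% names(record)))
  as_euros(rates$lab_day_cents * record$billed_days +
           rates$hotel_night_cents * record$nights)
}

fixed_cents_for <- function(profile, rates) {
  if (profile$carries_fixed_cost) rates$fixed_metrics_cents else 0
}

#' Per-trainee cost at a given cohort size
#'
#' For fixed-cost-bearing curricula: variable cost plus the amortized fixed
#' share `v_g + F / n`, strictly decreasing in `n` and converging to `v_g`.
#' For the apprenticeship curriculum: constant `v_g`.
#'
#' @param profile A `group_cost_profile`.
#' @param rates A `cost_rates` object.
#' @param n_trainees Cohort size(s) (>= 1); vectorised.
#' @param display If `TRUE` (default) round half-up to whole euros.
#' @return Euros per trainee.
#' @export
per_trainee_cost <- function(profile, rates, n_trainees, display = TRUE) {
  stopifnot(inherits(profile, "group_cost_profile"), inherits(rates, "cost_rates"))
  if (!is.numeric(n_trainees) || any(n_trainees < 1)) {
    stop("n_trainees must be at least 1")
  }
  cents <- profile$variable_cents + fixed_cents_for(profile, rates) / n_trainees
  out <- as_euros(cents)
  if (display) round_half_up(out) else out
}

#' Total cohort cost at a given size
#'
#' The affine cost model: `n * v_g + F` for fixed-cost-bearing curricula
#' (the fixed cost is charged once, never per trainee) and `n * v_g` for the
#' apprenticeship curriculum.
#'
#' @inheritParams per_trainee_cost
#' @return Euros.
#' @export
total_cost <- function(profile, rates, n_trainees, display = TRUE) {
  stopifnot(inherits(profile, "group_cost_profile"), inherits(rates, "cost_rates"))
  if (!is.numeric(n_trainees) || any(n_trainees < 1)) {
    stop("n_trainees must be at least 1")
  }
  cents <- n_trainees * profile$variable_cents + fixed_cents_for(profile, rates)
  out <- as_euros(cents)
  if (display) round_half_up(out) else out
}

#' Effective cost per proficient trainee
#'
#' Divides the per-trainee cost by the fraction of trainees who actually
#' reach the proficiency benchmark: a curriculum that graduates only 58% of
#' its trainees must train `1/0.58` trainees per proficient surgeon produced.
#'
#' @inheritParams per_trainee_cost
#' @param proficiency_rate Fraction in (0, 1].
#' @return Euros per proficient trainee.
#' @export
cost_per_proficient_trainee <- function(profile, rates, n_trainees,
                                        proficiency_rate, display = TRUE) {
  if (!is.numeric(proficiency_rate) || any(proficiency_rate <= 0) ||
      any(proficiency_rate > 1)) {
    stop("proficiency_rate must be in (0, 1]")
  }
  out <- per_trainee_cost(profile, rates, n_trainees, display = FALSE) /
    proficiency_rate
  if (display) round_half_up(out) else out
}

# Published per-trainee costs at the 12-trainee cohort: G1 printed directly,
# G2/G3 as printed group totals / 12, G4 as printed total / 12.
printed_per_trainee_at_12 <- function() {
  c(G1_full_pbp = 14139,
    G2_elearning = 174144 / 12,      # 14512
    G3_traditional = 182604 / 12,    # 15217
    G4_apprenticeship = 84804 / 12)  # 7067
}

#' Calibrate a cost profile from the published 12-trainee figures
#'
#' The canonical calibration path: the variable cost `v_g` is the published
#' per-trainee cost at 12 trainees minus the (display-rounded) amortized
#' fixed share at 12 — e.g. `14139 - 11031 = 3108` for the full-PBP arm. The
#' apprenticeship arm carries no fixed cost, so its per-trainee figure is
#' `v_g` directly.
#'
#' @param group One of [pbp_groups()].
#' @param rates A `cost_rates` object.
#' @return A `group_cost_profile`.
#' @export
calibrate_profile_printed <- function(group, rates = cost_rates()) {
  group <- match.arg(group, pbp_groups())
  per12 <- printed_per_trainee_at_12()[[group]]
  carries <- group != "G4_apprenticeship"
  v <- if (carries) {
    per12 - amortize_fixed(as_euros(rates$fixed_metrics_cents), 12)
  } else {
    per12
  }
  group_cost_profile(group, v, carries, "from_printed_per_trainee_at_12")
}

#' Calibrate a cost profile from trainee records
#'
#' The alternative path: `v_g` is the mean variable cost ([trainee_cost()])
#' over a group's records. Agrees with the published-figure calibration only
#' approximately, since the published figures carry rounding.
#'
#' @param records A `trainee_records` object.
#' @param group One of [pbp_groups()].
#' @param rates A `cost_rates` object.
#' @return A `group_cost_profile`.
#' @export
calibrate_profile_records <- function(records, group, rates = cost_rates()) {
  group <- match.arg(group, pbp_groups())
  sub <- records[records$group == group, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records for group ", group)
  v <- as_euros(round(mean(as_cents(trainee_cost(sub, rates)))))
  group_cost_profile(group, v, group != "G4_apprenticeship", "from_records")
}

#' Cost profiles for all four curricula
#'
#' @param source `"printed"` (calibrate from published per-trainee figures at
#'   12 trainees) or `"records"` (calibrate from trainee-level records).
#' @param rates A `cost_rates` object.
#' @param records Required when `source = "records"`.
#' @return Named list of `group_cost_profile`, one per group.
#' @export
osset_profiles <- function(source = c("printed", "records"),
                           rates = cost_rates(), records = NULL) {
  source <- match.arg(source)
  stats::setNames(lapply(pbp_groups(), function(g) {
    if (source == "printed") {
      calibrate_profile_printed(g, rates)
    } else {
      if (is.null(records)) stop("records required for source = 'records'")
      calibrate_profile_records(records, g, rates)
    }
  }), pbp_groups())
}

#' Variable cost of a profile, in euros
#'
#' @param profile A `group_cost_profile`.
#' @return Euros.
#' @export
variable_cost <- function(profile) {
  stopifnot(inherits(profile, "group_cost_profile"))
  as_euros(profile$variable_cents)
}
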