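#' Configuration of a full reproduction run
#'
#' Collects every input of the pipeline — cost rates, calibration source,
#' cohort-size grid, seeds, resampling settings — so a run is fully
#' determined by its config. The config is serialized to YAML next to the
#' outputs of [run_reproduction()].
#'
#' @param rates A `cost_rates` object.
#' @param calibration `"printed"` (variable costs from the published
#'   12-trainee figures) or `"records"` (from the generated cohorts).
#' @param sizes Cohort-size grid.
#' @param cohort_n Synthetic trainees generated per group (default 12, the
#'   trial's arm size).
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @param n_boot Bootstrap resamples.
#' @param n_perm Permutations.
#' @param level Confidence level.
#' @return A `run_config` list.
#' @export
run_config <- function(rates = cost_rates(), calibration = c("printed", "records"),
                       sizes = default_size_grid(), cohort_n = 12,
                       seed = 20260921, n_boot = 10000, n_perm = 9999,
                       level = 0.95) {
  calibration <- match.arg(calibration)
  stopifnot(inherits(rates, "cost_rates"), cohort_n >= 2,
            seed == round(seed), abs(seed) < 2^31 - 10)
  structure(list(
    rates = rates, calibration = calibration, sizes = sizes,
    cohort_n = cohort_n, seed = as.integer(seed),
    n_boot = n_boot, n_perm = n_perm, level = level
  ), class = "run_config")
}

config_as_list <- function(config) {
  list(
    lab_day_rate = as_euros(config$rates$lab_day_cents),
    hotel_night_rate = as_euros(config$rates$hotel_night_cents),
    fixed_metrics_cost = as_euros(config$rates$fixed_metrics_cents),
    calibration = config$calibration,
    sizes = as.numeric(config$sizes),
    cohort_n = config$cohort_n,
    seed = config$seed,
    n_boot = config$n_boot,
    n_perm = config$n_perm,
    level = config$level
  )
}

# Derived per-stage seeds, all < 2^31.
stage_seed <- function(config, stage) {
  offsets <- c(cohort = 11L, bootstrap = 23L, permutation = 37L)
  (config$seed + offsets[[stage]]) %% .Machine$integer.max
}

grid_to_wide <- function(grid) {
  value_cols <- setdiff(names(grid), c("size", "group"))
  out <- data.frame(size = sort(unique(grid$size)))
  for (g in unique(grid$group)) {
    sub <- grid[grid$group == g, ]
    sub <- sub[order(sub$size), ]
    for (col in value_cols) {
      out[[paste(g, col, sep = ".")]] <- sub[[col]]
    }
  }
  out
}

write_table <- function(df, dir, name, log) {
  # stage via tempfile + rename so a failed run leaves no half-written table
  tmp <- tempfile(tmpdir = dir, fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE)
  path <- file.path(dir, name)
  file.rename(tmp, path)
  cat(sprintf("wrote %s (%d rows x %d cols)\n", name, nrow(df), ncol(df)),
      file = log, append = TRUE)
  path
}

#' Run the full cost-analysis reproduction
#'
#' Executes the whole pipeline: generates synthetic cohorts for the four
#' curricula, summarises them, calibrates cost profiles, builds the
#' amortization schedule and the per-trainee and total cost grids with
#' bootstrap uncertainty bounds, locates the cost-equivalence point between
#' full PBP and apprenticeship training, and runs permutation tests of
#' between-group cost differences. All tables are computed first and written
#' only afterwards (no half-written output on failure); the config and a log
#' of every table are written alongside. Two runs with identical configs
#' produce byte-identical CSVs.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the computed tables.
#' @export
run_reproduction <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)

  rates <- config$rates
  params <- osset_params()
  cohorts <- do.call(rbind, lapply(seq_along(params), function(i) {
    generate_cohort(params[[i]], config$cohort_n,
                    seed = stage_seed(config, "cohort") + i)
  }))
  class(cohorts) <- c("trainee_records", "data.frame")

  summaries <- summarize_groups(cohorts)
  ref_hours <- summaries$mean_hours[summaries$group == "G1_full_pbp"]
  summaries$hours_increase_vs_g1_pct <-
    percent_increase(ref_hours, summaries$mean_hours)

  profiles <- osset_profiles(config$calibration, rates, records = cohorts)

  amort <- data.frame(
    n_trainees = config$sizes,
    amortized_share = amortize_fixed(as_euros(rates$fixed_metrics_cents),
                                     config$sizes)
  )

  intervals <- lapply(pbp_groups(), function(g) {
    costs <- trainee_cost(cohorts[cohorts$group == g, ], rates)
    bootstrap_ci(costs, level = config$level, n_boot = config$n_boot,
                 seed = stage_seed(config, "bootstrap"))
  })
  names(intervals) <- pbp_groups()

  grid <- project(profiles, rates, config$sizes, intervals = intervals)
  per_trainee_grid <- grid_to_wide(
    grid[, c("size", "group", "per_trainee", "per_trainee_lo", "per_trainee_hi")])
  per_trainee_grid$amortized_share <- amort$amortized_share[
    match(per_trainee_grid$size, amort$n_trainees)]
  total_grid <- grid_to_wide(
    grid[, c("size", "group", "total", "total_lo", "total_hi")])

  eq <- equivalence_point(profiles$G1_full_pbp, profiles$G4_apprenticeship, rates)
  g4 <- per_trainee_cost(profiles$G4_apprenticeship, rates, 1)
  equivalence <- data.frame(
    comparison = "G1_full_pbp_vs_G4_apprenticeship",
    n_star = eq$n_star,
    first_cheaper_integer_cohort = eq$n_integer,
    variable_gap = eq$variable_gap,
    advantage_at_50_pct = relative_cost_advantage(
      g4, per_trainee_cost(profiles$G1_full_pbp, rates, 50)),
    advantage_at_500_pct = relative_cost_advantage(
      g4, per_trainee_cost(profiles$G1_full_pbp, rates, 500)),
    g4_cost_per_proficient = cost_per_proficient_trainee(
      profiles$G4_apprenticeship, rates, 12, 7 / 12)
  )

  uncertainty <- do.call(rbind, lapply(pbp_groups(), function(g) {
    ci <- intervals[[g]]
    data.frame(group = g, point = ci$point, lo = ci$lo, hi = ci$hi,
               level = ci$level, method = ci$method, n_boot = ci$n_boot,
               seed = ci$seed, stringsAsFactors = FALSE)
  }))

  perm <- do.call(rbind, lapply(setdiff(pbp_groups(), "G4_apprenticeship"),
    function(g) {
      pt <- permutation_test(
        trainee_cost(cohorts[cohorts$group == g, ], rates),
        trainee_cost(cohorts[cohorts$group == "G4_apprenticeship", ], rates),
        n_perm = config$n_perm, seed = stage_seed(config, "permutation"))
      data.frame(group_a = g, group_b = "G4_apprenticeship",
                 mean_difference = pt$statistic, p_value = pt$p_value,
                 n_perm = pt$n_perm, stringsAsFactors = FALSE)
    }))

  tables <- list(
    cohorts = as.data.frame(cohorts),
    group_summaries = summaries,
    amortization = amort,
    per_trainee_grid = per_trainee_grid,
    total_grid = total_grid,
    equivalence = equivalence,
    uncertainty = uncertainty,
    permutation_tests = perm
  )

  log <- file.path(out_dir, "run.log")
  cat(sprintf("pbpcost reproduction run, master seed %d, calibration '%s'\n",
              config$seed, config$calibration), file = log)
  yaml::write_yaml(config_as_list(config), file.path(out_dir, "config.yaml"))
  for (nm in names(tables)) {
    write_table(tables[[nm]], out_dir, paste0(nm, ".csv"), log)
  }
  invisible(tables)
}
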