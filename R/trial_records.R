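#' Curriculum group labels
#'
#' The four training curricula, in decreasing order of adherence to
#' proficiency-based progression (PBP): full PBP (online training with a
#' mandatory benchmark before practice), e-learning (same content, no
#' benchmark), traditional (in-person lectures), and apprenticeship
#' (expert-supervised conventional training, no metrics or benchmarks).
#'
#' @return Character vector of the four group labels.
#' @export
pbp_groups <- function() {
  c("G1_full_pbp", "G2_elearning", "G3_traditional", "G4_apprenticeship")
}

# Column schema shared by the reader, writer and generator.
record_columns <- function() {
  c("trainee_id", "group", "trials", "hands_on_hours",
    "billed_days", "nights", "proficient")
}

# Training was limited to 3.5 laboratory days per group, billed on a
# half-day grid; each training trial occupies at most a 30-minute console slot.
DAY_CAP <- 3.5
HOURS_PER_TRIAL <- 0.5

on_half_day_grid <- function(x, tol = 1e-8) abs(x * 2 - round(x * 2)) < tol

#' Construct a validated set of trainee records
#'
#' A trainee record holds one participant's training trajectory and billable
#' resource use: training trials attempted, hands-on robot console hours,
#' laboratory days billed on a half-day grid, hotel nights, and whether the
#' proficiency benchmark was reached within the allotted training.
#'
#' Invariants enforced:
#' * `billed_days` lies on the half-day grid \{0.5, 1.0, 1.5, ...\} and is
#'   at most 3.5 (the per-group laboratory limit);
#' * `hands_on_hours <= 0.5 * trials + tol` (each trial is capped at 30 min);
#' * `trials` is a positive integer, `nights` a non-negative integer;
#' * `group` is one of [pbp_groups()].
#'
#' @param df A data frame with columns `trainee_id`, `group`, `trials`,
#'   `hands_on_hours`, `billed_days`, `nights`, `proficient`.
#' @param tol Numeric tolerance for the hours-per-trial cap.
#' @return `df` with class `trainee_records` prepended, types normalised.
#' @export
trainee_records <- function(df, tol = 1e-6) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(record_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[record_columns()]
  df$trainee_id <- as.character(df$trainee_id)
  df$group <- as.character(df$group)
  df$proficient <- as.logical(df$proficient)

  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad)) {
      problems <<- c(problems, paste0(
        msg, " (row ", paste(which(bad), collapse = ", "), ")"))
    }
  }
  flag(!df$group %in% pbp_groups(), "unknown group label")
  flag(is.na(df$trials) | df$trials < 1 | df$trials != round(df$trials),
       "trials must be a positive integer")
  flag(is.na(df$hands_on_hours) | df$hands_on_hours < 0,
       "hands_on_hours must be non-negative")
  flag(df$hands_on_hours > HOURS_PER_TRIAL * df$trials + tol,
       "hands_on_hours exceeds 0.5 h per trial cap")
  flag(is.na(df$billed_days) | df$billed_days <= 0 | !on_half_day_grid(df$billed_days),
       "billed_days must be a positive half-day multiple")
  flag(df$billed_days > DAY_CAP + 1e-8,
       "billed_days exceeds the 3.5-day training limit")
  flag(is.na(df$nights) | df$nights < 0 | df$nights != round(df$nights),
       "nights must be a non-negative integer")
  flag(is.na(df$proficient), "proficient must be TRUE/FALSE")
  if (length(problems) > 0) {
    stop("invalid trainee record(s):\n  ", paste(problems, collapse = "\n  "))
  }
  df$trials <- as.integer(df$trials)
  df$nights <- as.integer(df$nights)
  class(df) <- c("trainee_records", "data.frame")
  df
}

#' Read trainee records from a CSV file
#'
#' Expects a comma-separated UTF-8 file with a header row naming the columns
#' `trainee_id, group, trials, hands_on_hours, billed_days, nights,
#' proficient`. Every row is validated; violations are reported with row
#' numbers.
#'
#' @param path Path to the CSV file.
#' @return A `trainee_records` data frame.
#' @seealso [write_records()], [trainee_records()]
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  trainee_records(df)
}

#' Write trainee records to a CSV file
#'
#' @param records A `trainee_records` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(inherits(records, "trainee_records"))
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarise one curriculum group
#'
#' Descriptive statistics for a group's trainee records: trainee count,
#' fraction reaching the proficiency benchmark (exact), and means/medians of
#' trials, hands-on hours, laboratory days and hotel nights.
#'
#' @param records A `trainee_records` object.
#' @param group One of [pbp_groups()].
#' @return A `group_summary` list with elements `group`, `n`,
#'   `prop_proficient`, `mean_trials`, `mean_hours`, `mean_days`,
#'   `median_days`, `mean_nights`.
#' @export
summarize_group <- function(records, group) {
  stopifnot(inherits(records, "trainee_records"))
  group <- match.arg(group, pbp_groups())
  sub <- records[records$group == group, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records for group ", group)
  out <- list(
    group = group,
    n = nrow(sub),
    prop_proficient = sum(sub$proficient) / nrow(sub),
    mean_trials = mean(sub$trials),
    mean_hours = mean(sub$hands_on_hours),
    mean_days = mean(sub$billed_days),
    median_days = stats::median(sub$billed_days),
    mean_nights = mean(sub$nights)
  )
  class(out) <- "group_summary"
  out
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(
    "%s: n=%d, proficient %.1f%%, trials %.2f, hours %.2f, days %.2f (median %.2f), nights %.2f\n",
    x$group, x$n, 100 * x$prop_proficient, x$mean_trials, x$mean_hours,
    x$mean_days, x$median_days, x$mean_nights))
  invisible(x)
}

#' Summarise all groups present in a record set
#'
#' @param records A `trainee_records` object.
#' @return A data frame with one row per group, columns as in
#'   [summarize_group()].
#' @export
summarize_groups <- function(records) {
  stopifnot(inherits(records, "trainee_records"))
  groups <- intersect(pbp_groups(), unique(records$group))
  do.call(rbind, lapply(groups, function(g) {
    as.data.frame(unclass(summarize_group(records, g)))
  }))
}

#' Export a group summary as JSON
#'
#' @param summary A `group_summary` object or the data frame from
#'   [summarize_groups()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  if (inherits(summary, "group_summary")) summary <- unclass(summary)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Percent increase relative to a reference
#'
#' `100 * (value - reference) / reference`, rounded half-up to the nearest
#' integer — the convention behind statements like "required 14% more
#' hands-on time".
#'
#' @param reference Positive reference value (e.g. the full-PBP group's mean
#'   hands-on hours).
#' @param value Value to compare.
#' @return Integer percent change (negative when `value < reference`).
#' @export
#' @examples
#' percent_increase(2.96, 3.38)  # 14
#' percent_increase(2.96, 6.00)  # 103
percent_increase <- function(reference, value) {
  stopifnot(is.numeric(reference), is.numeric(value))
  if (any(reference <= 0)) stop("reference must be positive")
  round_half_up(100 * (value - reference) / reference)
}
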