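#' Bootstrap confidence interval for a mean
#'
#' Percentile bootstrap of the sample mean (default), or a normal-theory
#' interval `mean +/- z * sd/sqrt(n)`. Used for the per-trainee variable
#' cost; the amortized fixed share is a known constant and is added outside
#' the interval. A constant input yields a degenerate zero-width interval,
#' flagged but not an error.
#'
#' @param values Numeric vector (length >= 2), e.g. per-trainee variable
#'   costs.
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param n_boot Number of bootstrap resamples (>= 1000; default 10000).
#' @param seed Integer seed (required for the percentile method).
#' @param method `"percentile_bootstrap"` or `"normal"`.
#' @return An `interval_estimate` list: `point` (sample mean), `lo`, `hi`,
#'   `level`, `method`, `n_boot`, `seed`, `degenerate`.
#' @export
bootstrap_ci <- function(values, level = 0.95, n_boot = 10000, seed = NULL,
                         method = c("percentile_bootstrap", "normal")) {
  method <- match.arg(method)
  stopifnot(is.numeric(values), length(values) >= 2, level > 0, level < 1)
  point <- mean(values)
  alpha <- 1 - level
  degenerate <- stats::sd(values) == 0
  if (degenerate) {
    lo <- hi <- point
  } else if (method == "normal") {
    half <- stats::qnorm(1 - alpha / 2) * stats::sd(values) / sqrt(length(values))
    lo <- point - half
    hi <- point + half
  } else {
    if (n_boot < 1000) stop("n_boot must be at least 1000")
    if (is.null(seed)) stop("seed is required for the percentile bootstrap")
    n <- length(values)
    means <- withr::with_seed(as.integer(seed), {
      colMeans(matrix(sample(values, n * n_boot, replace = TRUE), nrow = n))
    })
    q <- stats::quantile(means, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo <- q[1]
    hi <- q[2]
  }
  structure(list(point = point, lo = lo, hi = hi, level = level,
                 method = method,
                 n_boot = if (method == "percentile_bootstrap" && !degenerate) n_boot else NA_integer_,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 degenerate = degenerate),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.2f (%d%% CI %.2f-%.2f, %s%s)\n", x$point,
              round(100 * x$level), x$lo, x$hi, x$method,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' Scale an interval estimate by a constant
#'
#' Multiplies point and bounds by `k`: the total-cost interval for a cohort
#' of `n` trainees is `n` times the per-trainee interval.
#'
#' @param interval An `interval_estimate`.
#' @param k Positive scale factor.
#' @param shift Constant added after scaling (default 0), e.g. the fixed cost.
#' @return A new `interval_estimate`.
#' @export
scale_interval <- function(interval, k, shift = 0) {
  stopifnot(inherits(interval, "interval_estimate"), k > 0)
  out <- interval
  out$point <- k * interval$point + shift
  out$lo <- k * interval$lo + shift
  out$hi <- k * interval$hi + shift
  out
}

# Mean difference for a pooled vector split by a logical assignment.
mean_diff <- function(pooled, in_a) {
  mean(pooled[in_a]) - mean(pooled[!in_a])
}

#' Two-sample permutation test for a difference in means
#'
#' Two-sided test of `mean(a) == mean(b)` by permuting group labels. The
#' Monte-Carlo p-value uses the add-one correction
#' `p = (b + 1) / (n_perm + 1)` where `b` counts permuted statistics at least
#' as extreme as the observed `|mean(a) - mean(b)|`; it is therefore bounded
#' below by `1 / (n_perm + 1)`. With `exact = TRUE` (feasible for small
#' groups) all label assignments are enumerated and the p-value is the exact
#' proportion of assignments at least as extreme, with no correction.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param n_perm Number of permutations (>= 999; default 9999).
#' @param seed Integer seed (required unless `exact = TRUE`).
#' @param exact Enumerate all `choose(na + nb, na)` assignments instead of
#'   sampling (refuses above 500000 assignments).
#' @return A `permutation_test` list: `p_value`, `statistic` (observed mean
#'   difference a - b), `n_perm` (or number of assignments enumerated),
#'   `exact`, `seed`.
#' @export
permutation_test <- function(group_a, group_b, n_perm = 9999, seed = NULL,
                             exact = FALSE) {
  stopifnot(is.numeric(group_a), is.numeric(group_b),
            length(group_a) >= 1, length(group_b) >= 1)
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  obs <- mean(group_a) - mean(group_b)
  tol <- 1e-9 * (max(abs(pooled)) + 1)
  if (exact) {
    combos <- utils::combn(length(pooled), na)
    stats_all <- apply(combos, 2, function(idx) {
      in_a <- rep(FALSE, length(pooled))
      in_a[idx] <- TRUE
      mean_diff(pooled, in_a)
    })
    n_used <- ncol(combos)
    if (n_used > 500000) stop("too many assignments for exact enumeration")
    p <- mean(abs(stats_all) >= abs(obs) - tol)
  } else {
    if (n_perm < 999) stop("n_perm must be at least 999")
    if (is.null(seed)) stop("seed is required for the Monte-Carlo test")
    stats_all <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(pooled), na)
        in_a <- rep(FALSE, length(pooled))
        in_a[idx] <- TRUE
        mean_diff(pooled, in_a)
      }, numeric(1))
    })
    b <- sum(abs(stats_all) >= abs(obs) - tol)
    p <- (b + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(p_value = p, statistic = obs, n_perm = n_used,
                 exact = exact,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("permutation test: mean difference %.2f, p = %.4g (%s, %d %s)\n",
              x$statistic, x$p_value,
              if (x$exact) "exact" else "Monte-Carlo",
              x$n_perm,
              if (x$exact) "assignments" else "permutations"))
  invisible(x)
}
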