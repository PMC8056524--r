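#' Power of a two-sided two-sample t-test
#'
#' Computes the exact power of the equal-n, equal-variance two-sample t-test
#' from the noncentral t distribution: with `n` subjects per arm the test
#' statistic has `2n - 2` degrees of freedom and noncentrality
#' `mean_diff / (sd * sqrt(2/n))`, and power is the probability that its
#' absolute value exceeds the two-sided critical value. No normal
#' approximation is used.
#'
#' @param n_per_arm Integer (vectorised), subjects per arm, >= 2.
#' @param mean_diff True difference in group means (same units as `sd`).
#' @param sd Common within-group standard deviation, > 0.
#' @param alpha Two-sided type-I error rate, default 0.05.
#'
#' @return Numeric vector of power values in [0, 1].
#' @export
#' @examples
#' power_two_sample_t(44, 0.2 * 2.83, 0.93)
power_two_sample_t <- function(n_per_arm, mean_diff, sd, alpha = 0.05) {
  if (any(n_per_arm < 2)) stop("n_per_arm must be >= 2")
  if (sd <= 0) stop("sd must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- 2 * n_per_arm - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- mean_diff / (sd * sqrt(2 / n_per_arm))
  stats::pt(-tcrit, df, ncp = ncp) + stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
}

#' Smallest per-arm n detecting a fractional reduction in accumulation rate
#'
#' Finds the minimal integer `n` per arm for which a two-sided two-sample
#' t-test at level `alpha` reaches `target_power` to detect a difference of
#' `reduction_fraction * mean_pct` between arms, assuming a common SD of
#' `sd_pct`. This is the design used for amyloid prevention trials: the
#' treated arm's mean annualized accumulation is reduced by a fixed fraction
#' (default 20%) relative to placebo.
#'
#' The search brackets the solution by doubling and then bisects; minimality
#' (power at `n - 1` below target) is asserted on every call.
#'
#' @param mean_pct Placebo-arm mean annualized % change (must be positive:
#'   powering a trial on a fractional reduction of a non-positive
#'   accumulation rate is undefined).
#' @param sd_pct Between-subject SD of annualized % change, > 0.
#' @param reduction_fraction Fraction of `mean_pct` removed by treatment,
#'   in (0, 1); default 0.20.
#' @param alpha Two-sided type-I error, default 0.05.
#' @param target_power Required power, default 0.80.
#'
#' @return A list of class `sample_size_result` with `n_per_arm`,
#'   `achieved_power` (at n), `power_below` (at n - 1), and the inputs.
#' @export
#' @examples
#' required_n_per_arm(2.83, 0.93)$n_per_arm  # 44
required_n_per_arm <- function(mean_pct, sd_pct, reduction_fraction = 0.20,
                               alpha = 0.05, target_power = 0.80) {
  if (!is.finite(mean_pct) || mean_pct <= 0) {
    stop("mean_pct must be positive: a fractional reduction of a non-positive ",
         "accumulation rate does not define a detectable effect")
  }
  if (sd_pct <= 0) stop("sd_pct must be positive")
  if (reduction_fraction <= 0 || reduction_fraction >= 1) {
    stop("reduction_fraction must be in (0, 1)")
  }
  if (target_power <= 0 || target_power >= 1) stop("target_power must be in (0, 1)")
  mean_diff <- reduction_fraction * mean_pct

  lo <- 2L
  if (power_two_sample_t(lo, mean_diff, sd_pct, alpha) >= target_power) {
    n <- lo
  } else {
    hi <- 4L
    while (power_two_sample_t(hi, mean_diff, sd_pct, alpha) < target_power) {
      lo <- hi
      hi <- hi * 2L
      if (hi > 1e8) stop("required n exceeds 1e8; check inputs")
    }
    while (hi - lo > 1L) {
      mid <- lo + (hi - lo) %/% 2L
      if (power_two_sample_t(mid, mean_diff, sd_pct, alpha) >= target_power) {
        hi <- mid
      } else {
        lo <- mid
      }
    }
    n <- hi
  }
  p_n <- power_two_sample_t(n, mean_diff, sd_pct, alpha)
  p_below <- if (n > 2L) power_two_sample_t(n - 1L, mean_diff, sd_pct, alpha) else NA_real_
  stopifnot(p_n >= target_power, is.na(p_below) || p_below < target_power)
  structure(
    list(n_per_arm = n, achieved_power = p_n, power_below = p_below,
         mean_pct = mean_pct, sd_pct = sd_pct,
         reduction_fraction = reduction_fraction, alpha = alpha,
         target_power = target_power),
    class = "sample_size_result"
  )
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf(
    "n per arm = %d (power %.3f at n, %.3f at n-1)\n  detecting a %.0f%% reduction of %.2f %%/yr (SD %.2f), alpha = %.2f\n",
    x$n_per_arm, x$achieved_power,
    ifelse(is.na(x$power_below), NaN, x$power_below),
    100 * x$reduction_fraction, x$mean_pct, x$sd_pct, x$alpha))
  invisible(x)
}

#' Sample-size grid over trial scenarios
#'
#' Builds the scenario-by-metric/ROI/population grid of per-arm sample sizes
#' from a table of group accumulation summaries, one row per combination of
#' trial scenario (defined by a Centiloid stratum filter), quantification
#' metric (SUVR or DVR), composite ROI (cortical or early) and population
#' filter (all subjects or APOE-e4 carriers only).
#'
#' @param group_summaries Data frame with columns `stratum`
#'   (`low`/`intermediate`/`high`/`amyloid_positive`/`whole`), `population`
#'   (`all`/`carriers`), `metric`, `roi`, `mean_pct`, `sd_pct` (and
#'   optionally `n`). Such a table comes from [summarize_group_rates()] over
#'   a fitted cohort, or from a published summary table via
#'   [read_group_summaries()].
#' @param scenarios Data frame with columns `scenario` (name) and `stratum`
#'   (which stratum label of `group_summaries` the scenario draws on);
#'   default the three prevention designs (secondary = amyloid-positive
#'   CL > 20.1, early secondary = intermediate 20.1 < CL <= 49.4, primary =
#'   low CL <= 20.1).
#' @param reduction_fraction,alpha,target_power Passed to
#'   [required_n_per_arm()].
#'
#' @return Data frame: scenario x metric x roi x population with `mean_pct`,
#'   `sd_pct`, `n_per_arm`, `achieved_power`.
#' @export
scenario_table <- function(group_summaries, scenarios = default_scenarios(),
                           reduction_fraction = 0.20, alpha = 0.05,
                           target_power = 0.80) {
  required <- c("stratum", "population", "metric", "roi", "mean_pct", "sd_pct")
  missing_cols <- setdiff(required, names(group_summaries))
  if (length(missing_cols)) {
    stop("group_summaries lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  grid <- expand.grid(
    scenario = scenarios$scenario,
    metric = c("SUVR", "DVR"), roi = c("cortical", "early"),
    population = c("all", "carriers"),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  grid$stratum <- scenarios$stratum[match(grid$scenario, scenarios$scenario)]
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    row <- group_summaries[
      group_summaries$stratum == g$stratum &
        group_summaries$population == g$population &
        group_summaries$metric == g$metric &
        group_summaries$roi == g$roi, , drop = FALSE]
    if (nrow(row) == 0) {
      stop(sprintf(
        "no group summary for scenario '%s' (%s, %s, %s, %s)",
        g$scenario, g$stratum, g$metric, g$roi, g$population))
    }
    res <- required_n_per_arm(row$mean_pct[1], row$sd_pct[1],
                              reduction_fraction, alpha, target_power)
    out[[i]] <- data.frame(
      scenario = g$scenario, stratum = g$stratum, metric = g$metric,
      roi = g$roi, population = g$population,
      mean_pct = row$mean_pct[1], sd_pct = row$sd_pct[1],
      n_per_arm = res$n_per_arm, achieved_power = res$achieved_power,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Default prevention-trial scenarios
#'
#' Secondary prevention enrols all amyloid-positive subjects (CL > 20.1,
#' i.e. the intermediate and high strata pooled at the subject level);
#' early secondary prevention enrols the intermediate stratum
#' (20.1 < CL <= 49.4); primary prevention enrols amyloid-negative subjects
#' (CL <= 20.1).
#'
#' @return Data frame with columns `scenario` and `stratum`.
#' @export
default_scenarios <- function() {
  data.frame(
    scenario = c("secondary", "early_secondary", "primary"),
    stratum = c("amyloid_positive", "intermediate", "low"),
    stringsAsFactors = FALSE
  )
}

#' Power curve over a grid of per-arm sample sizes
#'
#' @param mean_pct,sd_pct,reduction_fraction,alpha As in
#'   [required_n_per_arm()].
#' @param n_grid Increasing integer vector of per-arm sizes.
#'
#' @return Data frame with columns `n_per_arm` and `power`.
#' @export
power_curve <- function(mean_pct, sd_pct, reduction_fraction = 0.20,
                        n_grid = seq(10L, 400L, by = 5L), alpha = 0.05) {
  if (length(n_grid) == 0) stop("n_grid is empty")
  if (is.unsorted(n_grid, strictly = TRUE)) stop("n_grid must be strictly increasing")
  data.frame(
    n_per_arm = n_grid,
    power = power_two_sample_t(n_grid, reduction_fraction * mean_pct, sd_pct, alpha)
  )
}

#' Per-arm n over a sweep of treatment effect sizes
#'
#' @param mean_pct,sd_pct,alpha,target_power As in [required_n_per_arm()].
#' @param reductions Vector of reduction fractions, default 0.2 to 0.8.
#'
#' @return Data frame with columns `reduction_fraction` and `n_per_arm`.
#' @export
effect_size_sweep <- function(mean_pct, sd_pct,
                              reductions = seq(0.2, 0.8, by = 0.1),
                              alpha = 0.05, target_power = 0.80) {
  n <- vapply(reductions, function(r) {
    required_n_per_arm(mean_pct, sd_pct, r, alpha, target_power)$n_per_arm
  }, integer(1))
  data.frame(reduction_fraction = reductions, n_per_arm = n)
}
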