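#' Fit subject-level accumulation slopes by a random-slopes mixed model
#'
#' Fits `value ~ time` with correlated subject-level random intercepts and
#' random slopes by maximum likelihood, and returns the empirical-Bayes
#' (shrunken) per-subject intercepts and slopes together with the
#' annualized % change (100 * slope / intercept). The mixed model accounts
#' for subjects differing in number of scans and follow-up interval. If the
#' mixed fit fails to converge the function falls back to per-subject
#' ordinary least squares, flagged in `fit_method` and announced by a
#' warning.
#'
#' @param observations Long data frame with columns `subject_id`, `time_yr`,
#'   `value` (one metric/ROI at a time; pre-filter with
#'   [filter_observations()]). Each subject needs >= 2 time points.
#' @param min_subjects Minimum subjects for variance-component estimation
#'   (default 2; a single subject is always an error).
#'
#' @return Data frame of class `trajectory_fits`: `subject_id`, `intercept`,
#'   `slope`, `annual_pct_change`, `fit_method`.
#' @export
fit_random_slopes <- function(observations, min_subjects = 2L) {
  req <- c("subject_id", "time_yr", "value")
  if (!all(req %in% names(observations))) {
    stop("observations must have columns ", paste(req, collapse = ", "))
  }
  if (length(unique(paste(observations$metric, observations$roi))) > 1 &&
      all(c("metric", "roi") %in% names(observations))) {
    stop("observations mix multiple metric/ROI series; filter to one first")
  }
  subj <- unique(observations$subject_id)
  if (length(subj) < 2) stop("variance components unidentifiable with a single subject")
  if (length(subj) < min_subjects) stop("need at least ", min_subjects, " subjects")
  counts <- table(observations$subject_id)
  if (any(counts < 2)) {
    stop("every subject needs at least 2 observations; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  if (stats::var(observations$value) == 0 && stats::var(observations$time_yr) == 0) {
    stop("degenerate input: no variation in times or values")
  }

  ols_fits <- function() {
    res <- do.call(rbind, lapply(split(observations, observations$subject_id),
      function(d) {
        cf <- stats::coef(stats::lm(value ~ time_yr, data = d))
        data.frame(subject_id = d$subject_id[1], intercept = unname(cf[1]),
                   slope = unname(cf[2]), stringsAsFactors = FALSE)
      }))
    rownames(res) <- NULL
    res$fit_method <- "ols_fallback"
    res
  }

  fits <- tryCatch({
    mod <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ time_yr + (1 + time_yr | subject_id),
                 data = observations, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    ))
    cf <- stats::coef(mod)$subject_id
    data.frame(subject_id = rownames(cf), intercept = cf[["(Intercept)"]],
               slope = cf[["time_yr"]], fit_method = "lme_blup",
               stringsAsFactors = FALSE)
  }, error = function(e) {
    warning("mixed model failed (", conditionMessage(e),
            "); falling back to per-subject OLS", call. = FALSE)
    ols_fits()
  })

  if (any(fits$intercept <= 0)) {
    stop("non-positive fitted intercept; annualized % change undefined")
  }
  fits$annual_pct_change <- annualize_percent_change(fits$intercept, fits$slope)
  structure(fits[match(sort(as.character(subj)), fits$subject_id), ],
            class = c("trajectory_fits", "data.frame"))
}

#' Annualized percent change from an intercept and slope
#'
#' The accumulation slope normalized to the subject's baseline level:
#' `100 * slope / intercept`, in %/yr.
#'
#' @param intercept Fitted metric value at time 0, > 0.
#' @param slope Fitted metric change per year.
#' @return Annual % change (%/yr), vectorised.
#' @export
annualize_percent_change <- function(intercept, slope) {
  if (any(intercept <= 0)) stop("intercept must be positive")
  100 * slope / intercept
}

#' Filter a long observation table to one metric/ROI series
#' @param observations Long table from [simulate_measurements()] or
#'   [read_metric_table()].
#' @param metric `"SUVR"` or `"DVR"`.
#' @param roi `"cortical"` or `"early"` (matched against the `region`
#'   column).
#' @return The filtered data frame.
#' @export
filter_observations <- function(observations, metric, roi) {
  out <- observations[observations$metric == metric &
                        observations$region == roi, , drop = FALSE]
  if (nrow(out) == 0) stop("no observations for ", metric, " / ", roi)
  out
}

#' Summarize group accumulation rates
#'
#' Sample mean, SD (denominator n - 1) and effect size (mean/SD) of
#' per-subject annualized % change within a burden stratum and population
#' filter.
#'
#' @param fits A [fit_random_slopes()] result.
#' @param profiles Subject table with `subject_id`, `stratum` (or
#'   `stratum_true`) and `apoe4_carrier`.
#' @param stratum One of `"low"`, `"intermediate"`, `"high"`, `"whole"`
#'   (everyone) or `"amyloid_positive"` (intermediate and high pooled,
#'   CL > 20.1).
#' @param population `"all"`, `"carriers"` or `"noncarriers"`.
#'
#' @return One-row data frame: `stratum, population, n, mean_pct, sd_pct,
#'   effect_size`.
#' @export
summarize_group_rates <- function(fits, profiles, stratum = "whole",
                                  population = c("all", "carriers",
                                                 "noncarriers")) {
  population <- match.arg(population)
  strat_col <- if ("stratum" %in% names(profiles)) "stratum" else "stratum_true"
  prof <- profiles
  keep <- switch(stratum,
    whole = rep(TRUE, nrow(prof)),
    amyloid_positive = prof[[strat_col]] %in% c("intermediate", "high"),
    prof[[strat_col]] == stratum)
  if (population == "carriers") keep <- keep & prof$apoe4_carrier
  if (population == "noncarriers") keep <- keep & !prof$apoe4_carrier
  ids <- prof$subject_id[keep]
  x <- fits$annual_pct_change[fits$subject_id %in% ids]
  if (length(x) == 0) stop("empty group: ", stratum, " / ", population)
  if (length(x) < 2) stop("need at least 2 subjects in ", stratum, " / ",
                          population)
  m <- mean(x); s <- stats::sd(x)
  data.frame(stratum = stratum, population = population, n = length(x),
             mean_pct = m, sd_pct = s, effect_size = m / s,
             stringsAsFactors = FALSE)
}

#' Group-rate summaries over all strata and populations for one series
#'
#' @param fits A [fit_random_slopes()] result for one metric/ROI.
#' @param profiles Subject table as in [summarize_group_rates()].
#' @param metric,roi Labels attached to the output rows.
#' @param strata,populations Grids to summarize over.
#' @return Data frame with one row per stratum x population, shaped like a
#'   published group-summary table.
#' @export
summarize_all_groups <- function(fits, profiles, metric, roi,
                                 strata = c("whole", "low", "intermediate",
                                            "high", "amyloid_positive"),
                                 populations = c("all", "carriers")) {
  grid <- expand.grid(stratum = strata, population = populations,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    summarize_group_rates(fits, profiles, grid$stratum[i], grid$population[i])
  }))
  out$metric <- metric
  out$roi <- roi
  out[, c("metric", "roi", "stratum", "population", "n", "mean_pct",
          "sd_pct", "effect_size")]
}
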