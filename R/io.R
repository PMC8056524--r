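#' Write / read the long-format metric table
#'
#' CSV dialect: comma-separated, header row, '.' decimal, UTF-8. Columns:
#' `subject_id, session, time_yr, region, metric, value` with times in
#' years and positive values.
#'
#' @param observations Long observation table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(observations, path) {
  req <- c("subject_id", "session", "time_yr", "region", "metric", "value")
  missing <- setdiff(req, names(observations))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  utils::write.csv(observations[, req], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_metric_table
#' @param path CSV path to read.
#' @return For the reader, the validated observation data frame.
#' @export
read_metric_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("subject_id", "session", "time_yr", "region", "metric", "value")
  missing <- setdiff(req, names(d))
  if (length(missing)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(d$value) | d$value <= 0)
  if (length(bad)) {
    stop("validation error in ", path, ": non-positive or non-numeric value ",
         "at data row(s) ", paste(utils::head(bad, 10), collapse = ", "))
  }
  bad_t <- which(!is.finite(d$time_yr) | d$time_yr < 0)
  if (length(bad_t)) {
    stop("validation error in ", path, ": negative or missing time_yr at ",
         "data row(s) ", paste(utils::head(bad_t, 10), collapse = ", "))
  }
  d
}

#' Read a published group-summary table
#'
#' Reads a CSV of group accumulation summaries (one row per metric x ROI x
#' stratum x population) with columns `metric, roi, stratum, population, n,
#' mean_pct, sd_pct`, the shape produced by [summarize_all_groups()] and the
#' input of the table-only sample-size path. The package ships a
#' transcription of a published summary table as
#' `system.file("extdata", "table1_group_summaries.csv", package =
#' "amytrial")`.
#'
#' @param path CSV path.
#' @return Validated data frame of group summaries.
#' @export
read_group_summaries <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("metric", "roi", "stratum", "population", "n", "mean_pct", "sd_pct")
  missing <- setdiff(req, names(d))
  if (length(missing)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(d$sd_pct) | d$sd_pct <= 0)
  if (length(bad)) {
    stop("validation error in ", path, ": non-positive sd_pct at data row(s) ",
         paste(bad, collapse = ", "))
  }
  d
}

#' Sample-size table directly from published group summaries
#'
#' The table-only path: bypasses simulation entirely and converts a group
#' accumulation summary table into the per-arm sample-size grid for the
#' early-secondary (intermediate stratum) and primary (low stratum)
#' prevention scenarios. The pooled amyloid-positive scenario needs
#' subject-level data and is only included when the summaries contain an
#' `amyloid_positive` stratum.
#'
#' @param group_summaries Data frame from [read_group_summaries()] or
#'   [summarize_all_groups()].
#' @param reduction_fraction,alpha,target_power Passed to
#'   [required_n_per_arm()].
#' @return A [scenario_table()] result.
#' @export
table_only_sample_sizes <- function(group_summaries, reduction_fraction = 0.20,
                                    alpha = 0.05, target_power = 0.80) {
  scen <- default_scenarios()
  if (!"amyloid_positive" %in% group_summaries$stratum) {
    scen <- scen[scen$stratum != "amyloid_positive", ]
  }
  scenario_table(group_summaries, scen, reduction_fraction, alpha, target_power)
}

#' Run the full synthetic analysis pipeline
#'
#' simulate -> fit trajectories -> TRT cutoffs -> accumulators ->
#' associations -> sample sizes, writing a group-summary CSV, a sample-size
#' CSV, a stats JSON and a run manifest (config hash, seed, package
#' version) under `out_dir`. Deterministic given the config seed.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param trt_population Cutoff population for accumulator classification.
#' @return List with `cohort`, `observations`, `fits` (per metric/ROI),
#'   `group_summaries`, `trt`, `accumulators`, `associations`,
#'   `sample_sizes`, invisibly also written to disk.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         trt_population = c("CU_only", "all")) {
  trt_population <- match.arg(trt_population)
  stage <- "simulate"
  result <- tryCatch({
    cohort <- generate_cohort(config)
    obs <- simulate_measurements(cohort, mode = "values")

    stage <- "fit-trajectories"
    series <- expand.grid(metric = c("SUVR", "DVR"),
                          roi = c("cortical", "early"),
                          stringsAsFactors = FALSE)
    fits <- list()
    summaries <- list()
    for (i in seq_len(nrow(series))) {
      key <- paste(series$metric[i], series$roi[i], sep = "_")
      fits[[key]] <- fit_random_slopes(
        filter_observations(obs, series$metric[i], series$roi[i]))
      summaries[[key]] <- summarize_all_groups(
        fits[[key]], cohort$profiles, series$metric[i], series$roi[i])
    }
    group_summaries <- do.call(rbind, summaries)
    rownames(group_summaries) <- NULL

    stage <- "trt"
    pairs <- generate_trt_pairs(noise_targets = config$noise_trt_target,
                                bias_slope_baseline = config$bias_slope_baseline,
                                early_multiplier = config$early_multiplier,
                                seed = config$seed + 2L)
    trt <- do.call(rbind, lapply(seq_len(nrow(series)), function(i) {
      trt_cohort_summary(pairs, series$metric[i], series$roi[i],
                         trt_population)
    }))
    accumulators <- lapply(seq_len(nrow(series)), function(i) {
      key <- paste(series$metric[i], series$roi[i], sep = "_")
      classify_accumulators(fits[[key]], trt$trt_pct[i], cohort$profiles)
    })
    names(accumulators) <- paste(series$metric, series$roi, sep = "_")

    stage <- "associations"
    base_s <- fits$SUVR_cortical
    base_d <- fits$DVR_cortical
    stopifnot(identical(base_s$subject_id, base_d$subject_id))
    associations <- list(
      baseline = bland_altman(base_s$intercept, base_d$intercept, "baseline"),
      annual_pct = bland_altman(base_s$annual_pct_change,
                                base_d$annual_pct_change, "annual_pct"),
      curve = compare_baseline_rate_models(base_d$intercept,
                                           base_d$annual_pct_change),
      covariates = fit_covariate_models(
        data.frame(subject_id = base_d$subject_id,
                   baseline = base_d$intercept),
        base_d, cohort$profiles)
    )

    stage <- "power"
    sample_sizes <- scenario_table(group_summaries)

    list(cohort = cohort, observations = obs, fits = fits,
         group_summaries = group_summaries, trt_pairs = pairs, trt = trt,
         accumulators = accumulators, associations = associations,
         sample_sizes = sample_sizes)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(result$group_summaries,
                     file.path(out_dir, "group_rate_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(result$sample_sizes,
                     file.path(out_dir, "sample_sizes.csv"), row.names = FALSE)
    write_metric_table(result$observations,
                       file.path(out_dir, "observations.csv"))
    stats <- list(
      trt = result$trt,
      accumulator_counts = lapply(result$accumulators, `[[`, "counts"),
      baseline_bland_altman = unclass(result$associations$baseline),
      annual_pct_bland_altman = unclass(result$associations$annual_pct),
      curve_comparison = unclass(result$associations$curve),
      covariate_effects = result$associations$covariates
    )
    jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    manifest <- list(
      config_hash = config_hash(config),
      seed = config$seed,
      n_subjects = config$n_subjects,
      package_version = as.character(utils::packageVersion("amytrial")),
      r_version = R.version.string
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}

#' Stable hash of a configuration object
#'
#' MD5 of the canonical JSON serialisation; identical configurations hash
#' identically across sessions, so a manifest hash identifies a run's
#' inputs.
#'
#' @param config Any JSON-serialisable list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
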