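#' Fit the quadratic rate curve through three (CL, rate) calibration points
#'
#' The mean true annualized % change (DVR scale) is modelled as a quadratic
#' in baseline Centiloid, the inverted-U shape of amyloid accumulation:
#' rates are low in amyloid-negative subjects, peak at intermediate burden,
#' and fall again at high burden as regions saturate.
#'
#' @param cl Length-3 vector of baseline Centiloid abscissae.
#' @param rate_pct Length-3 vector of mean annual % change at those points.
#' @return Named coefficients `c(a, b, c)` of `rate = a*CL^2 + b*CL + c`.
#' @export
fit_rate_curve <- function(cl = c(7, 35, 70), rate_pct = c(0.49, 2.34, 1.55)) {
  if (length(cl) != 3 || length(rate_pct) != 3) stop("need exactly 3 points")
  coef <- solve(cbind(cl^2, cl, 1), rate_pct)
  stats::setNames(as.numeric(coef), c("a", "b", "c"))
}

#' Evaluate a quadratic rate curve
#'
#' Centiloid values are clamped to `cl_range` before evaluation: outside
#' the range spanned by the calibration points the quadratic is pure
#' extrapolation (it turns sharply negative at very high burden), so the
#' curve is held at its boundary values — rates plateau at the highest
#' calibrated burden rather than collapsing.
#'
#' @param cl Centiloid value(s).
#' @param curve Coefficients from [fit_rate_curve()].
#' @param cl_range Calibrated abscissa range; evaluation clamps to it.
#' @return Mean annual % change at `cl`.
#' @export
eval_rate_curve <- function(cl, curve, cl_range = c(0, 70)) {
  cl <- pmin(pmax(cl, cl_range[1]), cl_range[2])
  curve[["a"]] * cl^2 + curve[["b"]] * cl + curve[["c"]]
}

#' Default test-retest variability targets, percent
#'
#' Per-metric/ROI mean relative test-retest difference that the simulated
#' measurement noise is calibrated to induce. Defaults are the cognitively
#' unimpaired test-retest values observed with PIB: DVR is roughly twice as
#' repeatable as SUVR on both composites.
#'
#' @return Named numeric vector over `metric_roi` keys.
#' @export
default_trt_targets <- function() {
  c(DVR_cortical = 0.85, SUVR_cortical = 1.61,
    DVR_early = 2.05, SUVR_early = 3.46)
}

#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defaults emulate the composition of the reference observational cohort:
#' 237 cognitively unimpaired subjects of whom 81.8% have low (CL <= 20.1),
#' 8.44% intermediate (20.1 < CL <= 49.4) and 9.7% high (CL > 49.4) amyloid
#' burden, APOE-e4 carrier fractions of 24.8/75/65.2% per stratum,
#' 2.5 +/- 0.6 scans per subject (range 2-5) and 4.8 +/- 2.1 years between
#' first and last scan.
#'
#' @param n_subjects Number of subjects.
#' @param frac_low,frac_intermediate,frac_high Stratum proportions; must sum
#'   to 1.
#' @param frac_carriers_by_stratum Named proportions of APOE-e4 carriers per
#'   stratum.
#' @param scan_count_mean,scan_count_sd Scans per subject; draws are rounded
#'   and clipped to [2, 5].
#' @param total_span_mean_yr,total_span_sd_yr First-to-last scan interval in
#'   years; draws truncated below at `min_span_yr`.
#' @param min_span_yr Lower truncation for the scan span.
#' @param age_mean,age_sd,age_range Baseline age distribution (years).
#' @param frac_female Proportion of women.
#' @param rate_curve Quadratic coefficients from [fit_rate_curve()] mapping
#'   true baseline CL to mean true annual % change on the DVR scale.
#' @param rate_cl_range Centiloid range over which the rate curve is
#'   calibrated; evaluation clamps to it (see [eval_rate_curve()]).
#' @param rate_sd_by_stratum Named between-subject SD of true annual %
#'   change per stratum (%/yr).
#' @param baseline_meanlog,baseline_sdlog Named per-stratum log-normal
#'   parameters for the specific signal (cortical DVR - 1); samples are
#'   truncated to the stratum's DVR bounds implied by the Centiloid map.
#' @param apoe_meanlog_shift Upward shift of carriers' baseline `meanlog`
#'   within stratum (carriership enters baseline only, not the true rate).
#' @param cl_max Upper Centiloid truncation of the high stratum's baseline
#'   distribution; keeps baselines inside the range where the quadratic
#'   rate curve is calibrated.
#' @param early_multiplier Ratio of early-composite to cortical-composite
#'   specific signal.
#' @param region_multipliers Named per-region multipliers of the cortical
#'   specific signal; cortical members average to 1 so the cortical
#'   composite reproduces the subject's true DVR.
#' @param noise_trt_target Named per-`metric_roi` TRT% targets the
#'   measurement noise is calibrated to; see [default_trt_targets()].
#' @param bias_slope_baseline Proportional SUVR-over-DVR bias of the
#'   specific signal at baseline (default 0.30: SUVR - 1 = 1.3 (DVR - 1)).
#' @param bias_slope_rate Extra proportional inflation of the SUVR drift
#'   component (default 0.15), reproducing the observed overestimation of
#'   accumulation rates by SUVR.
#' @param cl_map [centiloid_map()] used for stratum bounds and CL truth.
#' @param k2 SRTM efferent rate used when emitting kinetic parameters
#'   (1/min).
#' @param seed RNG seed; fixed seed gives byte-identical output.
#'
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 237,
                          frac_low = 0.818, frac_intermediate = 0.0844,
                          frac_high = 0.0976,
                          frac_carriers_by_stratum = c(low = 0.248,
                                                       intermediate = 0.750,
                                                       high = 0.652),
                          scan_count_mean = 2.5, scan_count_sd = 0.6,
                          total_span_mean_yr = 4.8, total_span_sd_yr = 2.1,
                          min_span_yr = 0.5,
                          age_mean = 65.3, age_sd = 9.4, age_range = c(42, 90),
                          frac_female = 0.65,
                          rate_curve = fit_rate_curve(),
                          rate_cl_range = c(0, 70),
                          rate_sd_by_stratum = c(low = 0.96,
                                                 intermediate = 0.72,
                                                 high = 0.93),
                          baseline_meanlog = c(low = log(0.04),
                                               intermediate = log(0.26),
                                               high = log(0.48)),
                          baseline_sdlog = c(low = 0.7, intermediate = 0.25,
                                             high = 0.18),
                          cl_max = 100,
                          apoe_meanlog_shift = 0.25,
                          early_multiplier = 1.3,
                          region_multipliers = NULL,
                          noise_trt_target = default_trt_targets(),
                          bias_slope_baseline = 0.30,
                          bias_slope_rate = 0.15,
                          cl_map = centiloid_map(),
                          k2 = 0.15,
                          seed = 1L) {
  fr <- c(frac_low, frac_intermediate, frac_high)
  if (any(fr < 0) || any(fr > 1)) stop("stratum fractions must lie in [0, 1]")
  fr <- fr / sum(fr)
  if (abs(frac_low + frac_intermediate + frac_high - 1) > 1e-6) {
    stop("stratum fractions must sum to 1")
  }
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (any(frac_carriers_by_stratum < 0 | frac_carriers_by_stratum > 1)) {
    stop("carrier fractions must lie in [0, 1]")
  }
  if (total_span_mean_yr <= 0 || min_span_yr <= 0) stop("spans must be positive")
  if (is.null(region_multipliers)) {
    # cortical members average exactly to 1; early members to early_multiplier
    prec <- 1.24
    region_multipliers <- c(
      frontal = (4 - prec) / 3, parietal = (4 - prec) / 3,
      temporal = (4 - prec) / 3, precuneus = prec,
      isthmus_cingulate = 3 * early_multiplier - prec - 1.30,
      lateral_orbitofrontal = 1.30
    )
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         frac_low = fr[1], frac_intermediate = fr[2], frac_high = fr[3],
         frac_carriers_by_stratum = frac_carriers_by_stratum,
         scan_count_mean = scan_count_mean, scan_count_sd = scan_count_sd,
         total_span_mean_yr = total_span_mean_yr,
         total_span_sd_yr = total_span_sd_yr, min_span_yr = min_span_yr,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         frac_female = frac_female,
         rate_curve = rate_curve, rate_cl_range = rate_cl_range,
         rate_sd_by_stratum = rate_sd_by_stratum,
         baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
         apoe_meanlog_shift = apoe_meanlog_shift, cl_max = cl_max,
         early_multiplier = early_multiplier,
         region_multipliers = region_multipliers,
         noise_trt_target = noise_trt_target,
         bias_slope_baseline = bias_slope_baseline,
         bias_slope_rate = bias_slope_rate,
         cl_map = cl_map, k2 = k2, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# DVR specific-signal bounds of each stratum implied by the Centiloid map
# and the SUVR bias slope (stratification is Centiloid-, i.e. SUVR-, based)
.stratum_specific_bounds <- function(config) {
  b0 <- config$bias_slope_baseline
  s_at <- function(cl) (centiloid_to_suvr(cl, config$cl_map) - 1) / (1 + b0)
  list(low = c(1e-3, s_at(20.1)),
       intermediate = c(s_at(20.1), s_at(49.4)),
       high = c(s_at(49.4), s_at(config$cl_max)))
}

# truncated log-normal via inverse-CDF
.rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' Generate a synthetic longitudinal amyloid-PET cohort
#'
#' Draws subject profiles (age, sex, APOE-e4 carriership, true burden
#' stratum), true trajectories (baseline cortical DVR, per-region baselines,
#' true annual % change from the inverted-U rate curve) and per-subject scan
#' times (first scan at 0, last at the drawn span, interior times uniform).
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort` with data frames `profiles`
#'   (subject_id, age_baseline, sex, apoe4_carrier, stratum_true, cl_true),
#'   `trajectories` (subject_id, dvr0, rate_pct and per-region baseline
#'   columns), and `scan_times` (subject_id, session, time_yr).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects

  strata <- sample(c("low", "intermediate", "high"), n, replace = TRUE,
                   prob = c(config$frac_low, config$frac_intermediate,
                            config$frac_high))
  carrier <- stats::runif(n) < config$frac_carriers_by_stratum[strata]
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$frac_female, "F", "M")

  bounds <- .stratum_specific_bounds(config)
  s <- numeric(n)
  for (st in c("low", "intermediate", "high")) {
    idx <- which(strata == st)
    if (!length(idx)) next
    shift <- ifelse(carrier[idx], config$apoe_meanlog_shift, 0)
    s[idx] <- mapply(function(sh) {
      .rlnorm_trunc(1, config$baseline_meanlog[[st]] + sh,
                    config$baseline_sdlog[[st]],
                    bounds[[st]][1], bounds[[st]][2])
    }, shift)
  }
  dvr0 <- 1 + s
  cl_true <- suvr_to_centiloid(1 + (1 + config$bias_slope_baseline) * s,
                               config$cl_map)
  rate <- eval_rate_curve(cl_true, config$rate_curve, config$rate_cl_range) +
    stats::rnorm(n, 0, config$rate_sd_by_stratum[strata])

  ids <- sprintf("S%04d", seq_len(n))
  profiles <- data.frame(
    subject_id = ids, age_baseline = age, sex = sex,
    apoe4_carrier = carrier, stratum_true = strata, cl_true = cl_true,
    stringsAsFactors = FALSE
  )
  region_base <- outer(s, config$region_multipliers) + 1
  colnames(region_base) <- names(config$region_multipliers)
  trajectories <- data.frame(subject_id = ids, dvr0 = dvr0, rate_pct = rate,
                             region_base, stringsAsFactors = FALSE)

  n_scans <- pmin(pmax(round(stats::rnorm(n, config$scan_count_mean,
                                          config$scan_count_sd)), 2L), 5L)
  span <- pmax(stats::rnorm(n, config$total_span_mean_yr,
                            config$total_span_sd_yr), config$min_span_yr)
  scan_times <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- n_scans[i]
    interior <- if (k > 2) sort(stats::runif(k - 2, 0, span[i])) else numeric(0)
    data.frame(subject_id = ids[i], session = seq_len(k),
               time_yr = c(0, interior, span[i]), stringsAsFactors = FALSE)
  }))

  structure(list(profiles = profiles, trajectories = trajectories,
                 scan_times = scan_times, config = config),
            class = "synthetic_cohort")
}

#' Noise SD inducing a target mean test-retest variability
#'
#' With multiplicative Gaussian noise of SD `sigma` on the specific signal
#' `s = value - 1`, two independent repeats have mean relative test-retest
#' difference (first order) `100 * s/(1+s) * 2 sigma / sqrt(pi)`. This
#' inverts that relation, so that noise calibrated at a subject's own burden
#' level induces the same TRT% at every burden.
#'
#' @param target_pct Target mean TRT%.
#' @param specific_signal True specific signal `value - 1`, > 0.
#' @return Noise SD on the multiplicative specific-signal scale.
#' @export
trt_noise_sigma <- function(target_pct, specific_signal) {
  if (any(specific_signal <= 0)) stop("specific_signal must be positive")
  if (any(target_pct < 0)) stop("target_pct must be non-negative")
  target_pct / 100 * sqrt(pi) / 2 * (1 + specific_signal) / specific_signal
}

# true composite values and SUVR counterpart at time t (vectorised over t)
# DVR_roi(t) = (1 + s_roi)(1 + r t/100); SUVR - 1 = (1 + b0)(DVR - 1) at
# baseline, and the SUVR annual % change is (1 + br) times the DVR one
.true_values <- function(s_roi, rate_pct, t, b0, br) {
  dvr <- (1 + s_roi) * (1 + rate_pct / 100 * t)
  suvr <- (1 + (1 + b0) * s_roi) * (1 + (1 + br) * rate_pct / 100 * t)
  list(DVR = dvr, SUVR = suvr)
}

#' Simulate observed measurements for a synthetic cohort
#'
#' In `"values"` mode, emits one noisy observation per subject, session,
#' composite ROI and metric. The true SUVR specific signal equals
#' `(1 + bias_slope_baseline)` times the true DVR specific signal at
#' baseline, and the true SUVR annual % change is `(1 + bias_slope_rate)`
#' times the DVR one; measurement noise is multiplicative Gaussian on
#' the specific signal, calibrated per metric/ROI so repeated measurements
#' reproduce the configured TRT% targets. In `"kinetic"` mode, emits
#' noiseless per-region SRTM kinetic parameters (`BPND = DVR - 1`) for the
#' quantification layer to turn into time-activity curves.
#'
#' @param cohort A [generate_cohort()] result.
#' @param mode `"values"` or `"kinetic"`.
#' @param noise_scale Multiplier on the calibrated noise SDs (0 disables
#'   noise; 1 is the TRT-calibrated default).
#' @param seed RNG seed for the measurement noise (defaults to
#'   `config$seed + 1`).
#'
#' @return Data frame. Values mode: `subject_id, session, time_yr, region,
#'   metric, value` with `region` in `{cortical, early}`. Kinetic mode:
#'   `subject_id, session, time_yr, region, R1, k2, BPND` per atomic region.
#' @export
simulate_measurements <- function(cohort, mode = c("values", "kinetic"),
                                  noise_scale = 1, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  mode <- match.arg(mode)
  config <- cohort$config
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)

  traj <- cohort$trajectories
  st <- cohort$scan_times
  i <- match(st$subject_id, traj$subject_id)

  if (mode == "kinetic") {
    regions <- names(config$region_multipliers)
    out <- do.call(rbind, lapply(regions, function(rg) {
      s_rg <- (traj[[rg]] - 1)[i]
      dvr_t <- (1 + s_rg) * (1 + traj$rate_pct[i] / 100 * st$time_yr)
      data.frame(subject_id = st$subject_id, session = st$session,
                 time_yr = st$time_yr, region = rg,
                 R1 = 1, k2 = config$k2, BPND = pmax(dvr_t - 1, 0),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out[order(out$subject_id, out$session, out$region), ])
  }

  b0 <- config$bias_slope_baseline
  br <- config$bias_slope_rate
  roi_mult <- c(cortical = 1, early = config$early_multiplier)
  out <- list()
  for (roi in names(roi_mult)) {
    s_roi <- (traj$dvr0[i] - 1) * roi_mult[[roi]]
    truth <- .true_values(s_roi, traj$rate_pct[i], st$time_yr, b0, br)
    for (metric in c("DVR", "SUVR")) {
      tv <- truth[[metric]]
      key <- paste(metric, roi, sep = "_")
      target <- config$noise_trt_target[[key]]
      if (is.null(target)) stop("no noise_trt_target for ", key)
      # noise SD calibrated at |specific signal|, so the absolute noise stays
      # ~ target/100 * sqrt(pi)/2 * (1 + |s|) even for values near (or below) 1
      s_abs <- pmax(abs(tv - 1), 1e-6)
      obs <- tv + noise_scale * s_abs * trt_noise_sigma(target, s_abs) *
        stats::rnorm(length(tv))
      out[[key]] <- data.frame(
        subject_id = st$subject_id, session = st$session,
        time_yr = st$time_yr, region = roi, metric = metric, value = obs,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject_id, res$session, res$region, res$metric), ]
}

#' Generate a synthetic test-retest pair set
#'
#' Emulates a small single-site test-retest dataset: each subject has one
#' latent cortical DVR (cognitively unimpaired subjects drawn from a
#' low-burden distribution, impaired subjects from a higher one), the early
#' composite and SUVR values follow the bias model, and test and retest
#' values are the latent truth under two independent draws of the
#' TRT-calibrated multiplicative noise.
#'
#' @param n_cu Number of cognitively unimpaired subjects (default 4).
#' @param n_impaired Number of impaired subjects (default 7; the first is
#'   labelled MCI, the rest AD).
#' @param noise_targets Named per-`metric_roi` TRT% targets; see
#'   [default_trt_targets()].
#' @param bias_slope_baseline SUVR-over-DVR bias of the specific signal.
#' @param early_multiplier Early-to-cortical specific-signal ratio.
#' @param seed RNG seed.
#'
#' @return Data frame of class `trt_pair_set`: `subject_id, diagnosis,
#'   metric, roi, value_test, value_retest`.
#' @export
generate_trt_pairs <- function(n_cu = 4, n_impaired = 7,
                               noise_targets = default_trt_targets(),
                               bias_slope_baseline = 0.30,
                               early_multiplier = 1.3, seed = 1L) {
  if (n_cu < 0 || n_impaired < 0) stop("subject counts must be non-negative")
  n <- n_cu + n_impaired
  if (n == 0) stop("need at least one subject")
  set.seed(seed)
  s_latent <- c(stats::rlnorm(n_cu, log(0.04), 0.5),
                stats::rlnorm(n_impaired, log(0.45), 0.3))
  diagnosis <- c(rep("CU", n_cu),
                 if (n_impaired > 0) c("MCI", rep("AD", max(n_impaired - 1, 0))))
  ids <- sprintf("T%02d", seq_len(n))
  out <- list()
  for (roi in c("cortical", "early")) {
    mult <- if (roi == "early") early_multiplier else 1
    for (metric in c("DVR", "SUVR")) {
      s_roi <- s_latent * mult
      truth <- if (metric == "SUVR") 1 + (1 + bias_slope_baseline) * s_roi
               else 1 + s_roi
      key <- paste(metric, roi, sep = "_")
      target <- noise_targets[[key]]
      if (is.null(target)) stop("no noise target for ", key)
      sigma <- trt_noise_sigma(target, truth - 1)
      test <- 1 + (truth - 1) * (1 + stats::rnorm(n, 0, sigma))
      retest <- 1 + (truth - 1) * (1 + stats::rnorm(n, 0, sigma))
      out[[key]] <- data.frame(
        subject_id = ids, diagnosis = diagnosis, metric = metric, roi = roi,
        value_test = test, value_retest = retest, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res[order(res$subject_id, res$metric, res$roi), ],
            class = c("trt_pair_set", "data.frame"))
}
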