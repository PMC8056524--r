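test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(frac_low = 0.9, frac_intermediate = 0.4,
                             frac_high = 0.2), "sum to 1")
  expect_error(cohort_config(n_subjects = 1), "at least 2")
  expect_error(cohort_config(frac_carriers_by_stratum = c(low = 1.2,
                                                          intermediate = 0.5,
                                                          high = 0.5)),
               "carrier fractions")
})

test_that("degenerate stratum fractions and determinism behave as declared", {
  cfg <- cohort_config(n_subjects = 50, frac_low = 1, frac_intermediate = 0,
                       frac_high = 0, seed = 11)
  co <- generate_cohort(cfg)
  expect_true(all(co$profiles$stratum_true == "low"))
  expect_equal(nrow(co$profiles), 50)

  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)
  obs <- simulate_measurements(co, "values")
  obs2 <- simulate_measurements(co2, "values")
  expect_identical(obs, obs2)
})

test_that("default cohort matches the target composition", {
  co <- generate_cohort(cohort_config(seed = 5))
  counts <- table(factor(co$profiles$stratum_true,
                         c("low", "intermediate", "high")))
  # binomial 3-sigma bands around (194, 20, 23) of 237
  for (i in seq_along(counts)) {
    p <- c(0.818, 0.0844, 0.0976)[i]
    expect_lt(abs(counts[i] - 237 * p), 3 * sqrt(237 * p * (1 - p)) + 1)
  }
  # scans per subject within [2, 5], first scan at 0, times increasing
  st <- split(co$scan_times$time_yr, co$scan_times$subject_id)
  expect_true(all(lengths(st) >= 2 & lengths(st) <= 5))
  expect_true(all(vapply(st, function(t) t[1] == 0 && !is.unsorted(t, strictly = TRUE),
                         logical(1))))
  # stratum label consistent with the true Centiloid value
  expect_identical(classify_burden_stratum(co$profiles$cl_true),
                   co$profiles$stratum_true)
})

test_that("carriers have higher true baselines and the rate curve peaks at intermediate burden", {
  co <- generate_cohort(cohort_config(n_subjects = 2000, seed = 8))
  low <- co$profiles$stratum_true == "low"
  expect_gt(mean(co$trajectories$dvr0[low & co$profiles$apoe4_carrier]),
            mean(co$trajectories$dvr0[low & !co$profiles$apoe4_carrier]))
  rate_by <- tapply(co$trajectories$rate_pct, co$profiles$stratum_true, mean)
  expect_gt(rate_by[["intermediate"]], rate_by[["low"]])
  expect_gt(rate_by[["intermediate"]], rate_by[["high"]])
})

test_that("rate curve interpolates its calibration points and clamps extrapolation", {
  curve <- fit_rate_curve()
  expect_equal(eval_rate_curve(c(7, 35, 70), curve), c(0.49, 2.34, 1.55),
               tolerance = 1e-10)
  expect_equal(eval_rate_curve(120, curve), eval_rate_curve(70, curve))
})

test_that("noiseless measurements follow the bias model exactly", {
  cfg <- cohort_config(n_subjects = 40, seed = 9)
  co <- generate_cohort(cfg)
  obs <- simulate_measurements(co, "values", noise_scale = 0)
  base <- obs[obs$session == 1 & obs$region == "cortical", ]
  dvr <- base$value[base$metric == "DVR"]
  suvr <- base$value[base$metric == "SUVR"]
  # SUVR - 1 = 1.3 (DVR - 1) at baseline: a true DVR of 1.20 maps to 1.26
  expect_equal(suvr - 1, 1.3 * (dvr - 1), tolerance = 1e-12)
  i <- match(base$subject_id[base$metric == "DVR"],
             co$trajectories$subject_id)
  expect_equal(dvr, co$trajectories$dvr0[i], tolerance = 1e-12)

  # per-subject observed annual % change equals the true rate without noise
  d <- filter_observations(obs, "DVR", "cortical")
  pct <- vapply(split(d, d$subject_id), function(s) {
    cf <- stats::coef(stats::lm(value ~ time_yr, data = s))
    100 * cf[[2]] / cf[[1]]
  }, numeric(1))
  truth <- co$trajectories$rate_pct[match(names(pct),
                                          co$trajectories$subject_id)]
  expect_equal(unname(pct), truth, tolerance = 1e-8)
})

test_that("kinetic mode emits SRTM parameters consistent with the regional truth", {
  cfg <- cohort_config(n_subjects = 10, seed = 12)
  co <- generate_cohort(cfg)
  kin <- simulate_measurements(co, "kinetic")
  expect_setequal(unique(kin$region), names(cfg$region_multipliers))
  first <- kin[kin$session == 1 & kin$region == "precuneus", ]
  i <- match(first$subject_id, co$trajectories$subject_id)
  expect_equal(first$BPND, co$trajectories$precuneus[i] - 1, tolerance = 1e-12)
  expect_true(all(kin$BPND >= 0) && all(kin$k2 == cfg$k2))
})

test_that("measurement noise reproduces the configured TRT targets", {
  pairs <- generate_trt_pairs(n_cu = 6000, n_impaired = 6000, seed = 21)
  targets <- default_trt_targets()
  for (key in names(targets)) {
    parts <- strsplit(key, "_")[[1]]
    got <- trt_cohort_summary(pairs, parts[1], parts[2], "all")$trt_pct
    expect_lt(abs(got - targets[[key]]) / targets[[key]], 0.20)
  }
})

test_that("realized TRT increases monotonically with the configured target", {
  realized <- vapply(c(0.85, 2, 5), function(tg) {
    pairs <- generate_trt_pairs(
      n_cu = 2000, n_impaired = 2000, seed = 3,
      noise_targets = c(DVR_cortical = tg, SUVR_cortical = 1.61,
                        DVR_early = 2.05, SUVR_early = 3.46))
    trt_cohort_summary(pairs, "DVR", "cortical", "all")$trt_pct
  }, numeric(1))
  expect_true(all(diff(realized) > 0))
})

test_that("test-retest pair sets have the declared shape and noise ordering", {
  pairs <- generate_trt_pairs(n_cu = 4, n_impaired = 7, seed = 2)
  expect_equal(length(unique(pairs$subject_id)), 11)
  expect_equal(nrow(pairs), 44)  # 11 subjects x 2 metrics x 2 ROIs
  expect_equal(sum(pairs$diagnosis == "CU") / 4, 4)
  expect_true(all(pairs$value_test > 0 & pairs$value_retest > 0))
  # impaired latent burden higher than CU
  cu <- pairs$metric == "DVR" & pairs$roi == "cortical" &
    pairs$diagnosis == "CU"
  imp <- pairs$metric == "DVR" & pairs$roi == "cortical" &
    pairs$diagnosis != "CU"
  expect_gt(mean(pairs$value_test[imp]), mean(pairs$value_test[cu]))

  silent <- generate_trt_pairs(4, 7, noise_targets = c(
    DVR_cortical = 0, SUVR_cortical = 0, DVR_early = 0, SUVR_early = 0))
  expect_true(all(trt_percent(silent$value_test, silent$value_retest) == 0))
  expect_error(generate_trt_pairs(-1, 5), "non-negative")

  # larger SUVR noise target -> larger cohort SUVR TRT than DVR TRT
  big <- generate_trt_pairs(n_cu = 500, n_impaired = 500, seed = 4)
  expect_gt(trt_cohort_summary(big, "SUVR", "cortical", "all")$trt_pct,
            trt_cohort_summary(big, "DVR", "cortical", "all")$trt_pct)
})
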