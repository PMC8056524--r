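test_that("Bland-Altman degenerates correctly for identical metrics", {
  x <- c(1.0, 1.2, 1.4, 1.6)
  fit <- bland_altman(x, x)
  expect_equal(fit$mean_bias, 0)
  expect_equal(fit$bias_slope, 0)
  expect_equal(fit$correlation, 1)
})

test_that("Bland-Altman recovers the proportional bias of the generator", {
  co <- generate_cohort(cohort_config(n_subjects = 300, seed = 17))
  s <- co$trajectories$dvr0 - 1
  dvr <- 1 + s
  suvr <- 1 + 1.3 * s
  fit <- bland_altman(suvr, dvr, level = "baseline")
  # diff = 0.3 s, mean = 1 + 1.15 s -> slope 0.3/1.15 of the raw mean; on
  # the specific-signal scale the bias slope is the configured 0.30
  fit_specific <- bland_altman(suvr - 1, dvr - 1, level = "baseline")
  expect_equal(fit_specific$bias_slope, 0.3 / 1.15, tolerance = 1e-10)
  expect_gt(fit$correlation, 0.999)
  expect_equal(stats::coef(stats::lm(I(suvr - dvr) ~ s))[[2]], 0.30,
               tolerance = 1e-10)
})

test_that("Bland-Altman is antisymmetric and handles anti-monotone pairs", {
  a <- c(1, 2, 3); b <- c(3, 2, 1)
  fit <- bland_altman(a, b, level = "annual_pct")
  expect_equal(fit$correlation, -1)
  swapped <- bland_altman(b, a, level = "annual_pct")
  expect_equal(swapped$mean_bias, -fit$mean_bias)
  expect_equal(swapped$bias_slope, -fit$bias_slope)
  expect_error(bland_altman(1:4, 1:3), "equal length")
})

test_that("paired-test choice follows the normality screen", {
  set.seed(23)
  normal_diff <- bland_altman(stats::rnorm(80, 1.3, 0.05) + 0.02,
                              stats::rnorm(80, 1.3, 0.05), "annual_pct")
  expect_identical(normal_diff$paired_test, "paired_t")
  base <- stats::rnorm(80, 1.3, 0.02)
  skewed <- base + stats::rexp(80, 2)^3
  skew_fit <- bland_altman(skewed, base, "annual_pct")
  expect_identical(skew_fit$paired_test, "wilcoxon_signed_rank")
  expect_true(normal_diff$paired_test_p >= 0 && normal_diff$paired_test_p <= 1)
})

test_that("AIC selects the quadratic for inverted-U data and the linear for nested noiseless fits", {
  set.seed(41)
  x <- stats::runif(200, 0, 3)
  y <- -x^2 + 3 * x + stats::rnorm(200, 0, 0.1)
  cmp <- compare_baseline_rate_models(x, y)
  expect_identical(cmp$selected_model, "quadratic")
  expect_true(all(cmp$delta_aic < 0))

  y_lin <- 2 * x + 1
  cmp_lin <- compare_baseline_rate_models(x, y_lin)
  expect_identical(cmp_lin$selected_model, "linear")

  expect_error(compare_baseline_rate_models(x[1:5], y[1:5]), "at least 10")
  expect_error(compare_baseline_rate_models(rep(1, 20), y[1:20]),
               "rank-deficient")
})

test_that("AIC ranking is invariant to affine rescaling of the predictor", {
  set.seed(3)
  x <- stats::runif(150, 0, 2)
  y <- 0.5 * x^2 - x + stats::rnorm(150, 0, 0.2)
  c1 <- compare_baseline_rate_models(x, y)
  c2 <- compare_baseline_rate_models(10 * x + 3, y)
  expect_identical(c1$selected_model, c2$selected_model)
  expect_equal(c1$delta_aic, c2$delta_aic, tolerance = 1e-6)
})

test_that("covariate models recover a known APOE baseline shift", {
  set.seed(19)
  n <- 500
  prof <- data.frame(
    subject_id = sprintf("s%03d", 1:n),
    age_baseline = stats::rnorm(n, 65, 9),
    sex = sample(c("F", "M"), n, replace = TRUE),
    apoe4_carrier = stats::runif(n) < 0.3)
  baseline <- 1.1 + 0.1 * prof$apoe4_carrier + stats::rnorm(n, 0, 0.05)
  fits <- data.frame(subject_id = prof$subject_id,
                     annual_pct_change = stats::rnorm(n, 1, 1))
  eff <- fit_covariate_models(
    data.frame(subject_id = prof$subject_id, baseline = baseline),
    fits, prof)
  apoe <- eff[eff$outcome == "baseline" & eff$term == "apoe4", ]
  expect_lt(abs(apoe$beta - 0.1), 0.02)
  expect_lt(apoe$p_value, 0.001)
  expect_true("baseline_adjustment" %in% eff$term[eff$outcome == "rate"])
})

test_that("constant covariates are dropped with a warning", {
  n <- 40
  prof <- data.frame(subject_id = sprintf("s%02d", 1:n),
                     age_baseline = stats::rnorm(n, 65, 5),
                     sex = "M",
                     apoe4_carrier = stats::runif(n) < 0.5)
  fits <- data.frame(subject_id = prof$subject_id,
                     annual_pct_change = stats::rnorm(n))
  w <- testthat::capture_warnings(
    eff <- fit_covariate_models(
      data.frame(subject_id = prof$subject_id,
                 baseline = stats::rnorm(n, 1.2, 0.1)),
      fits, prof))
  expect_true(any(grepl("sexM", w)))  # dropped in both outcome models
  expect_false("sex" %in% eff$term)
})

test_that("null covariates reject at the nominal rate", {
  n <- 80
  rejections <- vapply(1:200, function(seed) {
    set.seed(seed)
    prof <- data.frame(subject_id = sprintf("s%02d", 1:n),
                       age_baseline = stats::rnorm(n, 65, 9),
                       sex = sample(c("F", "M"), n, replace = TRUE),
                       apoe4_carrier = stats::runif(n) < 0.4)
    fits <- data.frame(subject_id = prof$subject_id,
                       annual_pct_change = stats::rnorm(n, 1, 1))
    eff <- fit_covariate_models(
      data.frame(subject_id = prof$subject_id,
                 baseline = stats::rnorm(n, 1.2, 0.1)),
      fits, prof)
    eff$p_value[eff$outcome == "rate" & eff$term == "apoe4"] < 0.05
  }, logical(1))
  # binomial 99% band around 5% of 200
  expect_lt(abs(mean(rejections) - 0.05), 2.58 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})
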