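#' Bland-Altman comparison of SUVR against DVR
#'
#' Regresses the paired difference (SUVR - DVR) on the pair mean by ordinary
#' least squares; the slope quantifies proportional bias (how much the SUVR
#' overestimation grows per unit of underlying burden or accumulation).
#' Also reports the correlation between the two metrics (Spearman's rho at
#' the baseline level, following the convention for skewed baseline burden;
#' Pearson's r for annual % change) and a paired test of the mean
#' difference: a paired t-test when the differences pass a Shapiro-Wilk
#' normality screen at alpha = 0.05, a Wilcoxon signed-rank test otherwise.
#'
#' @param suvr,dvr Paired values of the two metrics (same subjects, same
#'   order).
#' @param level `"baseline"` (burden values) or `"annual_pct"` (rates);
#'   selects the correlation type.
#'
#' @return List of class `bland_altman_fit`: `mean_bias`, `bias_slope`,
#'   `intercept`, `correlation`, `correlation_type`, `paired_test`,
#'   `paired_test_p`, `n`.
#' @export
bland_altman <- function(suvr, dvr, level = c("baseline", "annual_pct")) {
  level <- match.arg(level)
  if (length(suvr) != length(dvr)) stop("paired vectors must have equal length")
  if (length(suvr) < 3) stop("need at least 3 pairs")
  diff <- suvr - dvr
  avg <- (suvr + dvr) / 2
  if (stats::sd(avg) < 1e-12) {
    slope <- 0; intercept <- mean(diff)
  } else {
    cf <- stats::coef(stats::lm(diff ~ avg))
    intercept <- unname(cf[1]); slope <- unname(cf[2])
  }
  cor_type <- if (level == "baseline") "spearman" else "pearson"
  correlation <- if (stats::sd(suvr) < 1e-12 || stats::sd(dvr) < 1e-12) NA_real_
                 else stats::cor(suvr, dvr, method = cor_type)
  if (stats::sd(diff) < 1e-12) {
    test_used <- "none"; p <- if (abs(mean(diff)) < 1e-12) 1 else 0
  } else {
    sw_p <- tryCatch(stats::shapiro.test(diff)$p.value, error = function(e) 0)
    if (sw_p > 0.05) {
      test_used <- "paired_t"
      p <- stats::t.test(suvr, dvr, paired = TRUE)$p.value
    } else {
      test_used <- "wilcoxon_signed_rank"
      p <- suppressWarnings(stats::wilcox.test(suvr, dvr, paired = TRUE)$p.value)
    }
  }
  structure(list(mean_bias = mean(diff), bias_slope = slope,
                 intercept = intercept, correlation = correlation,
                 correlation_type = cor_type, paired_test = test_used,
                 paired_test_p = p, n = length(suvr)),
            class = "bland_altman_fit")
}

#' Compare baseline-vs-rate curve shapes by AIC
#'
#' Fits the relationship between baseline amyloid burden and annualized %
#' change with three fixed-effect models — linear, quadratic, and a natural
#' cubic spline with one interior knot at the baseline median — by least
#' squares, and compares them by AIC (Gaussian likelihood, 2k - 2logL).
#' `delta_aic` is reported relative to the quadratic model (AIC_quadratic -
#' AIC_competitor), so negative values mean the quadratic is preferred. An
#' inverted-U accumulation pattern selects the quadratic.
#'
#' @param baseline Baseline metric values.
#' @param annual_pct Annualized % change values, same subjects.
#'
#' @return List of class `curve_model_comparison`: per-model `r_squared` and
#'   `aic`, `selected_model` (minimal AIC; ties go to fewer parameters),
#'   `delta_aic` (named, vs quadratic).
#' @export
compare_baseline_rate_models <- function(baseline, annual_pct) {
  if (length(baseline) != length(annual_pct)) stop("length mismatch")
  if (length(baseline) < 10) stop("need at least 10 points")
  if (stats::sd(baseline) < 1e-12) stop("rank-deficient design: constant baseline")
  d <- data.frame(x = baseline, y = annual_pct)
  models <- list(
    linear = stats::lm(y ~ x, data = d),
    quadratic = stats::lm(y ~ x + I(x^2), data = d),
    natural_cubic_spline_1knot = stats::lm(
      y ~ splines::ns(x, knots = stats::median(x),
                      Boundary.knots = range(x)), data = d)
  )
  aic <- vapply(models, stats::AIC, numeric(1))
  r2 <- vapply(models, function(m) {
    suppressWarnings(summary(m)$r.squared)  # degenerate perfect fits warn
  }, numeric(1))
  k <- vapply(models, function(m) length(stats::coef(m)), numeric(1))
  # minimal AIC; break near-ties (within 1e-6, e.g. exactly nested noiseless
  # fits) in favour of fewer parameters
  ord <- order(aic + 1e-6 * k)
  selected <- names(models)[ord[1]]
  structure(list(
    r_squared = r2, aic = aic, selected_model = selected,
    delta_aic = aic[["quadratic"]] - aic[setdiff(names(aic), "quadratic")]
  ), class = "curve_model_comparison")
}

#' Covariate effects on baseline burden and accumulation rate
#'
#' Baseline outcome: a general linear model of baseline amyloid burden on
#' age, sex and APOE-e4 carriership. Rate outcome: a baseline-adjusted
#' linear model of the per-subject (empirical-Bayes) annualized % change on
#' the same covariates plus baseline burden. Constant covariates are
#' dropped with a warning.
#'
#' @param baselines Data frame `subject_id, baseline` (metric units).
#' @param fits A [fit_random_slopes()] result.
#' @param profiles Subject table with `subject_id, age_baseline, sex,
#'   apoe4_carrier`.
#'
#' @return Data frame of class `covariate_effects`: `outcome, term, beta,
#'   t_stat, p_value`.
#' @export
fit_covariate_models <- function(baselines, fits, profiles) {
  need <- c("subject_id", "age_baseline", "sex", "apoe4_carrier")
  if (!all(need %in% names(profiles))) {
    stop("profiles must have columns ", paste(need, collapse = ", "))
  }
  d <- merge(merge(baselines, fits[, c("subject_id", "annual_pct_change")],
                   by = "subject_id"),
             profiles[, need], by = "subject_id")
  if (anyNA(d)) stop("covariates incomplete for some subjects")
  d$sexM <- as.integer(d$sex == "M")
  d$apoe4 <- as.integer(d$apoe4_carrier)

  usable <- function(terms) {
    const <- terms[vapply(terms, function(v) stats::var(d[[v]]) == 0, logical(1))]
    if (length(const)) {
      warning("constant covariate(s) dropped: ", paste(const, collapse = ", "),
              call. = FALSE)
    }
    setdiff(terms, const)
  }
  tidy <- function(model, outcome) {
    sm <- summary(model)$coefficients
    sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
    data.frame(outcome = outcome, term = rownames(sm), beta = sm[, 1],
               t_stat = sm[, 3], p_value = sm[, 4],
               row.names = NULL, stringsAsFactors = FALSE)
  }

  base_terms <- usable(c("age_baseline", "sexM", "apoe4"))
  if (!length(base_terms)) stop("no usable covariates for the baseline model")
  m_base <- stats::lm(stats::reformulate(base_terms, "baseline"), data = d)

  rate_terms <- usable(c("age_baseline", "sexM", "apoe4", "baseline"))
  m_rate <- stats::lm(stats::reformulate(rate_terms, "annual_pct_change"),
                      data = d)

  out <- rbind(tidy(m_base, "baseline"), tidy(m_rate, "rate"))
  out$term <- sub("^sexM$", "sex", sub("^apoe4$", "apoe4", sub(
    "^age_baseline$", "age", sub("^baseline$", "baseline_adjustment", out$term))))
  structure(out, class = c("covariate_effects", "data.frame"))
}
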