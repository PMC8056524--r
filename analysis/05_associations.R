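#!/usr/bin/env Rscript
# Step 5: metric agreement, curve shape, and covariate effects.
#
# Bland-Altman comparison of SUVR against DVR at baseline and for annualized
# % change; AIC comparison of linear / quadratic / natural-spline models of
# the baseline-burden vs accumulation-rate relationship (the inverted-U);
# and covariate models for age, sex and APOE-e4 on baseline and rate.

suppressPackageStartupMessages(library(amytrial))

fits <- read.csv("results/subject_fits.csv")
profiles <- read.csv("results/cohort_profiles.csv")

dvr <- fits[fits$metric == "DVR" & fits$roi == "cortical", ]
suvr <- fits[fits$metric == "SUVR" & fits$roi == "cortical", ]
suvr <- suvr[match(dvr$subject_id, suvr$subject_id), ]

ba_base <- bland_altman(suvr$intercept, dvr$intercept, level = "baseline")
ba_rate <- bland_altman(suvr$annual_pct_change, dvr$annual_pct_change,
                        level = "annual_pct")
cat(sprintf("Baseline:   mean bias %.3f, proportional-bias slope %.3f, %s rho/r %.3f (%s, p=%.2g)\n",
            ba_base$mean_bias, ba_base$bias_slope, ba_base$correlation_type,
            ba_base$correlation, ba_base$paired_test, ba_base$paired_test_p))
cat(sprintf("Annual %%:   mean bias %.3f, proportional-bias slope %.3f, r %.3f (%s, p=%.2g)\n",
            ba_rate$mean_bias, ba_rate$bias_slope, ba_rate$correlation,
            ba_rate$paired_test, ba_rate$paired_test_p))

cmp <- compare_baseline_rate_models(dvr$intercept, dvr$annual_pct_change)
cat("\nBaseline-vs-rate curve selected by AIC:", cmp$selected_model, "\n")
print(round(cmp$delta_aic, 2))

eff <- fit_covariate_models(
  data.frame(subject_id = dvr$subject_id, baseline = dvr$intercept),
  dvr, profiles)
print(eff, digits = 3)

jsonlite::write_json(
  list(ba_baseline = unclass(ba_base), ba_rate = unclass(ba_rate),
       curve_comparison = lapply(unclass(cmp), as.list),
       covariate_effects = eff),
  "results/associations.json", auto_unbox = TRUE, digits = 6)
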