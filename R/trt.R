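#' Relative test-retest variability, percent
#'
#' The percent absolute difference between a test and a retest measurement,
#' normalized to their mean:
#' \deqn{TRT(\%) = \frac{|T - R|}{0.5\,|T + R|} \cdot 100.}
#' Symmetric in its arguments and invariant to a common positive rescaling.
#'
#' @param value_test,value_retest Test and retest values (vectorised).
#' @return TRT in percent, >= 0.
#' @export
#' @examples
#' trt_percent(1.05, 0.95)  # 10
trt_percent <- function(value_test, value_retest) {
  s <- value_test + value_retest
  if (any(s == 0)) stop("test + retest must be non-zero")
  abs(value_test - value_retest) / (0.5 * abs(s)) * 100
}

#' Cohort test-retest summary per metric and ROI
#'
#' Mean of the per-subject TRT% values for one metric/ROI, over either the
#' cognitively unimpaired subjects only (the default cutoff population) or
#' all diagnostic groups.
#'
#' @param pairs A [generate_trt_pairs()]-shaped table: `subject_id,
#'   diagnosis, metric, roi, value_test, value_retest`.
#' @param metric,roi Which series to summarize.
#' @param population `"CU_only"` or `"all"`.
#'
#' @return One-row data frame: `metric, roi, population, n, trt_pct`.
#' @export
trt_cohort_summary <- function(pairs, metric, roi,
                               population = c("CU_only", "all")) {
  population <- match.arg(population)
  sel <- pairs$metric == metric & pairs$roi == roi
  if (population == "CU_only") sel <- sel & pairs$diagnosis == "CU"
  d <- pairs[sel, , drop = FALSE]
  if (nrow(d) == 0) stop("no test-retest pairs after filtering (", metric,
                         ", ", roi, ", ", population, ")")
  data.frame(metric = metric, roi = roi, population = population,
             n = nrow(d),
             trt_pct = mean(trt_percent(d$value_test, d$value_retest)),
             stringsAsFactors = FALSE)
}

#' Classify accumulators against a test-retest cutoff
#'
#' A subject is an accumulator when their annualized % change strictly
#' exceeds the TRT% cutoff for the same metric/ROI (ties are
#' non-accumulators). When `profiles` is supplied, per-stratum counts and
#' percentages are also returned.
#'
#' @param fits A [fit_random_slopes()] result (needs `subject_id` and
#'   `annual_pct_change`).
#' @param cutoff_pct TRT% cutoff, >= 0 (typically `trt_pct` from
#'   [trt_cohort_summary()] on the cognitively unimpaired subjects).
#' @param profiles Optional subject table with `subject_id` and `stratum`
#'   (or `stratum_true`).
#'
#' @return List with `calls` (per-subject data frame with `is_accumulator`)
#'   and, when `profiles` is given, `counts` (per-stratum n, accumulators,
#'   percentage).
#' @export
classify_accumulators <- function(fits, cutoff_pct, profiles = NULL) {
  if (is.null(fits) || nrow(fits) == 0) stop("no trajectory fits supplied")
  if (!is.finite(cutoff_pct) || cutoff_pct < 0) stop("cutoff_pct must be >= 0")
  calls <- data.frame(
    subject_id = fits$subject_id,
    annual_pct_change = fits$annual_pct_change,
    cutoff_pct = cutoff_pct,
    is_accumulator = fits$annual_pct_change > cutoff_pct,
    stringsAsFactors = FALSE
  )
  out <- list(calls = calls)
  if (!is.null(profiles)) {
    strat_col <- if ("stratum" %in% names(profiles)) "stratum" else "stratum_true"
    calls$stratum <- profiles[[strat_col]][match(calls$subject_id,
                                                 profiles$subject_id)]
    counts <- do.call(rbind, lapply(
      c("low", "intermediate", "high", "whole"), function(st) {
        d <- if (st == "whole") calls else calls[calls$stratum == st, ]
        data.frame(stratum = st, n = nrow(d),
                   n_accumulators = sum(d$is_accumulator),
                   pct_accumulators = if (nrow(d)) 100 * mean(d$is_accumulator)
                                      else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    out$counts <- counts
  }
  out
}

#' Subjects called accumulator by one metric but not another
#'
#' The discordant set: accumulator under the reference metric (typically
#' DVR, the more repeatable one) but not under the comparison metric
#' (typically SUVR).
#'
#' @param calls_ref,calls_other `calls` data frames from
#'   [classify_accumulators()] for the two metrics, same subjects.
#' @return Character vector of discordant subject ids.
#' @export
discordant_accumulators <- function(calls_ref, calls_other) {
  i <- match(calls_ref$subject_id, calls_other$subject_id)
  if (any(is.na(i))) stop("subject sets differ between the two call sets")
  calls_ref$subject_id[calls_ref$is_accumulator & !calls_other$is_accumulator[i]]
}
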