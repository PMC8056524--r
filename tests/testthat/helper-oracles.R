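# Independent oracles used across tests.

# SRTM target curve by brute-force discrete convolution on a fine grid,
# independent of the closed-form route inside simulate_srtm_tac().
srtm_numeric_oracle <- function(ref_params, kin, schedule, dt = 0.002) {
  tmax <- max(schedule$frame_end)
  grid <- seq(0, tmax, by = dt)
  cr <- ref_params$A * (exp(-ref_params$lambda1 * grid) -
                          exp(-ref_params$lambda2 * grid))
  decay <- exp(-kin$k2a * grid)
  conv <- dt * stats::convolve(cr, rev(decay), type = "open")[seq_along(grid)]
  ct <- kin$R1 * cr + (kin$k2 - kin$R1 * kin$k2a) * conv
  vapply(seq_len(nrow(schedule)), function(i) {
    sel <- grid >= schedule$frame_start[i] & grid <= schedule$frame_end[i]
    mean(ct[sel])
  }, numeric(1))
}

# Monte-Carlo power of the two-sided two-sample t-test.
mc_power_two_sample_t <- function(n, mean_diff, sd, alpha = 0.05,
                                  reps = 1e5) {
  x <- matrix(stats::rnorm(n * reps, mean_diff, sd), nrow = n)
  y <- matrix(stats::rnorm(n * reps, 0, sd), nrow = n)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- (colSums(x^2) - n * mx^2) / (n - 1)
  vy <- (colSums(y^2) - n * my^2) / (n - 1)
  sp <- sqrt((vx + vy) / 2)
  tstat <- (mx - my) / (sp * sqrt(2 / n))
  mean(abs(tstat) > stats::qt(1 - alpha / 2, 2 * n - 2))
}

# small noiseless longitudinal table with known per-subject lines
make_linear_series <- function(intercepts, slopes, times = c(0, 2, 4)) {
  do.call(rbind, lapply(seq_along(intercepts), function(i) {
    data.frame(subject_id = sprintf("S%02d", i), time_yr = times,
               value = intercepts[i] + slopes[i] * times,
               stringsAsFactors = FALSE)
  }))
}
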