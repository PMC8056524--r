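#!/usr/bin/env Rscript
# Step 2: dynamic vs static quantification on simulated tracer kinetics.
#
# Simulates SRTM target-region time-activity curves over a bi-exponential
# reference curve across a grid of binding potentials, then quantifies each
# with the reference Logan graphical method (DVR, t* = 30 min) and the
# static 30-60 min uptake ratio (SUVR). Demonstrates that DVR recovers
# 1 + BP_ND nearly unbiasedly while SUVR overshoots, increasingly so at
# higher burden.

suppressPackageStartupMessages(library(amytrial))

sched <- extend_schedule(frame_schedule(), until_min = 90)
ref <- simulate_reference_tac(sched)

grid <- expand.grid(BPND = c(0, 0.25, 0.5, 0.75, 1.0, 1.5),
                    k2 = c(0.10, 0.15, 0.20))
grid$dvr <- NA_real_
grid$suvr <- NA_real_
for (i in seq_len(nrow(grid))) {
  tgt <- simulate_srtm_tac(ref, kinetic_params(R1 = 1, k2 = grid$k2[i],
                                               BPND = grid$BPND[i]))
  grid$dvr[i] <- compute_rlogan_dvr(tgt, ref, t_star = 30,
                                    k2_ref = grid$k2[i])$dvr
  grid$suvr[i] <- compute_suvr(tgt, ref)
}
grid$true_dvr <- 1 + grid$BPND
grid$dvr_bias_pct <- 100 * (grid$dvr / grid$true_dvr - 1)
grid$suvr_overshoot <- grid$suvr - grid$dvr

dir.create("results", showWarnings = FALSE)
write.csv(grid, "results/kinetics_grid.csv", row.names = FALSE)
print(grid, digits = 4)
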