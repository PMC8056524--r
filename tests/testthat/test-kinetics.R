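test_that("reference TAC is a frame-averaged bi-exponential with an early peak", {
  sch <- frame_schedule()
  expect_equal(max(sch$frame_end), 60)
  expect_true(all(diff(sch$frame_start) > 0))

  zero <- simulate_reference_tac(sch, A = 0)
  expect_true(all(zero$activity == 0))

  ref <- simulate_reference_tac(sch)
  ref2 <- simulate_reference_tac(sch, A = 200)
  expect_equal(ref2$activity, 2 * ref$activity, tolerance = 1e-12)

  # argmax frame mid-time before the closed-form peak bound of 10 min
  peak_t <- log(0.6 / 0.03) / (0.6 - 0.03)
  expect_lt(peak_t, 10)
  expect_lt(sch$frame_mid[which.max(ref$activity)], 10)

  expect_error(simulate_reference_tac(sch, lambda1 = 0.6, lambda2 = 0.3),
               "lambda2")
})

test_that("SRTM with identity kinetics returns the reference", {
  ref <- simulate_reference_tac()
  tgt <- simulate_srtm_tac(ref, kinetic_params(R1 = 1, k2 = 0.15, BPND = 0))
  expect_lt(max(abs(tgt$activity - ref$activity) / pmax(ref$activity, 1e-9)),
            1e-6)
  expect_error(kinetic_params(k2 = -0.1), "k2")
  expect_error(kinetic_params(BPND = -0.2), "BPND")
})

test_that("binding raises late-frame activity and R1=0 gives a pure convolution term", {
  ref <- simulate_reference_tac()
  t0 <- simulate_srtm_tac(ref, kinetic_params(BPND = 0))
  t5 <- simulate_srtm_tac(ref, kinetic_params(BPND = 0.5))
  late <- ref$schedule$frame_mid >= 30
  expect_true(all(t5$activity[late] > t0$activity[late]))

  conv_only <- simulate_srtm_tac(ref, structure(
    list(R1 = 1e-12, k2 = 0.15, BPND = 0.5, k2a = 0.1), class = "kinetic_params"))
  expect_lt(conv_only$activity[1] / max(conv_only$activity), 0.02)
})

test_that("closed-form SRTM matches an independent discrete-convolution oracle", {
  sch <- frame_schedule()
  ref <- simulate_reference_tac(sch)
  for (bp in c(0.25, 1.0)) {
    kin <- kinetic_params(R1 = 0.9, k2 = 0.15, BPND = bp)
    got <- simulate_srtm_tac(ref, kin)$activity
    oracle <- srtm_numeric_oracle(ref$params, kin, sch)
    expect_lt(max(abs(got - oracle)) / max(oracle), 0.01)
  }
})

test_that("SUVR is a windowed ratio with the expected algebra", {
  ref <- simulate_reference_tac()
  expect_equal(compute_suvr(ref, ref), 1.0, tolerance = 1e-12)
  doubled <- tac(ref$schedule, 2 * ref$activity)
  expect_equal(compute_suvr(doubled, ref), 2.0, tolerance = 1e-12)
  expect_error(compute_suvr(ref, ref, window = c(300, 400)), "window")
  tgt <- simulate_srtm_tac(ref, kinetic_params(R1 = 1, k2 = 0.15, BPND = 0.5))
  # transient overshoot: the 30-60 min static ratio exceeds equilibrium DVR
  expect_gt(compute_suvr(tgt, ref), 1.5)
})

test_that("reference Logan recovers DVR on noiseless SRTM data", {
  sch <- extend_schedule(frame_schedule(), until_min = 90)
  ref <- simulate_reference_tac(sch)
  expect_equal(compute_rlogan_dvr(ref, ref)$dvr, 1.0, tolerance = 1e-6)
  scaled <- tac(sch, 1.7 * ref$activity)
  expect_equal(compute_rlogan_dvr(scaled, ref)$dvr, 1.7, tolerance = 1e-6)

  for (bp in c(0, 0.25, 0.5, 1.0)) {
    tgt <- simulate_srtm_tac(ref, kinetic_params(R1 = 1, k2 = 0.15, BPND = bp))
    dvr <- compute_rlogan_dvr(tgt, ref, t_star = 30, k2_ref = 0.15)$dvr
    tol <- if (bp == 0) 1e-6 else 0.03
    expect_equal(dvr, 1 + bp, tolerance = tol)
  }
  expect_error(compute_rlogan_dvr(ref, ref, t_star = 89), "3 frames")
})

test_that("SUVR and Logan DVR are invariant to a common global rescaling", {
  sch <- extend_schedule(frame_schedule(), until_min = 90)
  ref <- simulate_reference_tac(sch)
  tgt <- simulate_srtm_tac(ref, kinetic_params(BPND = 0.6))
  c_ref <- tac(sch, 3.2 * ref$activity)
  c_tgt <- tac(sch, 3.2 * tgt$activity)
  expect_equal(compute_suvr(c_tgt, c_ref), compute_suvr(tgt, ref),
               tolerance = 1e-10)
  expect_equal(compute_rlogan_dvr(c_tgt, c_ref)$dvr,
               compute_rlogan_dvr(tgt, ref)$dvr, tolerance = 1e-10)
})

test_that("Logan DVR increases with BPND and SUVR overestimates it for PIB-like kinetics", {
  sch <- extend_schedule(frame_schedule(), until_min = 90)
  ref <- simulate_reference_tac(sch)
  for (k2 in c(0.1, 0.15, 0.2)) {
    dvrs <- suvrs <- numeric(0)
    for (bp in seq(0, 1.5, by = 0.25)) {
      tgt <- simulate_srtm_tac(ref, kinetic_params(R1 = 1, k2 = k2, BPND = bp))
      dvrs <- c(dvrs, compute_rlogan_dvr(tgt, ref, k2_ref = k2)$dvr)
      suvrs <- c(suvrs, compute_suvr(tgt, ref))
    }
    expect_true(all(diff(dvrs) > 0))
    expect_true(all(suvrs >= dvrs - 1e-9))
    # the static-window bias grows with the underlying burden
    expect_true(all(diff(suvrs - dvrs) > 0))
  }
})

test_that("composite aggregation is a normalized weighted mean", {
  comp <- composite_definition("cortical")
  vals <- c(frontal = 1.2, parietal = 1.2, temporal = 1.2, precuneus = 1.2)
  expect_equal(aggregate_composite(vals, comp), 1.2)
  two <- composite_definition("ab", regions = c(a = 0.25, b = 0.75))
  expect_equal(aggregate_composite(c(a = 1, b = 2), two), 1.75)
  expect_equal(aggregate_composite(c(b = 2, a = 1), two), 1.75)
  expect_error(aggregate_composite(c(frontal = 1), comp), "precuneus")
  early <- composite_definition("early")
  expect_setequal(names(early$weights),
                  c("isthmus_cingulate", "precuneus", "lateral_orbitofrontal"))
})

test_that("Centiloid map is the anchored affine transform", {
  map <- centiloid_map(1.01, 1.90)
  expect_equal(suvr_to_centiloid(1.01, map), 0)
  expect_equal(suvr_to_centiloid(1.90, map), 100)
  expect_equal(suvr_to_centiloid(1.4555, map), 50.05618, tolerance = 1e-5)
  expect_equal(centiloid_to_suvr(suvr_to_centiloid(1.234, map), map), 1.234)
  expect_error(centiloid_map(1.9, 1.0), "exceed")
})

test_that("burden strata partition the Centiloid axis with boundaries in the lower stratum", {
  expect_identical(classify_burden_stratum(20.1), "low")
  expect_identical(classify_burden_stratum(49.4), "intermediate")
  expect_identical(classify_burden_stratum(49.41), "high")
  expect_identical(classify_burden_stratum(-5), "low")
  grid <- seq(-20, 120, by = 0.37)
  strata <- classify_burden_stratum(grid)
  expect_true(all(strata %in% c("low", "intermediate", "high")))
  expect_error(classify_burden_stratum(NaN), "finite")
})
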