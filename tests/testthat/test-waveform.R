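test_that("jump template has the right peak, flight and impulse structure", {
  cfg <- sim_config()
  f <- synthesize_jump_waveform(0.73, 0.55, 120, cfg)
  expect_length(f, round(60 / 120 * cfg$fs_force_acc))
  # landing peak within one-sample interpolation error
  expect_lt(abs(max(f) - 0.73), 1e-3)
  expect_true(all(f >= 0))
  # every flight sample is far below the 10% contact threshold
  land_start <- attr(f, "landing_start")
  n_seg <- aquagrf:::jump_segment_samples(120, cfg)
  flight <- f[(land_start - n_seg[["flight"]]):(land_start - 1L)]
  expect_true(all(flight < 0.1 * 0.55))
  # mean force over the period is a plausible sub-body-weight impulse
  expect_gt(mean(f), 0)
  expect_lt(mean(f), 1)
})

test_that("template rejects undetectable or out-of-range inputs", {
  expect_error(synthesize_jump_waveform(0.4, 0.55, 120, sim_config()),
               "undetectable")
  expect_error(synthesize_jump_waveform(0.7, 0.55, 30, sim_config()),
               "cadence")
  expect_error(synthesize_jump_waveform(0.7, 1.2, 120, sim_config()),
               "apparent_weight")
})

test_that("sessions honour the jump-count contract and are reproducible", {
  s <- generate_subject(seed = 5)
  ses <- generate_session(s, short_protocol(n_jumps = 9), sim_config(),
                          seed = 6)
  expect_equal(nrow(ses$jumps), 9)
  ses2 <- generate_session(s, short_protocol(n_jumps = 9), sim_config(),
                           seed = 6)
  expect_identical(ses$force_n, ses2$force_n)
  expect_identical(ses$acc, ses2$acc)
  expect_identical(ses$hr, ses2$hr)
  expect_error(session_protocol(labels = character(0)), "at least one phase")
})

test_that("noiseless acceleration peaks sit exactly on the linear link", {
  cfg <- noiseless_config()
  s <- generate_subject(seed = 5)
  ses <- generate_session(s, short_protocol(n_jumps = 7), cfg, seed = 8)
  lk <- cfg$acc_link$c7
  expect_equal(ses$jumps$peak_acc_c7,
               lk[["alpha0"]] + lk[["alpha1"]] * ses$jumps$peak_grf_bw,
               tolerance = 1e-12)
  # and the extracted peaks match within discretisation + filter error
  rec <- process_session(ses)
  expect_lt(max(abs(rec$c7acc - ses$jumps$peak_acc_c7)), 1.5e-3)
  expect_lt(max(abs(rec$grf_v_l_bw - ses$jumps$peak_grf_bw)), 1e-3)
})

test_that("cohort marginals match the per-intensity anchors", {
  co <- generate_cohort(2, seed = 21)
  j <- co$jumps
  # mean peak C7 resultant in the 80% phase ~ 1.61 g within 3 SE
  a80 <- j$peak_acc_c7[j$phase == "80"]
  expect_gte(length(a80), 90)
  expect_lt(abs(mean(a80) - 1.61), 3 * 0.125 / sqrt(length(a80)))
  # mean peak GRF strictly increases over intensity
  m <- tapply(j$peak_grf_bw, j$phase, mean)[c("50", "65", "80")]
  expect_true(all(diff(m) > 0))
  # wear-position ordering of mean peak resultants: L5 < C7 < TA
  expect_lt(mean(j$peak_acc_l5), mean(j$peak_acc_c7))
  expect_lt(mean(j$peak_acc_c7), mean(j$peak_acc_ta))
})

test_that("cohort size and determinism contracts hold", {
  co1 <- generate_cohort(3, seed = 31)
  co2 <- generate_cohort(3, seed = 31)
  expect_identical(co1$jumps, co2$jumps)
  # ~132 jumps per subject under default jump-number distributions
  expect_lt(abs(nrow(co1$jumps) - 3 * 132), 0.10 * 3 * 132)
  # single subject, one 5-jump phase
  co <- generate_cohort(1, seed = 32, protocol = short_protocol(n_jumps = 5))
  expect_equal(nrow(co$jumps), 5)
  expect_error(generate_cohort(0), ">= 1")
})
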