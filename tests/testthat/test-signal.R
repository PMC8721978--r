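test_that("zero-phase Butterworth honours the analytic magnitude response", {
  # DC gain 1
  x <- rep(3, 600)
  y <- lowpass_filter(x, fs = 1000)
  expect_lt(max(abs(y - 3)), 1e-9 * 3)
  # 5 Hz tone in the passband: squared 6th-order response at 5/50 is
  # 1/(1 + 0.1^12) ~ 1, so the amplitude is retained within 1%
  t <- (0:3999) / 1000
  y5 <- lowpass_filter(sin(2 * pi * 5 * t), fs = 1000)
  amp5 <- max(abs(y5[1000:3000]))
  expect_lt(abs(amp5 - 1 / (1 + (5 / 50)^12)), 0.01)
  # 200 Hz tone in the stopband: analytic attenuation (200/50)^-12 ~ 6e-8
  y200 <- lowpass_filter(sin(2 * pi * 200 * t), fs = 1000)
  expect_lt(max(abs(y200[1000:3000])), 1e-3)
})

test_that("filter rejects invalid sampling setups", {
  expect_error(lowpass_filter(rnorm(100), fs = 90, cutoff = 50), "Nyquist")
  expect_error(lowpass_filter(rnorm(10), fs = 1000), "too short")
})

test_that("resultant acceleration is the per-sample Euclidean norm", {
  expect_equal(resultant_acceleration(0, 0, 1), 1)
  expect_equal(resultant_acceleration(3, 4, 0), 5)
  set.seed(3)
  ax <- rnorm(200); ay <- rnorm(200); az <- rnorm(200)
  loop <- vapply(seq_along(ax),
                 function(i) sqrt(ax[i]^2 + ay[i]^2 + az[i]^2), numeric(1))
  expect_equal(resultant_acceleration(ax, ay, az), loop, tolerance = 1e-12)
  expect_equal(resultant_acceleration(cbind(ax, ay, az)), loop,
               tolerance = 1e-12)
  expect_error(resultant_acceleration(1:3, 1:2, 1:3), "equal lengths")
})

test_that("filtering each axis before the norm differs from the reverse order", {
  # the norm is nonlinear, so the two orders of operation disagree; the
  # pipeline fixes filter-then-resultant
  t <- (0:1999) / 1000
  ax <- sin(2 * pi * 30 * t); ay <- cos(2 * pi * 30 * t); az <- rep(1, 2000)
  filt_first <- resultant_acceleration(
    lowpass_filter(ax, 1000), lowpass_filter(ay, 1000),
    lowpass_filter(az, 1000))
  res_first <- lowpass_filter(resultant_acceleration(ax, ay, az), 1000)
  expect_gt(max(abs(filt_first - res_first)), 1e-6)
})

test_that("water body weight is the quiet-standing mean force", {
  expect_equal(water_body_weight(rep(300, 2000), c(1, 1000)), 300)
  # noiseless simulated subject: (1 - buoyancy) * mass * g0
  cfg <- noiseless_config()
  s <- generate_subject(seed = 4)
  ses <- generate_session(s, short_protocol(), cfg, seed = 4)
  wbw <- water_body_weight(ses$force_n, c(200, 1700))
  truth <- (1 - s$buoyancy_fraction) * s$mass_land * 9.80665
  expect_equal(wbw, truth, tolerance = 1e-6)
  # noisy mean obeys the CLT bound
  set.seed(9)
  noisy <- 300 + rnorm(5000, 0, 10)
  expect_lt(abs(water_body_weight(noisy, c(1, 5000)) - 300),
            3 * 10 / sqrt(5000))
  expect_error(water_body_weight(rep(300, 100), c(1, 100)), "at least 0.5")
})

test_that("contact segmentation recovers constructed pulses exactly", {
  f <- rep(0, 3000)
  f[201:500] <- 100   # three 300 ms pulses, 200 ms apart
  f[701:1000] <- 120
  f[1201:1500] <- 90
  ev <- segment_contacts(f, wbw = 300, fs = 1000)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$start_index, c(201, 701, 1201))
  expect_equal(ev$end_index, c(500, 1000, 1500))
  expect_true(all(ev$preceded_by_flight))
  expect_equal(ev$peak_force, c(100, 120, 90))
  # an all-zero trace yields no contacts
  expect_equal(nrow(segment_contacts(rep(0, 1000), 300)), 0)
  expect_error(segment_contacts(f, wbw = 0), "positive")
})

test_that("a simulated session yields one landing per jump, stance excluded", {
  s <- generate_subject(seed = 14)
  ses <- generate_session(s, short_protocol(n_jumps = 5), seed = 15)
  f <- lowpass_filter(ses$force_n, ses$fs)
  wbw <- water_body_weight(f, c(200, 1700))
  ev <- segment_contacts(f, wbw)
  expect_equal(sum(ev$preceded_by_flight), 5)
  expect_false(ev$preceded_by_flight[1])  # initial stance
})

test_that("GRF normalisation is linear and uses land body weight", {
  expect_equal(normalize_grf(53.1 * 9.80665, 53.1), 1)
  expect_equal(normalize_grf(0, 53.1), 0)
  expect_equal(round(normalize_grf(380.2, 53.1), 3), 0.730)
  f <- runif(10, 0, 700)
  expect_equal(normalize_grf(3.7 * f, 60), 3.7 * normalize_grf(f, 60))
  expect_error(normalize_grf(100, 0), "positive")
})

test_that("extracted features match simulator ground truth and geometry", {
  cfg <- noiseless_config()
  s <- generate_subject(seed = 16)
  ses <- generate_session(s, short_protocol(n_jumps = 6), cfg, seed = 17)
  rec <- process_session(ses)
  expect_equal(nrow(rec), 6)
  expect_lt(max(abs(rec$grf_v_l_bw - ses$jumps$peak_grf_bw)), 1e-3)
  expect_equal(rec$pwdh, rep(pwdh(s), 6))
  expect_equal(rec$age, rep(s$age, 6))
  expect_equal(rec$weight, rep(s$mass_land, 6))
  # peak indices lie inside their contact intervals
  expect_true(all(rec$peak_force_index >= rec$start_index &
                    rec$peak_force_index <= rec$end_index))
  expect_error(extract_jump_features(rep(1, 10), NULL,
                                     data.frame(start_index = 1,
                                                end_index = 20,
                                                preceded_by_flight = TRUE),
                                     s), "outside trace")
})

test_that("segmentation count equals ground truth across seeds and noise", {
  for (noise in c(0, 0.004)) {
    for (seed in 1:4) {
      cfg <- sim_config(force_noise_sd_bw = noise)
      s <- generate_subject(seed = seed)
      ses <- generate_session(s, short_protocol(n_jumps = 6), cfg,
                              seed = 100 + seed)
      rec <- process_session(ses)
      expect_equal(nrow(rec), 6)
    }
  }
})
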