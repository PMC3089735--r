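test_that("make_schedule produces the balanced jittered design", {
  cfg <- sim_config(seed = 2)
  sched <- make_schedule(cfg)
  expect_equal(nrow(sched), 60)
  expect_true(all(table(sched$duration_ms, sched$movement) == 15))
  expect_true(all(diff(sched$onset_s) > 0))
  # same seed twice: identical schedules
  expect_identical(sched, make_schedule(sim_config(seed = 2)))
  # different seed: different order
  expect_false(identical(sched$duration_ms,
                         make_schedule(sim_config(seed = 3))$duration_ms))
  # configs whose truncation floor dips below 13 s are rejected
  expect_error(sim_config(iti_mean_s = 16, iti_sd_s = 2), "13 s")
  expect_error(sim_config(iti_mean_s = 12), "13 s")
})

test_that("realized ITI matches the truncated-normal mean (Monte Carlo)", {
  # oracle: mean of N(19.2, 2.9) truncated below at mu - 2 sigma
  z <- -2
  trunc_mean <- 19.2 + 2.9 * stats::dnorm(z) / (1 - stats::pnorm(z))
  itis <- unlist(lapply(1:100, function(s) {
    diff(make_schedule(sim_config(seed = s, n_per_condition = 2L))$onset_s)
  }))
  se <- sd(itis) / sqrt(length(itis))
  expect_lt(abs(mean(itis) - trunc_mean), 3 * se)
  expect_true(all(itis >= 19.2 - 2 * 2.9))
})

test_that("epochs can never overlap: 1000-seed onset-spacing sweep", {
  min_gap <- min(vapply(1:1000, function(s) {
    min(diff(make_schedule(sim_config(seed = s, n_per_condition = 2L))$onset_s))
  }, numeric(1)))
  expect_gt(min_gap, 12.5)
})

test_that("simulate_pressure injects gamma transients on movement trials only", {
  # zero transient amplitudes + integer samples-per-beat: exactly periodic
  cfg0 <- sim_config(seed = 4, n_per_condition = 2L,
                     bp_transient_amplitude_mmHg = c(sbp = 0, dbp = 0),
                     heart_rate_bpm = 75, fs_bp_hz = 200)  # 160 samples/beat
  sched0 <- make_schedule(cfg0)
  sim0 <- simulate_pressure(sched0, cfg0)
  beats0 <- detect_beats(sim0$recording)
  expect_equal(max(abs(diff(beats0$sbp_mmHg))), 0)
  expect_equal(max(abs(diff(beats0$dbp_mmHg))), 0)
  # beat count over a segment follows the heart rate analytically
  in60 <- sum(beats0$systolic_time_s <= 60)
  expect_true(abs(in60 - 75) <= 1)
  # ground truth records the injected values per trial
  cfg <- sim_config(seed = 4, n_per_condition = 2L)
  sched <- make_schedule(cfg)
  sim <- simulate_pressure(sched, cfg)
  gt <- sim$truth$per_trial
  expect_equal(gt$sbp_amplitude_mmHg[gt$movement], rep(7.8, 4))
  expect_equal(gt$sbp_amplitude_mmHg[!gt$movement], rep(0, 4))
  expect_equal(gt$sbp_peak_s[gt$movement], rep(5.8, 4))
  # MAP deviation envelope is zero away from movement trials
  dev <- sim$truth$map_deviation_mmHg
  tn <- sim$truth$map_time_s
  pre <- tn < min(sched$onset_s[sched$movement])
  expect_lt(max(abs(dev[pre])), 1e-9)
  expect_gt(max(dev), 3)  # transient clearly present
  expect_error(simulate_pressure(sched, sim_config(fs_bp_hz = 10)), "25")
})

test_that("simulate_nirs builds the stated deep/shallow physiology", {
  cfg <- sim_config(seed = 6, n_per_condition = 2L)
  sched <- make_schedule(cfg)
  dev <- simulate_map_deviation(sched, cfg)$map_deviation_mmHg
  # null physiology: no HRF, no coupling, no noise/pulsation -> drift only,
  # and inversion + detrend returns ~0 chromophores
  cfg0 <- sim_config(seed = 6, n_per_condition = 2L,
                     hrf_amplitude_uM = list(o2hb = c("1500" = 0, "3000" = 0),
                                             hhb = c("1500" = 0, "3000" = 0)),
                     coupling_gain_deep_o2hb = 0, coupling_gain_deep_hhb = 0,
                     noise_sd_uM = 0, pulsation_amp_uM = 0)
  out0 <- simulate_nirs(sched, dev * 0, cfg0, "deep")
  conc0 <- od_to_conc(out0$raw)
  resid <- detrend_poly(conc0$conc$ch1_o2hb, 5)
  expect_lt(max(abs(resid)), 1e-8)
  # shallow noiseless: detrended O2Hb is an exact multiple of MAP deviation
  cfgS <- sim_config(seed = 6, n_per_condition = 2L, noise_sd_uM = 0,
                     pulsation_amp_uM = 0, drift_poly_coeffs = 0)
  outS <- simulate_nirs(sched, dev, cfgS, "shallow")
  concS <- od_to_conc(outS$raw)
  expect_gt(stats::cor(detrend_poly(concS$conc$ch1_o2hb), detrend_poly(dev)),
            0.99)
  # geometry follows the mode
  expect_equal(simulate_nirs(sched, dev, cfg, "deep")$raw$geometry$separation_cm, 4)
  expect_equal(outS$raw$geometry$separation_cm, 1)
  expect_error(simulate_nirs(sched, dev, cfg, "medium"))
  expect_error(simulate_nirs(sched, dev[-1], cfg, "deep"), "samples")
})

test_that("noise-free generation is conservative through the optical round trip", {
  cfg <- sim_config(seed = 8, n_per_condition = 2L, noise_sd_uM = 0)
  sched <- make_schedule(cfg)
  dev <- simulate_map_deviation(sched, cfg)$map_deviation_mmHg
  out <- simulate_nirs(sched, dev, cfg, "deep")
  back <- od_to_conc(out$raw)
  expect_lt(max(abs(back$conc$ch1_o2hb - out$conc_truth$conc$ch1_o2hb)), 1e-9)
  expect_lt(max(abs(back$conc$ch1_hhb - out$conc_truth$conc$ch1_hhb)), 1e-9)
})

test_that("identical configs give byte-identical CSV exports", {
  d1 <- file.path(tempdir(), "sess_a")
  d2 <- file.path(tempdir(), "sess_b")
  write_session(simulate_session(small_config()), d1)
  write_session(simulate_session(small_config()), d2)
  h1 <- dir_hashes(d1); h2 <- dir_hashes(d2)
  expect_equal(unname(h1), unname(h2))
  expect_true(length(h1) >= 5)
})
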