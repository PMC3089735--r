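# build a clean pulsatile waveform from the generator's template
template_wave <- function(hr_bpm = 70, dur_s = 60, fs = 200,
                          sbp = 120, dbp = 80) {
  t <- seq(0, dur_s, by = 1 / fs)
  per <- 60 / hr_bpm
  p <- dbp + (sbp - dbp) * nirsbp:::beat_shape(t %% per, per)
  pressure_recording(t, p)
}

test_that("detect_beats recovers count and template extrema on clean input", {
  rec <- template_wave(70, 60)
  beats <- detect_beats(rec)
  # 70 bpm x 60 s = 70 systolic peaks; complete beats drop one edge
  expect_true(abs((nrow(beats) + 1) - 70) <= 1)
  # SBP/DBP equal the template extrema to within one-sample discretization
  per <- 60 / 70
  one_sample_drop <- (120 - 80) *
    (1 - nirsbp:::beat_shape(0.08 - 1 / rec$fs_hz, per))
  expect_lt(max(abs(beats$sbp_mmHg - 120)), one_sample_drop + 1e-9)
  expect_lt(max(abs(beats$dbp_mmHg - 80)),
            (120 - 80) * nirsbp:::beat_shape(0.08 + (per - 0.08) -
                                              1 / rec$fs_hz, per) + 0.5)
  expect_true(all(diff(beats$systolic_time_s) > 0))
  expect_error(detect_beats(pressure_recording(0:99 / 200, rep(100, 100))),
               "fewer than 2")
})

test_that("a dicrotic bump inside the refractory window is not counted", {
  fs <- 200; per <- 1.0
  t <- seq(0, 30, by = 1 / fs)
  ph <- t %% per
  main <- exp(-((ph - 0.2) / 0.05)^2)      # systolic peak at 0.2 s
  bump <- 0.5 * exp(-((ph - 0.35) / 0.04)^2)  # dicrotic bump 0.15 s later
  p <- 80 + 40 * (main + bump)
  rec <- pressure_recording(t, p)
  beats <- detect_beats(rec, refractory_s = 0.3, prominence_mmHg = 5)
  # one systolic peak per 1 s period; 30 periods -> 29 complete beats
  expect_true(abs(nrow(beats) - 29) <= 1)
  # all detected peaks are the main peak, not the bump
  expect_true(all(abs(beats$systolic_time_s %% per - 0.2) < 0.05))
  # without the refractory period the bump would be counted (and the
  # resulting sub-physiological inter-beat intervals flagged)
  expect_warning(
    beats2 <- detect_beats(rec, refractory_s = 0.05, prominence_mmHg = 5),
    "inter-beat")
  expect_gt(nrow(beats2), 1.5 * nrow(beats))
})

test_that("map_from_beats implements both MAP definitions", {
  # constant-pressure limit: SBP = DBP = MAP for both methods
  rec <- template_wave(70, 30, sbp = 100 + 1e-9, dbp = 100)
  beats <- detect_beats(rec, prominence_mmHg = 0)
  for (m in c("waveform_mean", "onethird")) {
    b <- map_from_beats(beats, rec, method = m)
    expect_lt(max(abs(b$sbp_mmHg - 100)), 1e-6)
    expect_lt(max(abs(b$map_mmHg - 100)), 1e-6)
  }
  # onethird arithmetic: 120/80 -> 93.33
  fake <- structure(data.frame(systolic_time_s = c(1, 2),
                               sbp_mmHg = c(120, 120),
                               diastolic_time_s = c(1.5, 2.5),
                               dbp_mmHg = c(80, 80),
                               map_mmHg = NA_real_),
                    class = c("beat_series", "data.frame"))
  b3 <- map_from_beats(fake, method = "onethird")
  expect_equal(b3$map_mmHg, c(280 / 3, 280 / 3), tolerance = 1e-12)
  expect_error(map_from_beats(fake, method = "median"))
  # waveform_mean equals the numeric integral of the template over a period
  rec2 <- template_wave(60, 30)   # per = 1 s
  beats2 <- map_from_beats(detect_beats(rec2), rec2, method = "waveform_mean")
  ph <- seq(0, 1, length.out = 100001)[-100001]
  oracle <- 80 + 40 * mean(nirsbp:::beat_shape(ph, 1))
  expect_lt(max(abs(beats2$map_mmHg - oracle)), 0.05)
  # the ordering invariant on this clean series
  expect_true(all(beats2$dbp_mmHg <= beats2$map_mmHg + 1e-9 &
                  beats2$map_mmHg <= beats2$sbp_mmHg + 1e-9))
})

test_that("beats_to_continuous interpolates linearly through beat values", {
  fake <- structure(data.frame(systolic_time_s = c(1, 2, 3),
                               sbp_mmHg = c(100, 110, 110),
                               diastolic_time_s = c(1.4, 2.4, 3.4),
                               dbp_mmHg = c(70, 72, 74),
                               map_mmHg = c(80, 84, 88)),
                    class = c("beat_series", "data.frame"))
  cont <- beats_to_continuous(fake, fs_out_hz = 10, t_range = c(0, 4))
  at <- function(v, tt) v[which.min(abs(cont$time_s - tt))]
  # values at beat times reproduce beat values
  expect_equal(at(cont$sbp_mmHg, 2), 110)
  expect_equal(at(cont$dbp_mmHg, 2.4), 72, tolerance = 1e-12)
  # midpoint between 100 and 110 -> 105
  expect_equal(at(cont$sbp_mmHg, 1.5), 105)
  # equal SBP values interpolate to a constant
  expect_true(all(abs(cont$sbp_mmHg[cont$time_s >= 2 & cont$time_s <= 3] -
                      110) < 1e-12))
  # held constant beyond the first/last beat
  expect_equal(at(cont$sbp_mmHg, 0), 100)
  expect_equal(at(cont$map_mmHg, 4), 88, tolerance = 1e-12)
})

test_that("DBP <= MAP <= SBP across random clean configurations", {
  set.seed(123)
  for (i in 1:25) {
    sbp <- stats::runif(1, 95, 180)
    dbp <- stats::runif(1, 50, sbp - 20)
    hr <- stats::runif(1, 45, 150)
    rec <- template_wave(hr, 30, sbp = sbp, dbp = dbp)
    beats <- detect_beats(rec)
    for (m in c("waveform_mean", "onethird")) {
      b <- map_from_beats(beats, rec, method = m)
      expect_true(all(b$dbp_mmHg <= b$map_mmHg + 1e-9 &
                      b$map_mmHg <= b$sbp_mmHg + 1e-9))
    }
  }
})
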