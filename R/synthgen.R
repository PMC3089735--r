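# unit-peak gamma bump: g(t) = (t/tp)^(k-1) * exp(-(t - tp)/theta), t > 0,
# with theta = tp/(k-1) so the maximum (value 1) sits exactly at tp
gamma_bump <- function(t, peak_s, shape) {
  stopifnot(shape > 1, peak_s > 0)
  theta <- peak_s / (shape - 1)
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- exp((shape - 1) * log(tp / peak_s) - (tp - peak_s) / theta)
  out
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic session generator. The defaults encode
#' the emulated study design: 15 trials per cell of the 2 x 2 design
#' (stimulus persistency 1500/3000 ms x arm-raise movement yes/no), jittered
#' inter-trial interval 19.2 +/- 2.9 s, 50 Hz two-wavelength NIRS, 200 Hz
#' finger pressure, an arm-raise pressure transient of +7.8 mmHg systolic
#' (peak 5.8 s) / +5.6 mmHg diastolic (peak 5.1 s), cortical haemodynamic
#' responses (O2Hb positive, peak 8.6 s for 1500 ms and 10.4 s for 3000 ms
#' stimuli; HHb negative), and pressure-coupled signal components with
#' positive O2Hb gains in both channel depths and a negative deep / small
#' positive shallow HHb gain.
#'
#' @param seed integer RNG seed (fixed seed implies byte-identical outputs).
#' @param n_per_condition trials per condition cell (default 15).
#' @param iti_mean_s,iti_sd_s inter-trial interval mean and SD (s). The ITI is
#'   drawn from a normal truncated below at `iti_mean_s - 2 * iti_sd_s`, which
#'   must be >= 13 s so that -0.5..12 s epochs can never overlap.
#' @param cue_lead_s movement-cue lead before stimulus onset (s).
#' @param heart_rate_bpm constant heart rate (beats/min).
#' @param sbp_baseline_mmHg,dbp_baseline_mmHg resting systolic/diastolic
#'   pressure.
#' @param bp_transient_amplitude_mmHg named vector `c(sbp =, dbp =)` of
#'   arm-raise transient amplitudes.
#' @param bp_transient_peak_s named vector `c(sbp =, dbp =)` of transient peak
#'   latencies after stimulus onset.
#' @param bp_transient_shape gamma shape of the transient (dimensionless).
#' @param hrf_amplitude_uM named list `o2hb`/`hhb`, each a named vector
#'   `c("1500" =, "3000" =)` of response amplitudes (uM).
#' @param hrf_peak_s same structure, response peak latencies (s).
#' @param hrf_shape gamma shape of the haemodynamic response.
#' @param coupling_gain_shallow_o2hb,coupling_gain_shallow_hhb,coupling_gain_deep_o2hb,coupling_gain_deep_hhb
#'   signal change per mmHg of MAP deviation (uM/mmHg).
#' @param drift_poly_coeffs slow-drift polynomial coefficients (uM), evaluated
#'   on session time rescaled to [-1, 1] (ascending powers). Degree must stay
#'   <= the analysis detrend degree for the null-physiology identity to hold.
#' @param drift_hhb_ratio drift carried into HHb as a fraction of the O2Hb
#'   drift.
#' @param pulsation_amp_uM cardiac pulsation amplitude in O2Hb (uM); HHb gets
#'   a quarter of it.
#' @param noise_sd_uM white measurement noise SD (uM, per chromophore).
#' @param age_years participant age (sets the DPF).
#' @param fs_nirs_hz,fs_bp_hz sampling rates (Hz).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_condition = 15L,
                       iti_mean_s = 19.2,
                       iti_sd_s = 2.9,
                       cue_lead_s = 1.0,
                       heart_rate_bpm = 70,
                       sbp_baseline_mmHg = 120,
                       dbp_baseline_mmHg = 80,
                       bp_transient_amplitude_mmHg = c(sbp = 7.8, dbp = 5.6),
                       bp_transient_peak_s = c(sbp = 5.8, dbp = 5.1),
                       bp_transient_shape = 8,
                       hrf_amplitude_uM = list(
                         o2hb = c("1500" = 0.26, "3000" = 0.38),
                         hhb = c("1500" = -0.09, "3000" = -0.11)),
                       hrf_peak_s = list(
                         o2hb = c("1500" = 8.6, "3000" = 10.4),
                         hhb = c("1500" = 7.4, "3000" = 8.8)),
                       hrf_shape = 10,
                       coupling_gain_shallow_o2hb = 0.066,
                       coupling_gain_shallow_hhb = 0.0136,
                       coupling_gain_deep_o2hb = 0.063,
                       coupling_gain_deep_hhb = -0.012,
                       drift_poly_coeffs = c(0, 0.4, -0.2, 0.15),
                       drift_hhb_ratio = 0.3,
                       pulsation_amp_uM = 0.1,
                       noise_sd_uM = 0.05,
                       age_years = 25,
                       fs_nirs_hz = 50,
                       fs_bp_hz = 200) {
  cfg <- list(seed = as.integer(seed), n_per_condition = as.integer(n_per_condition),
              iti_mean_s = iti_mean_s, iti_sd_s = iti_sd_s,
              cue_lead_s = cue_lead_s,
              heart_rate_bpm = heart_rate_bpm,
              sbp_baseline_mmHg = sbp_baseline_mmHg,
              dbp_baseline_mmHg = dbp_baseline_mmHg,
              bp_transient_amplitude_mmHg = bp_transient_amplitude_mmHg,
              bp_transient_peak_s = bp_transient_peak_s,
              bp_transient_shape = bp_transient_shape,
              hrf_amplitude_uM = hrf_amplitude_uM,
              hrf_peak_s = hrf_peak_s,
              hrf_shape = hrf_shape,
              coupling_gain_shallow_o2hb = coupling_gain_shallow_o2hb,
              coupling_gain_shallow_hhb = coupling_gain_shallow_hhb,
              coupling_gain_deep_o2hb = coupling_gain_deep_o2hb,
              coupling_gain_deep_hhb = coupling_gain_deep_hhb,
              drift_poly_coeffs = drift_poly_coeffs,
              drift_hhb_ratio = drift_hhb_ratio,
              pulsation_amp_uM = pulsation_amp_uM,
              noise_sd_uM = noise_sd_uM,
              age_years = age_years,
              fs_nirs_hz = fs_nirs_hz, fs_bp_hz = fs_bp_hz)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  nonneg <- c("heart_rate_bpm", "pulsation_amp_uM", "noise_sd_uM",
              "age_years", "fs_nirs_hz", "fs_bp_hz", "iti_sd_s")
  for (f in nonneg)
    if (any(cfg[[f]] < 0)) stop(f, " must be non-negative")
  if (cfg$n_per_condition < 1) stop("n_per_condition must be >= 1")
  if (cfg$iti_mean_s <= 13)
    stop("iti_mean_s must exceed 13 s so epochs cannot overlap")
  if (cfg$iti_mean_s - 2 * cfg$iti_sd_s < 13)
    stop(sprintf(
      "ITI truncation floor %.2f s is below 13 s (epoch-overlap hazard); ",
      cfg$iti_mean_s - 2 * cfg$iti_sd_s),
      "reduce iti_sd_s or raise iti_mean_s")
  if (any(cfg$bp_transient_amplitude_mmHg < 0))
    stop("bp_transient_amplitude_mmHg must be non-negative")
  invisible(TRUE)
}

#' Generate a randomized trial schedule
#'
#' Builds the 2 x 2 (duration x movement) event-related design: each cell is
#' replicated `n_per_condition` times, the trial order is a seeded random
#' permutation, and inter-trial intervals are drawn from a normal distribution
#' truncated below at `iti_mean_s - 2 * iti_sd_s` (validated >= 13 s), so the
#' -0.5..12 s analysis epochs can never overlap.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `trial_schedule` with columns `onset_s`
#'   (strictly increasing), `duration_ms` (1500 or 3000) and `movement`
#'   (logical); attribute `cue_lead_s`.
#' @export
#' @examples
#' sched <- make_schedule(sim_config(seed = 7))
#' nrow(sched)         # 60 trials
#' table(sched$duration_ms, sched$movement)
make_schedule <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cells <- expand.grid(duration_ms = c(1500, 3000),
                       movement = c(FALSE, TRUE))
  trials <- cells[rep(seq_len(nrow(cells)), each = config$n_per_condition), ]
  trials <- trials[sample(nrow(trials)), ]
  n <- nrow(trials)
  floor_s <- config$iti_mean_s - 2 * config$iti_sd_s
  draw_iti <- function(m) {
    out <- numeric(0)
    while (length(out) < m) {
      x <- rnorm(m, config$iti_mean_s, config$iti_sd_s)
      out <- c(out, x[x >= floor_s])
    }
    out[seq_len(m)]
  }
  itis <- draw_iti(n)   # first draw doubles as the lead-in to trial 1
  onsets <- 5 + cumsum(itis)
  sched <- data.frame(onset_s = onsets,
                      duration_ms = trials$duration_ms,
                      movement = trials$movement)
  rownames(sched) <- NULL
  structure(sched, class = c("trial_schedule", "data.frame"),
            cue_lead_s = config$cue_lead_s)
}

session_end_s <- function(schedule) max(schedule$onset_s) + 20

# normalized single-beat shape s(phase) in [0, 1]: raised-cosine systolic
# upstroke over 80 ms, then an exponential decay rescaled to reach exactly 0
# (the diastolic level) at the end of the cardiac period
beat_shape <- function(phase, period_s, upstroke_s = 0.08) {
  tau <- (period_s - upstroke_s) / 4
  E <- exp(-(period_s - upstroke_s) / tau)
  up <- phase < upstroke_s
  s <- numeric(length(phase))
  s[up] <- 0.5 * (1 - cos(pi * phase[up] / upstroke_s))
  s[!up] <- (exp(-(phase[!up] - upstroke_s) / tau) - E) / (1 - E)
  s
}

# mean of the beat shape over one period (time fraction spent near systole);
# used to build the ground-truth MAP envelope
beat_shape_mean <- function(period_s, upstroke_s = 0.08) {
  ph <- seq(0, period_s, length.out = 20001)[-20001]
  mean(beat_shape(ph, period_s, upstroke_s))
}

# slowly varying SBP/DBP envelopes (baseline + movement-trial gamma
# transients), evaluated at arbitrary times
bp_envelopes <- function(t, schedule, config) {
  sbp <- rep(config$sbp_baseline_mmHg, length(t))
  dbp <- rep(config$dbp_baseline_mmHg, length(t))
  amp <- config$bp_transient_amplitude_mmHg
  pk <- config$bp_transient_peak_s
  if (length(pk) == 1) pk <- c(sbp = unname(pk), dbp = unname(pk))
  mov <- schedule$onset_s[schedule$movement]
  for (on in mov) {
    sbp <- sbp + amp[["sbp"]] *
      gamma_bump(t - on, pk[["sbp"]], config$bp_transient_shape)
    dbp <- dbp + amp[["dbp"]] *
      gamma_bump(t - on, pk[["dbp"]], config$bp_transient_shape)
  }
  list(sbp = sbp, dbp = dbp)
}

#' Simulate the continuous finger-pressure waveform
#'
#' Builds a pulsatile waveform from a per-beat template (raised-cosine
#' systolic upstroke, exponential diastolic decay; one beat per cardiac
#' period) whose systolic and diastolic envelopes are the configured baselines
#' plus, on movement trials only, gamma-shaped transients peaking
#' `bp_transient_peak_s` after stimulus onset with the configured amplitudes.
#' The generator is noiseless and deterministic given the schedule.
#'
#' @param schedule a [make_schedule()] result.
#' @param config a [sim_config()] with `fs_bp_hz >= 25`.
#' @return list with `recording` (a [pressure_recording()]), `truth` (injected
#'   per-trial amplitudes/latencies, envelopes on the NIRS grid and the
#'   ground-truth `map_deviation_mmHg` used to couple NIRS channels) and
#'   `config` echo.
#' @export
simulate_pressure <- function(schedule, config) {
  stopifnot(inherits(schedule, "trial_schedule"))
  if (config$fs_bp_hz < 25) stop("fs_bp_hz must be >= 25")
  t_end <- session_end_s(schedule)
  t <- seq(0, t_end, by = 1 / config$fs_bp_hz)
  period <- 60 / config$heart_rate_bpm
  env <- bp_envelopes(t, schedule, config)
  phase <- t %% period
  s <- beat_shape(phase, period)
  p <- env$dbp + (env$sbp - env$dbp) * s
  rec <- pressure_recording(t, p)

  tn <- seq(0, t_end, by = 1 / config$fs_nirs_hz)
  envn <- bp_envelopes(tn, schedule, config)
  sbar <- beat_shape_mean(period)
  map_dev <- (envn$dbp - config$dbp_baseline_mmHg) +
    ((envn$sbp - config$sbp_baseline_mmHg) -
     (envn$dbp - config$dbp_baseline_mmHg)) * sbar
  amp <- config$bp_transient_amplitude_mmHg
  pk <- config$bp_transient_peak_s
  truth <- list(
    per_trial = data.frame(
      onset_s = schedule$onset_s,
      movement = schedule$movement,
      sbp_amplitude_mmHg = ifelse(schedule$movement, amp[["sbp"]], 0),
      sbp_peak_s = ifelse(schedule$movement, pk[["sbp"]], NA_real_),
      dbp_amplitude_mmHg = ifelse(schedule$movement, amp[["dbp"]], 0),
      dbp_peak_s = ifelse(schedule$movement, pk[["dbp"]], NA_real_)),
    map_time_s = tn,
    map_deviation_mmHg = map_dev,
    beat_shape_mean = sbar)
  list(recording = rec, truth = truth, config = config)
}

#' Ground-truth MAP deviation envelope
#'
#' Convenience wrapper returning only the analytic mean-arterial-pressure
#' deviation (mmHg, relative to baseline) on the NIRS sampling grid — the
#' exact series the generator feeds into the NIRS coupling terms — without
#' synthesising the pulsatile waveform.
#'
#' @inheritParams simulate_pressure
#' @return list `time_s`, `map_deviation_mmHg`.
#' @export
simulate_map_deviation <- function(schedule, config) {
  t_end <- session_end_s(schedule)
  tn <- seq(0, t_end, by = 1 / config$fs_nirs_hz)
  envn <- bp_envelopes(tn, schedule, config)
  sbar <- beat_shape_mean(60 / config$heart_rate_bpm)
  dev <- (envn$dbp - config$dbp_baseline_mmHg) +
    ((envn$sbp - config$sbp_baseline_mmHg) -
     (envn$dbp - config$dbp_baseline_mmHg)) * sbar
  list(time_s = tn, map_deviation_mmHg = dev)
}

#' Simulate a raw two-wavelength NIRS channel
#'
#' Constructs ground-truth chromophore traces and passes them through the
#' forward modified Beer-Lambert model ([conc_to_od()]) to emit the optical
#' densities the device would record. In `deep` mode each trial adds a gamma
#' haemodynamic response (O2Hb positive, HHb negative, peak latency increasing
#' with stimulus duration) plus `coupling_gain_deep_* x map_deviation`; in
#' `shallow` mode there is no neural response, only
#' `coupling_gain_shallow_* x map_deviation` (HHb gain small and positive).
#' Both modes add the slow drift polynomial, a cardiac pulsation at the heart
#' rate, and white noise. RNG stream: `seed + 1` (deep) or `seed + 2`
#' (shallow).
#'
#' @param schedule a [make_schedule()] result.
#' @param map_deviation MAP-minus-baseline series (mmHg) sampled at
#'   `fs_nirs_hz` over the session (see [simulate_map_deviation()]).
#' @param config a [sim_config()].
#' @param mode `"deep"` (4 cm separation) or `"shallow"` (1 cm).
#' @param ext,dpfm coefficient tables for the forward model.
#' @return list with `raw` (a [raw_optical_recording()], one channel `ch1`),
#'   `conc_truth` (the noiseless-inversion target, a
#'   [chromophore_recording()]) and `truth` (injected per-condition
#'   amplitudes/latencies and the coupling gains used).
#' @export
simulate_nirs <- function(schedule, map_deviation, config,
                          mode = c("deep", "shallow"),
                          ext = extinction_table(), dpfm = dpf_model()) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "trial_schedule"))
  t_end <- session_end_s(schedule)
  t <- seq(0, t_end, by = 1 / config$fs_nirs_hz)
  if (length(map_deviation) != length(t))
    stop(sprintf("map_deviation must be sampled at fs_nirs_hz over the session (expected %d samples, got %d)",
                 length(t), length(map_deviation)))
  set.seed(config$seed + if (mode == "deep") 1L else 2L)

  o2 <- numeric(length(t)); hh <- numeric(length(t))
  if (mode == "deep") {
    for (i in seq_len(nrow(schedule))) {
      dur <- as.character(schedule$duration_ms[i])
      on <- schedule$onset_s[i]
      o2 <- o2 + config$hrf_amplitude_uM$o2hb[[dur]] *
        gamma_bump(t - on, config$hrf_peak_s$o2hb[[dur]], config$hrf_shape)
      hh <- hh + config$hrf_amplitude_uM$hhb[[dur]] *
        gamma_bump(t - on, config$hrf_peak_s$hhb[[dur]], config$hrf_shape)
    }
    g_o2 <- config$coupling_gain_deep_o2hb
    g_hh <- config$coupling_gain_deep_hhb
    sep <- 4.0
  } else {
    g_o2 <- config$coupling_gain_shallow_o2hb
    g_hh <- config$coupling_gain_shallow_hhb
    sep <- 1.0
  }
  o2 <- o2 + g_o2 * map_deviation
  hh <- hh + g_hh * map_deviation

  u <- seq(-1, 1, length.out = length(t))
  drift <- drop(outer(u, seq_along(config$drift_poly_coeffs) - 1, `^`) %*%
                config$drift_poly_coeffs)
  phase <- stats::runif(1, 0, 2 * pi)
  puls <- sin(2 * pi * (config$heart_rate_bpm / 60) * t + phase)
  noise_o2 <- rnorm(length(t), 0, config$noise_sd_uM)
  noise_hh <- rnorm(length(t), 0, config$noise_sd_uM)

  o2_full <- o2 + drift + config$pulsation_amp_uM * puls + noise_o2
  hh_full <- hh + config$drift_hhb_ratio * drift +
    0.25 * config$pulsation_amp_uM * puls + noise_hh

  geom <- optical_geometry(separation_cm = sep, age_years = config$age_years)
  conc <- chromophore_recording(
    t, data.frame(ch1_o2hb = o2_full, ch1_hhb = hh_full), geometry = geom)
  raw <- conc_to_od(conc, ext = ext, dpfm = dpfm)

  truth <- list(
    mode = mode,
    coupling_gain_o2hb = g_o2,
    coupling_gain_hhb = g_hh,
    hrf_amplitude_uM = if (mode == "deep") config$hrf_amplitude_uM else NULL,
    hrf_peak_s = if (mode == "deep") config$hrf_peak_s else NULL,
    clean = list(o2hb = o2, hhb = hh))
  list(raw = raw, conc_truth = conc, truth = truth)
}

#' Simulate a complete session
#'
#' Seeded end-to-end generation: trial schedule, pulsatile pressure waveform
#' with arm-raise transients, and raw two-wavelength optical densities for one
#' deep (cortical) and one shallow (extracranial) channel, with full ground
#' truth.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_session`: `schedule`, `pressure`
#'   ([simulate_pressure()] output), `nirs_deep`, `nirs_shallow`
#'   ([simulate_nirs()] outputs) and `config`.
#' @export
simulate_session <- function(config = sim_config()) {
  schedule <- make_schedule(config)
  pres <- simulate_pressure(schedule, config)
  dev <- pres$truth$map_deviation_mmHg
  deep <- simulate_nirs(schedule, dev, config, "deep")
  shallow <- simulate_nirs(schedule, dev, config, "shallow")
  structure(list(schedule = schedule, pressure = pres,
                 nirs_deep = deep, nirs_shallow = shallow, config = config),
            class = "sim_session")
}

#' Write a simulated session to CSV/JSON files
#'
#' Emits `schedule.csv` (`onset_s,duration_ms,movement`), `pressure.csv`
#' (`time_s,pressure_mmHg`), `nirs_deep.csv` / `nirs_shallow.csv`
#' (`time_s,ch1_od_w1,ch1_od_w2`) and `ground_truth.json`. All floats are
#' written at 9 significant digits so identical seeds give byte-identical
#' files.
#'
#' @param session a [simulate_session()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "sim_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sch <- as.data.frame(session$schedule)
  write_table_9sig(sch, file.path(dir, "schedule.csv"))
  rec <- session$pressure$recording
  write_table_9sig(data.frame(time_s = rec$time_s,
                              pressure_mmHg = rec$pressure_mmHg),
                   file.path(dir, "pressure.csv"))
  for (mode in c("deep", "shallow")) {
    raw <- session[[paste0("nirs_", mode)]]$raw
    df <- cbind(data.frame(time_s = raw$time_s), raw$od)
    write_table_9sig(df, file.path(dir, paste0("nirs_", mode, ".csv")))
  }
  gt <- list(
    config = unclass(session$config),
    bp_per_trial = session$pressure$truth$per_trial,
    beat_shape_mean = session$pressure$truth$beat_shape_mean,
    deep = session$nirs_deep$truth[c("coupling_gain_o2hb",
                                     "coupling_gain_hhb",
                                     "hrf_amplitude_uM", "hrf_peak_s")],
    shallow = session$nirs_shallow$truth[c("coupling_gain_o2hb",
                                           "coupling_gain_hhb")])
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = 9, pretty = TRUE)
  invisible(dir)
}
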