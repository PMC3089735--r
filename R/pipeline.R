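#' Analysis parameters
#'
#' Every default is the value used by the emulated protocol: NIRS low-pass
#' 1 Hz, pressure low-pass 10 Hz, degree-5 polynomial detrend, NIRS epochs
#' `[-0.5, 12)` s and pressure epochs `[-0.5, 10)` s with a `[-0.5, 0)` s
#' baseline, +/-3 SD outlier rejection, waveform-mean MAP and a 0.05
#' family-wise alpha over the three planned comparisons.
#'
#' @param nirs_lowpass_hz,bp_lowpass_hz filter cutoffs (Hz).
#' @param detrend_degree polynomial detrend degree.
#' @param nirs_window_s,bp_window_s,baseline_s epoch windows (s).
#' @param reject_k outlier rejection threshold (SD units).
#' @param map_method `"waveform_mean"` or `"onethird"`.
#' @param family_alpha family-wise error rate for planned comparisons.
#' @return list of class `analysis_params`.
#' @export
analysis_params <- function(nirs_lowpass_hz = 1, bp_lowpass_hz = 10,
                            detrend_degree = 5,
                            nirs_window_s = c(-0.5, 12),
                            bp_window_s = c(-0.5, 10),
                            baseline_s = c(-0.5, 0),
                            reject_k = 3,
                            map_method = "waveform_mean",
                            family_alpha = 0.05) {
  structure(list(nirs_lowpass_hz = nirs_lowpass_hz,
                 bp_lowpass_hz = bp_lowpass_hz,
                 detrend_degree = detrend_degree,
                 nirs_window_s = nirs_window_s, bp_window_s = bp_window_s,
                 baseline_s = baseline_s, reject_k = reject_k,
                 map_method = map_method, family_alpha = family_alpha),
            class = "analysis_params")
}

#' Run configuration
#'
#' @param mode `"full"` (simulate then analyze), `"simulate"` (write synthetic
#'   inputs only) or `"analyze"` (load CSV inputs).
#' @param sim a [sim_config()] (simulate/full modes).
#' @param params an [analysis_params()].
#' @param seed optional integer overriding `sim$seed`.
#' @param paths for analyze mode: named list with `nirs`, `bp`, `schedule`,
#'   `age_years`, `nirs_mode` (`"deep"`/`"shallow"`).
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       sim = sim_config(), params = analysis_params(),
                       seed = NULL, paths = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) {
    sim$seed <- as.integer(seed)
    validate_sim_config(sim)
  }
  if (mode == "analyze" && is.null(paths))
    stop("analyze mode requires input paths")
  structure(list(mode = mode, sim = sim, params = params, paths = paths),
            class = "run_config")
}

cond_labels <- function(schedule) {
  paste0(schedule$duration_ms,
         ifelse(schedule$movement, "_move", "_nomove"))
}

# preprocess one uniformly sampled trace and epoch it:
# low-pass (optional) -> polynomial detrend -> epoch + baseline correction
preprocess_and_epoch <- function(x, fs_hz, schedule, params, window_s,
                                 lowpass_hz = NULL, signal_name = "signal",
                                 units = "") {
  if (!is.null(lowpass_hz)) x <- lowpass(x, fs_hz, lowpass_hz)
  x <- detrend_poly(x, degree = params$detrend_degree)
  epoch_signal(x, fs_hz, schedule$onset_s, window_s = window_s,
               baseline_s = params$baseline_s,
               conditions = cond_labels(schedule),
               signal_name = signal_name, units = units)
}

# per-trial response metrics for the non-rejected epochs of an epoch_set
per_trial_metrics <- function(ep, schedule, polarity) {
  keep <- which(!ep$rejected)
  rows <- lapply(keep, function(i) {
    m <- response_metrics(ep$data[i, ], ep$time_s, polarity = polarity)
    data.frame(trial = i, onset_s = ep$onsets_s[i],
               amplitude = m$amplitude, latency_s = m$latency_s)
  })
  out <- do.call(rbind, rows)
  sel <- match(out$onset_s, schedule$onset_s)
  out$duration_ms <- schedule$duration_ms[sel]
  out$movement <- schedule$movement[sel]
  out
}

#' Analyze the blood-pressure branch of a session
#'
#' Low-pass filters the waveform at 10 Hz, peak-picks beats, fills MAP,
#' resamples the beat-wise SBP/DBP/MAP series to the NIRS rate, detrends,
#' epochs `[-0.5, 10)` s around stimulus onsets and computes per-trial and
#' condition-averaged response metrics.
#'
#' @param rec a [pressure_recording()].
#' @param schedule a trial schedule (`onset_s`, `duration_ms`, `movement`).
#' @param params an [analysis_params()].
#' @param fs_out_hz resampling rate for the beat series (default 50).
#' @return list with `beats`, per-signal `epochs`, `averages`, `metrics`
#'   (per-trial data.frames keyed `sbp`, `dbp`, `map`).
#' @export
analyze_pressure <- function(rec, schedule, params = analysis_params(),
                             fs_out_hz = 50) {
  filt <- pressure_recording(rec$time_s,
                             lowpass(rec$pressure_mmHg, rec$fs_hz,
                                     params$bp_lowpass_hz))
  beats <- detect_beats(filt)
  beats <- map_from_beats(beats, filt, method = params$map_method)
  cont <- beats_to_continuous(beats, fs_out_hz,
                              t_range = c(0, max(rec$time_s)))
  out <- list(beats = beats, continuous = cont,
              epochs = list(), averages = list(), metrics = list())
  for (sig in c("sbp", "dbp", "map")) {
    ep <- preprocess_and_epoch(cont[[paste0(sig, "_mmHg")]], fs_out_hz,
                               schedule, params, params$bp_window_s,
                               lowpass_hz = NULL,
                               signal_name = sig, units = "mmHg")
    out$epochs[[sig]] <- ep
    out$averages[[sig]] <- average_by_condition(ep)
    out$metrics[[sig]] <- per_trial_metrics(ep, schedule, polarity = "max")
  }
  out
}

#' Analyze one NIRS channel of a session
#'
#' Converts optical densities to chromophore concentrations, low-pass filters
#' at 1 Hz, detrends with a degree-5 polynomial, epochs `[-0.5, 12)` s,
#' rejects +/-3 SD outlier epochs per condition cell and computes per-trial
#' and condition-averaged amplitude/latency metrics. O2Hb responses are
#' measured as maxima; HHb polarity follows the channel depth — `min` for
#' deep (cortical washout makes HHb negative) and `max` for shallow (the
#' extracranial HHb response tracks pressure weakly positively).
#'
#' @param raw a [raw_optical_recording()].
#' @param schedule trial schedule.
#' @param params an [analysis_params()].
#' @param mode `"deep"` or `"shallow"`; sets the HHb metric polarity.
#' @param ext,dpfm coefficient tables for the inversion.
#' @return list with per-chromophore `epochs`, `averages`, `metrics` and the
#'   `conc` recording.
#' @export
analyze_nirs <- function(raw, schedule, params = analysis_params(),
                         mode = c("deep", "shallow"),
                         ext = extinction_table(), dpfm = dpf_model()) {
  mode <- match.arg(mode)
  conc <- od_to_conc(raw, ext = ext, dpfm = dpfm)
  fs <- 1 / (conc$time_s[2] - conc$time_s[1])
  ch <- conc$channels[1]
  out <- list(conc = conc, epochs = list(), averages = list(),
              metrics = list())
  for (chrom in c("o2hb", "hhb")) {
    x <- conc$conc[[paste0(ch, "_", chrom)]]
    ep <- preprocess_and_epoch(x, fs, schedule, params, params$nirs_window_s,
                               lowpass_hz = params$nirs_lowpass_hz,
                               signal_name = chrom, units = "uM")
    ep <- reject_outliers(ep, k = params$reject_k)
    out$epochs[[chrom]] <- ep
    out$averages[[chrom]] <- average_by_condition(ep)
    out$metrics[[chrom]] <- per_trial_metrics(
      ep, schedule,
      polarity = if (chrom == "o2hb" || mode == "shallow") "max" else "min")
  }
  out
}

# group-averaged epoch (mean across non-rejected epochs in `mask` trials)
group_mean_epoch <- function(ep, mask) {
  i <- which(mask & !ep$rejected)
  if (length(i) == 0) return(NULL)
  colMeans(ep$data[i, , drop = FALSE])
}

condition_masks <- function(schedule) {
  list(move = schedule$movement,
       nomove = !schedule$movement,
       `1500_move` = schedule$movement & schedule$duration_ms == 1500,
       `3000_move` = schedule$movement & schedule$duration_ms == 3000,
       `1500_nomove` = !schedule$movement & schedule$duration_ms == 1500,
       `3000_nomove` = !schedule$movement & schedule$duration_ms == 3000)
}

# mask in epoch-trial space (epochs may have dropped out-of-bounds onsets)
epoch_mask <- function(ep, schedule, mask) {
  mask[match(ep$onsets_s, schedule$onset_s)]
}

#' End-to-end pipeline run
#'
#' In `simulate`/`full` mode, generates a seeded synthetic session and writes
#' its input files under `out_dir/inputs/`; in `analyze`/`full` mode, runs
#' conversion, preprocessing, beat extraction, metrics, planned comparisons
#' and coupling regressions, writing `tables/` (metrics, stats, regressions,
#' rejections), `traces/` (condition-averaged time-courses), a deterministic
#' `provenance.json` and `run.log` under `out_dir`. Identical seeds give
#' byte-identical output directories.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return the results bundle, invisibly (list with `metrics`, `stats`,
#'   `regressions`, `rejections`, `averages`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  loglines <- character(0)
  say <- function(level, fmt, ...) {
    loglines <<- c(loglines, sprintf("%s %s", level, sprintf(fmt, ...)))
  }
  params <- config$params

  if (config$mode %in% c("simulate", "full")) {
    session <- simulate_session(config$sim)
    write_session(session, file.path(out_dir, "inputs"))
    say("INFO", "simulated session: %d trials, seed %d",
        nrow(session$schedule), config$sim$seed)
    schedule <- session$schedule
    nirs_list <- list(deep = session$nirs_deep$raw,
                      shallow = session$nirs_shallow$raw)
    prec <- session$pressure$recording
  }
  if (config$mode == "analyze") {
    sess <- read_session(config$paths)
    schedule <- sess$schedule
    nirs_list <- setNames(list(sess$nirs), config$paths$nirs_mode)
    prec <- sess$pressure
  }
  if (config$mode == "simulate") {
    writeLines(loglines, logf)
    write_provenance(config, out_dir)
    return(invisible(list(schedule = schedule)))
  }

  pres <- analyze_pressure(prec, schedule, params)
  say("INFO", "pressure: %d beats detected, %d epochs per series",
      nrow(pres$beats), nrow(pres$epochs$sbp$data))

  nirs_res <- lapply(names(nirs_list), function(mode) {
    res <- analyze_nirs(nirs_list[[mode]], schedule, params, mode = mode)
    for (chrom in c("o2hb", "hhb"))
      say("INFO", "nirs %s %s: %d epochs kept, %d rejected", mode, chrom,
          sum(!res$epochs[[chrom]]$rejected),
          sum(res$epochs[[chrom]]$rejected))
    res
  })
  names(nirs_res) <- names(nirs_list)

  metrics_rows <- list(); stats_rows <- list(); reg_rows <- list()
  rej_rows <- list()
  masks <- condition_masks(schedule)

  add_metrics <- function(signal, avg) {
    for (cell in rownames(avg$mean)) {
      m <- response_metrics(avg$mean[cell, ], avg$time_s, polarity = "auto")
      metrics_rows[[length(metrics_rows) + 1]] <<- data.frame(
        signal = signal, condition = cell, amplitude = m$amplitude,
        latency_s = m$latency_s, n_epochs = unname(avg$n[cell]))
    }
  }
  add_stat <- function(contrast, measure, res) {
    stats_rows[[length(stats_rows) + 1]] <<- data.frame(
      contrast = contrast, measure = measure, t = res$t, df = res$df,
      p = res$p, significant = is.finite(res$p) & res$p < params$family_alpha)
  }

  # pressure: condition metrics + one-sample tests of arm-raise responses
  for (sig in c("sbp", "dbp", "map")) {
    add_metrics(sig, pres$averages[[sig]])
    mt <- pres$metrics[[sig]]
    add_stat(paste0(sig, "_move_vs_0"), "amplitude",
             one_sample_t(mt$amplitude[mt$movement]))
  }
  # systolic vs diastolic amplitude correlation across movement trials
  sb <- pres$metrics$sbp; db <- pres$metrics$dbp
  msk <- sb$movement
  if (sum(msk) >= 3 && sd(db$amplitude[msk]) > 0) {
    fit <- lm(sb$amplitude[msk] ~ db$amplitude[msk])
    ct <- suppressWarnings(cor.test(db$amplitude[msk], sb$amplitude[msk]))
    reg_rows[[length(reg_rows) + 1]] <- data.frame(
      signal = "sbp_vs_dbp", condition = "move",
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r = unname(ct$estimate), p = ct$p.value, n = sum(msk))
  }

  for (mode in names(nirs_res)) {
    res <- nirs_res[[mode]]
    for (chrom in c("o2hb", "hhb")) {
      sig <- paste(mode, chrom, sep = "_")
      add_metrics(sig, res$averages[[chrom]])
      rl <- res$epochs[[chrom]]$rejection_log
      rl$signal <- sig
      rej_rows[[length(rej_rows) + 1]] <- rl
      mt <- res$metrics[[chrom]]
      if (mode == "deep") {
        pc <- planned_comparisons(mt, family_alpha = params$family_alpha)
        crit <- attr(pc, "crit_alpha")
        for (i in seq_len(nrow(pc)))
          stats_rows[[length(stats_rows) + 1]] <- data.frame(
            contrast = paste(sig, pc$contrast[i], sep = ":"),
            measure = pc$measure[i], t = pc$t[i], df = pc$df[i], p = pc$p[i],
            significant = pc$significant[i])
        say("INFO", "planned comparisons %s: critical alpha %.3f", sig,
            attr(pc, "crit_alpha_display"))
      } else {
        add_stat(paste0(sig, "_move_vs_0"), "amplitude",
                 one_sample_t(mt$amplitude[mt$movement]))
      }
      # coupling regressions vs MAP over the shared [-0.5, 10) window
      map_avg <- pres$averages$map
      groups <- c("move", "nomove",
                  if (mode == "deep") c("1500_move", "3000_move"))
      for (grp in groups) {
        ge <- group_mean_epoch(res$epochs[[chrom]],
                               epoch_mask(res$epochs[[chrom]], schedule,
                                          masks[[grp]]))
        gm <- group_mean_epoch(pres$epochs$map,
                               epoch_mask(pres$epochs$map, schedule,
                                          masks[[grp]]))
        if (is.null(ge) || is.null(gm)) next
        rr <- tryCatch(
          coupling_regression(ge, res$epochs[[chrom]]$time_s,
                              gm, pres$epochs$map$time_s,
                              window_s = params$bp_window_s),
          error = function(e) {
            say("WARN", "regression %s/%s skipped: %s", sig, grp,
                conditionMessage(e))
            NULL
          })
        if (is.null(rr)) next
        reg_rows[[length(reg_rows) + 1]] <- data.frame(
          signal = sig, condition = grp, slope = rr$slope,
          intercept = rr$intercept, r = rr$r, p = rr$p, n = rr$n)
      }
    }
  }

  tables_dir <- file.path(out_dir, "tables")
  traces_dir <- file.path(out_dir, "traces")
  dir.create(tables_dir, showWarnings = FALSE)
  dir.create(traces_dir, showWarnings = FALSE)
  metrics <- do.call(rbind, metrics_rows)
  stats <- do.call(rbind, stats_rows)
  regressions <- do.call(rbind, reg_rows)
  rejections <- do.call(rbind, rej_rows)
  write_table_9sig(metrics, file.path(tables_dir, "metrics.csv"))
  write_table_9sig(stats, file.path(tables_dir, "stats.csv"))
  write_table_9sig(regressions, file.path(tables_dir, "regressions.csv"))
  write_table_9sig(rejections, file.path(tables_dir, "rejections.csv"))

  averages <- c(
    setNames(lapply(c("sbp", "dbp", "map"),
                    function(s) pres$averages[[s]]),
             c("sbp", "dbp", "map")),
    unlist(lapply(names(nirs_res), function(mode)
      setNames(lapply(c("o2hb", "hhb"),
                      function(chrom) nirs_res[[mode]]$averages[[chrom]]),
               paste(mode, c("o2hb", "hhb"), sep = "_"))),
      recursive = FALSE))
  for (nm in names(averages)) {
    avg <- averages[[nm]]
    df <- data.frame(time_s = avg$time_s)
    for (cell in rownames(avg$mean)) {
      df[[paste0(cell, "_mean")]] <- avg$mean[cell, ]
      df[[paste0(cell, "_sd")]] <- avg$sd[cell, ]
    }
    write_table_9sig(df, file.path(traces_dir, paste0(nm, ".csv")))
  }

  writeLines(loglines, logf)
  write_provenance(config, out_dir)
  invisible(list(metrics = metrics, stats = stats,
                 regressions = regressions, rejections = rejections,
                 averages = averages, pressure = pres, nirs = nirs_res))
}

# deterministic provenance: config echo + seed + package version, no clock
write_provenance <- function(config, out_dir) {
  prov <- list(
    package = "nirsbp",
    version = as.character(utils::packageVersion("nirsbp")),
    mode = config$mode,
    seed = config$sim$seed,
    sim_config = unclass(config$sim),
    analysis_params = unclass(config$params))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = 9, pretty = TRUE)
}

#' Read a session from CSV files
#'
#' Validates schemas (`nirs`: `time_s,ch1_od_w1,ch1_od_w2`; `bp`:
#' `time_s,pressure_mmHg`; `schedule`: `onset_s,duration_ms,movement`),
#' rejects non-finite samples naming the offending row, requires uniform
#' timestamps (1e-6 s tolerance) and strictly increasing, non-overlapping
#' onsets (spacing > 12.5 s), and drops (with a warning) trials whose epoch
#' window exceeds the recording.
#'
#' @param paths named list: `nirs`, `bp`, `schedule`, `age_years`,
#'   `nirs_mode` (`"deep"` or `"shallow"`).
#' @return list with `nirs` (a [raw_optical_recording()]), `pressure`
#'   (a [pressure_recording()]) and `schedule`.
#' @export
read_session <- function(paths) {
  need <- c("nirs", "bp", "schedule", "age_years", "nirs_mode")
  if (!all(need %in% names(paths)))
    stop("paths must contain: ", paste(need, collapse = ", "))
  for (f in c("nirs", "bp", "schedule"))
    if (!file.exists(paths[[f]])) stop("input file not found: ", paths[[f]])

  check_finite <- function(df, file) {
    for (cl in names(df)) {
      bad <- which(!is.finite(df[[cl]]) & !is.logical(df[[cl]]))
      if (length(bad) > 0)
        stop(sprintf("%s: non-finite value in column '%s' at data row %d",
                     file, cl, bad[1]))
    }
  }

  bp <- read.csv(paths$bp)
  if (!all(c("time_s", "pressure_mmHg") %in% names(bp)))
    stop("pressure CSV must have columns time_s,pressure_mmHg")
  check_finite(bp, paths$bp)
  pressure <- pressure_recording(bp$time_s, bp$pressure_mmHg)

  nr <- read.csv(paths$nirs)
  if (!("time_s" %in% names(nr)) ||
      !any(grepl("_od_w1$", names(nr))) || !any(grepl("_od_w2$", names(nr))))
    stop("NIRS CSV must have columns time_s and <ch>_od_w1,<ch>_od_w2")
  check_finite(nr, paths$nirs)
  sep <- if (paths$nirs_mode == "deep") 4.0 else
         if (paths$nirs_mode == "shallow") 1.0 else
         stop("nirs_mode must be 'deep' or 'shallow'")
  geom <- optical_geometry(separation_cm = sep,
                           age_years = paths$age_years)
  nirs <- raw_optical_recording(nr$time_s,
                                nr[, setdiff(names(nr), "time_s"),
                                   drop = FALSE],
                                geometry = geom)

  sch <- read.csv(paths$schedule)
  if (!all(c("onset_s", "duration_ms", "movement") %in% names(sch)))
    stop("schedule CSV must have columns onset_s,duration_ms,movement")
  sch$movement <- as.logical(sch$movement)
  if (is.unsorted(sch$onset_s, strictly = TRUE))
    stop("schedule onsets must be strictly increasing")
  if (nrow(sch) > 1 && min(diff(sch$onset_s)) <= 12.5)
    stop("overlapping epochs: onset spacing must exceed 12.5 s")
  t_end <- min(max(nr$time_s), max(bp$time_s))
  inside <- sch$onset_s - 0.5 >= 0 & sch$onset_s + 12 <= t_end
  if (any(!inside)) {
    warning(sprintf("%d trial(s) excluded: epoch window outside recording",
                    sum(!inside)))
    sch <- sch[inside, , drop = FALSE]
  }
  schedule <- structure(sch, class = c("trial_schedule", "data.frame"))
  list(nirs = nirs, pressure = pressure, schedule = schedule)
}
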