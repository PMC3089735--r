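#' Continuous finger arterial-pressure recording
#'
#' Container for a volume-clamp (Finometer-type) pressure waveform. Values
#' outside a physiological sanity range are logged with a warning (not an
#' error) so hardware glitches can be audited upstream.
#'
#' @param time_s uniformly sampled time axis (s).
#' @param pressure_mmHg waveform (mmHg).
#' @param sanity_range_mmHg plausibility bounds, default `c(20, 300)`.
#' @return object of class `pressure_recording` with an `fs_hz` field.
#' @export
pressure_recording <- function(time_s, pressure_mmHg,
                               sanity_range_mmHg = c(20, 300)) {
  stopifnot(length(time_s) == length(pressure_mmHg))
  check_uniform_time(time_s)
  bad <- which(pressure_mmHg < sanity_range_mmHg[1] |
               pressure_mmHg > sanity_range_mmHg[2])
  if (length(bad) > 0)
    warning(sprintf("%d pressure sample(s) outside [%g, %g] mmHg (first at row %d)",
                    length(bad), sanity_range_mmHg[1], sanity_range_mmHg[2],
                    bad[1]))
  fs <- if (length(time_s) > 1) 1 / (time_s[2] - time_s[1]) else NA_real_
  structure(list(time_s = time_s, pressure_mmHg = pressure_mmHg,
                 fs_hz = fs),
            class = "pressure_recording")
}

# candidate local maxima indices with scipy-style topographic prominence
local_peaks <- function(x, prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  core <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  keep <- logical(length(core))
  for (j in seq_along(core)) {
    i <- core[j]; h <- x[i]
    l <- i - 1L; lmin <- x[i]
    while (l >= 1L && x[l] <= h) { if (x[l] < lmin) lmin <- x[l]; l <- l - 1L }
    r <- i + 1L; rmin <- x[i]
    while (r <= n && x[r] <= h) { if (x[r] < rmin) rmin <- x[r]; r <- r + 1L }
    keep[j] <- (h - max(lmin, rmin)) >= prominence
  }
  core[keep]
}

#' Detect heart beats by peak picking
#'
#' Finds systolic peaks as local maxima of the (already low-pass filtered)
#' pressure waveform exceeding a prominence threshold and separated by at
#' least a refractory period (secondary dicrotic bumps inside the refractory
#' window are suppressed, keeping the higher peak). The diastolic trough of a
#' beat is the waveform minimum between consecutive systolic peaks, so the
#' first and last partial beats carry no trough and are dropped.
#'
#' @param rec a [pressure_recording()], low-pass filtered at 10 Hz upstream.
#' @param refractory_s minimum systolic peak separation (s); default 0.3
#'   (= 200 bpm ceiling).
#' @param prominence_mmHg minimum peak prominence (mmHg); default 5.
#' @return object of class `beat_series`: data.frame with one row per complete
#'   beat and columns `systolic_time_s`, `sbp_mmHg`, `diastolic_time_s`,
#'   `dbp_mmHg`, `map_mmHg` (NA until [map_from_beats()]).
#' @export
detect_beats <- function(rec, refractory_s = 0.3, prominence_mmHg = 5) {
  stopifnot(inherits(rec, "pressure_recording"))
  x <- rec$pressure_mmHg
  cand <- local_peaks(x, prominence_mmHg)
  if (length(cand) >= 2) {
    # greedy refractory enforcement: keep higher peaks first
    ord <- cand[order(x[cand], decreasing = TRUE)]
    kept <- numeric(0)
    refr <- refractory_s * rec$fs_hz
    for (i in ord)
      if (!length(kept) || min(abs(kept - i)) >= refr) kept <- c(kept, i)
    peaks <- sort(kept)
  } else peaks <- cand
  if (length(peaks) < 2)
    stop("fewer than 2 systolic peaks found; check prominence/filtering")
  # diastolic trough between consecutive systolic peaks; beat k is anchored at
  # the systolic peak k+1 with the trough preceding it
  nb <- length(peaks) - 1L
  sys_i <- integer(nb); dia_i <- integer(nb)
  for (k in seq_len(nb)) {
    seg <- peaks[k]:peaks[k + 1]
    dia_i[k] <- seg[which.min(x[seg])]
    sys_i[k] <- peaks[k + 1]
  }
  ibi <- diff(rec$time_s[peaks])
  out_of_range <- ibi < 0.3 | ibi > 2.0
  if (any(out_of_range))
    warning(sprintf("%d inter-beat interval(s) outside [0.3, 2] s",
                    sum(out_of_range)))
  beats <- data.frame(
    systolic_time_s = rec$time_s[sys_i],
    sbp_mmHg = x[sys_i],
    diastolic_time_s = rec$time_s[dia_i],
    dbp_mmHg = x[dia_i],
    map_mmHg = NA_real_)
  structure(beats, class = c("beat_series", "data.frame"))
}

#' Fill per-beat mean arterial pressure
#'
#' Two MAP definitions are offered: `waveform_mean` (default) integrates the
#' actual waveform over the beat, from this beat's diastolic trough to the
#' next one (the last beat, lacking a following trough, is dropped);
#' `onethird` uses the cuff-era approximation `DBP + (SBP - DBP) / 3` and
#' needs no waveform.
#'
#' @param beats a [detect_beats()] result.
#' @param rec the source [pressure_recording()] (required for
#'   `waveform_mean`).
#' @param method `"waveform_mean"` or `"onethird"`.
#' @return the beat series with `map_mmHg` filled.
#' @export
map_from_beats <- function(beats, rec = NULL,
                           method = c("waveform_mean", "onethird")) {
  method <- match.arg(method)
  stopifnot(inherits(beats, "beat_series"))
  if (method == "onethird") {
    beats$map_mmHg <- beats$dbp_mmHg + (beats$sbp_mmHg - beats$dbp_mmHg) / 3
    return(beats)
  }
  if (is.null(rec)) stop("waveform_mean MAP requires the pressure recording")
  nb <- nrow(beats)
  if (nb < 2) stop("waveform_mean MAP needs at least 2 complete beats")
  di <- round(beats$diastolic_time_s * rec$fs_hz) + 1L
  map <- rep(NA_real_, nb)
  for (k in seq_len(nb - 1L))
    map[k] <- mean(rec$pressure_mmHg[di[k]:(di[k + 1] - 1L)])
  beats$map_mmHg <- map
  beats <- beats[!is.na(map), , drop = FALSE]
  structure(beats, class = c("beat_series", "data.frame"))
}

#' Resample beat series to a uniform grid
#'
#' Linear interpolation of the per-beat SBP/DBP/MAP values onto a uniform
#' time grid (each series interpolated at its own anchor times: systolic peak
#' for SBP, diastolic trough for DBP and MAP); held constant beyond the first
#' and last beat. This turns the beat-wise series into ordinary uniformly
#' sampled signals that can be detrended and epoched like NIRS traces.
#'
#' @param beats a [beat_series][detect_beats()] with MAP filled (unless only
#'   SBP/DBP are needed).
#' @param fs_out_hz output sampling rate (Hz).
#' @param t_range output range `c(t0, t1)`; default spans the recording of the
#'   beats.
#' @return data.frame `time_s`, `sbp_mmHg`, `dbp_mmHg`, `map_mmHg`.
#' @export
beats_to_continuous <- function(beats, fs_out_hz, t_range = NULL) {
  stopifnot(inherits(beats, "beat_series"), nrow(beats) >= 2)
  if (is.null(t_range))
    t_range <- c(0, max(beats$systolic_time_s, beats$diastolic_time_s))
  grid <- seq(t_range[1], t_range[2], by = 1 / fs_out_hz)
  interp <- function(tt, v) approx(tt, v, xout = grid, rule = 2)$y
  data.frame(
    time_s = grid,
    sbp_mmHg = interp(beats$systolic_time_s, beats$sbp_mmHg),
    dbp_mmHg = interp(beats$diastolic_time_s, beats$dbp_mmHg),
    map_mmHg = if (all(is.na(beats$map_mmHg))) NA_real_
               else interp(beats$diastolic_time_s, beats$map_mmHg))
}
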