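# -- filtering ---------------------------------------------------------------

# coefficients of polynomial with given roots, descending powers, real part
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  Re(p)
}

#' Digital Butterworth low-pass coefficients
#'
#' Designs an order-`order` Butterworth low-pass filter by bilinear transform
#' of the analog prototype (frequency pre-warped), returning transfer-function
#' coefficients `b` (numerator) and `a` (denominator) in descending powers of
#' `z^-1`, normalized to unit DC gain.
#'
#' @param order filter order (>= 1); the package default low-pass is order 4.
#' @param cutoff_hz -3 dB cutoff frequency (Hz), `0 < cutoff < fs/2`.
#' @param fs_hz sampling rate (Hz).
#' @return list with numeric vectors `b` and `a`.
#' @export
butter_lowpass <- function(order, cutoff_hz, fs_hz) {
  stopifnot(order >= 1, fs_hz > 0)
  if (!(cutoff_hz > 0 && cutoff_hz < fs_hz / 2))
    stop("cutoff must satisfy 0 < cutoff < fs/2 (Nyquist)")
  warped <- 2 * fs_hz * tan(pi * cutoff_hz / fs_hz)
  k <- seq_len(order)
  p_analog <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2 * fs_hz
  p_z <- (fs2 + p_analog) / (fs2 - p_analog)
  a <- poly_from_roots(p_z)
  b <- poly_from_roots(rep(-1 + 0i, order))
  b <- b * sum(a) / sum(b)   # H(z = 1) = 1
  list(b = b, a = a)
}

# steady-state initial filter state for a unit-amplitude step input
# (direct-form-II-transposed state), so filtering a constant is transient-free
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  a <- c(a, rep(0, nf - length(a)))
  b <- c(b, rep(0, nf - length(b)))
  b <- b / a[1]
  a <- a / a[1]
  n <- nf - 1
  if (n == 0) return(numeric(0))
  A <- matrix(0, n, n)
  A[1, ] <- -a[-1]
  if (n > 1) A[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(A), B)
}

# zero-phase (forward-backward) application of an IIR filter, with
# odd-reflection padding and steady-state edge initial conditions
filtfilt_ba <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  nf <- max(length(a), length(b))
  if (is.null(padlen)) padlen <- 3 * nf
  padlen <- min(padlen, n - 1)
  if (padlen > 0) {
    ext <- c(2 * x[1] - x[(padlen + 1):2],
             x,
             2 * x[n] - x[(n - 1):(n - padlen)])
  } else {
    ext <- x
  }
  zi <- lfilter_zi(b, a)
  y <- lfilter_cpp(b, a, ext, zi * ext[1])
  y <- rev(lfilter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth low-pass applied forward and backward (zero phase):
#' the effective magnitude response is the square of the single-pass response
#' and peak latencies are preserved, which matters because response latency is
#' a primary outcome measure. DC gain is 1.
#'
#' @param x numeric signal vector.
#' @param fs_hz sampling rate (Hz).
#' @param cutoff_hz cutoff (Hz); 1 Hz for NIRS traces, 10 Hz for the pressure
#'   waveform in the default analysis.
#' @param order filter order for the single pass (default 4).
#' @return filtered signal, same length.
#' @export
lowpass <- function(x, fs_hz, cutoff_hz, order = 4) {
  ba <- butter_lowpass(order, cutoff_hz, fs_hz)
  # pad generously relative to the filter time constant so narrowband edge
  # transients die out before the retained segment
  padlen <- max(3 * (order + 1), ceiling(3 * fs_hz / cutoff_hz))
  filtfilt_ba(ba$b, ba$a, x, padlen = padlen)
}

# -- detrending --------------------------------------------------------------

#' Polynomial detrend
#'
#' Fits a least-squares polynomial of the given degree to the whole trace
#' (time rescaled to [-1, 1] for conditioning) and subtracts it. With the
#' default degree 5 this removes slow instrumental and physiological drift
#' while leaving event-related responses (tens of seconds) intact.
#'
#' @param x numeric signal vector, length > degree + 1.
#' @param degree polynomial degree (default 5).
#' @return detrended signal (residuals; mean ~ 0).
#' @export
detrend_poly <- function(x, degree = 5) {
  n <- length(x)
  if (n <= degree + 1) stop("signal too short for degree-", degree, " detrend")
  u <- seq(-1, 1, length.out = n)
  X <- outer(u, 0:degree, `^`)
  fit <- stats::.lm.fit(X, x)
  x - drop(X %*% fit$coefficients)
}

# -- epoching ----------------------------------------------------------------

#' Extract time-locked, baseline-corrected epochs
#'
#' Cuts the signal into per-trial windows relative to stimulus onsets under a
#' half-open sample convention `[onset + w0, onset + w1)` (the onset sample is
#' included at t = 0; at 50 Hz a [-0.5, 12) window has 625 samples), then
#' subtracts each epoch's mean over the baseline window. Onsets whose window
#' would leave the recording are dropped with a warning, not an error.
#'
#' @param x numeric signal vector.
#' @param fs_hz sampling rate (Hz); the signal is assumed to start at t = 0.
#' @param onsets_s stimulus onset times (s).
#' @param window_s epoch window `c(start, end)` relative to onset (default
#'   `c(-0.5, 12)`).
#' @param baseline_s baseline window (default `c(-0.5, 0)`, half-open).
#' @param conditions optional per-trial condition labels (factor or character).
#' @param signal_name,units labels carried in the result.
#' @return an object of class `epoch_set`: list with `data` (trials x samples
#'   matrix), `time_s` (relative axis), `conditions`, `rejected` (logical),
#'   `dropped_onsets`, `baseline_s`, `fs_hz`, `signal_name`, `units`.
#' @export
epoch_signal <- function(x, fs_hz, onsets_s, window_s = c(-0.5, 12),
                         baseline_s = c(-0.5, 0), conditions = NULL,
                         signal_name = "signal", units = "") {
  stopifnot(window_s[2] > window_s[1])
  n <- length(x)
  nsamp <- round((window_s[2] - window_s[1]) * fs_hz)
  rel_t <- window_s[1] + (seq_len(nsamp) - 1) / fs_hz
  if (!is.null(conditions)) stopifnot(length(conditions) == length(onsets_s))

  i0 <- round((onsets_s + window_s[1]) * fs_hz) + 1L  # 1-based start index
  ok <- i0 >= 1L & (i0 + nsamp - 1L) <= n
  if (any(!ok))
    warning(sprintf("%d trial(s) dropped: epoch window outside recording (onsets: %s)",
                    sum(!ok), paste(fmt_num(onsets_s[!ok]), collapse = ", ")))
  keep <- which(ok)
  if (length(keep) == 0) stop("no epoch lies fully inside the recording")
  mat <- t(vapply(keep, function(j) x[i0[j]:(i0[j] + nsamp - 1L)],
                  numeric(nsamp)))
  bl <- rel_t >= baseline_s[1] & rel_t < baseline_s[2]
  if (!any(bl)) stop("baseline window contains no samples")
  mat <- mat - rowMeans(mat[, bl, drop = FALSE])
  structure(
    list(data = mat, time_s = rel_t,
         conditions = if (is.null(conditions)) NULL else
           as.factor(conditions[keep]),
         onsets_s = onsets_s[keep],
         rejected = rep(FALSE, length(keep)),
         dropped_onsets = onsets_s[!ok],
         baseline_s = baseline_s, fs_hz = fs_hz,
         signal_name = signal_name, units = units),
    class = "epoch_set")
}

#' Mark outlier epochs (k-SD criterion)
#'
#' For each condition cell (or the whole set when no conditions are attached),
#' computes every epoch's peak absolute deviation from baseline, then marks as
#' rejected any epoch whose statistic falls outside `mean +/- k * SD` of that
#' cell's statistics. Mean and SD include the candidate epoch; the pass is
#' single and deterministic (it is not re-applied to the survivors). If a
#' cell's SD is zero nothing is rejected there.
#'
#' @param ep an [epoch_signal()] result.
#' @param k rejection threshold in SD units (default 3).
#' @return the epoch set with an updated `rejected` mask and a
#'   `rejection_log` data.frame (per-epoch statistic and decision).
#' @export
reject_outliers <- function(ep, k = 3) {
  stopifnot(inherits(ep, "epoch_set"))
  if (nrow(ep$data) < 3) stop("need at least 3 epochs for outlier rejection")
  stat <- apply(abs(ep$data), 1, max)
  cells <- if (is.null(ep$conditions)) factor(rep("all", nrow(ep$data)))
           else ep$conditions
  rejected <- rep(FALSE, length(stat))
  for (cell in levels(cells)) {
    i <- which(cells == cell)
    m <- mean(stat[i]); s <- sd(stat[i])
    if (is.finite(s) && s > 0)
      rejected[i] <- abs(stat[i] - m) > k * s
  }
  ep$rejected <- rejected
  ep$rejection_log <- data.frame(
    epoch = seq_along(stat),
    condition = as.character(cells),
    peak_abs_deviation = stat,
    rejected = rejected)
  ep
}

#' Condition-wise average time-courses
#'
#' Sample-wise mean and SD across non-rejected epochs, per condition cell.
#'
#' @param ep an [epoch_signal()] result (after optional [reject_outliers()]).
#' @return list with `time_s`, `mean` and `sd` (cells x samples matrices with
#'   cell rownames) and `n` (surviving trial count per cell).
#' @export
average_by_condition <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  cells <- if (is.null(ep$conditions)) factor(rep("all", nrow(ep$data)))
           else ep$conditions
  lv <- levels(cells)
  mu <- matrix(NA_real_, length(lv), ncol(ep$data), dimnames = list(lv, NULL))
  sdev <- mu
  n <- setNames(integer(length(lv)), lv)
  for (cell in lv) {
    i <- which(cells == cell & !ep$rejected)
    if (length(i) == 0)
      stop("no surviving epoch in condition cell '", cell, "'")
    n[cell] <- length(i)
    mu[cell, ] <- colMeans(ep$data[i, , drop = FALSE])
    sdev[cell, ] <- if (length(i) > 1) apply(ep$data[i, , drop = FALSE], 2, sd)
                    else rep(0, ncol(ep$data))
  }
  list(time_s = ep$time_s, mean = mu, sd = sdev, n = n)
}
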