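#' Response amplitude and latency of an epoch
#'
#' The response amplitude is the extremum of the baseline-corrected epoch over
#' the post-onset window `(0, end]`, signed and relative to the pre-stimulus
#' baseline; the latency is the time of that extremum after onset. `polarity`
#' selects the maximum (conventional for O2Hb), the minimum (HHb), or `auto`
#' (whichever has the larger absolute value). Ties are broken by the earliest
#' time. A perfectly flat epoch returns amplitude 0 with `latency_s = NA` and
#' `flat = TRUE`.
#'
#' @param x baseline-corrected epoch values.
#' @param time_s time axis relative to onset, same length.
#' @param polarity `"max"`, `"min"` or `"auto"`.
#' @return list of class `response_metrics`: `amplitude`, `latency_s`,
#'   `polarity`, `flat`, `search_window_s`.
#' @export
response_metrics <- function(x, time_s, polarity = c("auto", "max", "min")) {
  polarity <- match.arg(polarity)
  stopifnot(length(x) == length(time_s))
  post <- which(time_s > 0)
  if (length(post) == 0) stop("no post-onset samples in epoch")
  xp <- x[post]; tp <- time_s[post]
  if (max(xp) == min(xp) && max(xp) == 0) {
    return(structure(list(amplitude = 0, latency_s = NA_real_,
                          polarity = polarity, flat = TRUE,
                          search_window_s = range(tp)),
                     class = "response_metrics"))
  }
  i_max <- which.max(xp)  # which.max/min already take the earliest tie
  i_min <- which.min(xp)
  pol <- polarity
  if (pol == "auto")
    pol <- if (abs(xp[i_max]) >= abs(xp[i_min])) "max" else "min"
  i <- if (pol == "max") i_max else i_min
  structure(list(amplitude = xp[i], latency_s = tp[i], polarity = pol,
                 flat = FALSE, search_window_s = range(tp)),
            class = "response_metrics")
}

stat_result <- function(label, t, df, p, means, sds, ns, degenerate = FALSE) {
  structure(list(comparison = label, t = t, df = df, p = p,
                 means = means, sds = sds, ns = ns, degenerate = degenerate),
            class = "stat_result")
}

#' One-sample t-test against zero
#'
#' Classic one-sample t-test (`df = n - 1`, two-sided p). With zero sample
#' variance the statistic is reported as `+/-Inf` with `p = 0` and a
#' `degenerate` flag (plus a warning) rather than erroring, so automated
#' sweeps over null simulations keep running.
#'
#' @param values numeric sample, `n >= 2`.
#' @param mu null value (default 0).
#' @param label comparison label carried into the result.
#' @return a `stat_result` list: `t`, `df`, `p`, `means`, `sds`, `ns`.
#' @export
one_sample_t <- function(values, mu = 0, label = "one-sample") {
  n <- length(values)
  if (n < 2) stop("need n >= 2")
  if (sd(values) == 0) {
    if (mean(values) == mu) {
      warning("zero variance and mean equal to mu: t undefined, reported as 0")
      return(stat_result(label, 0, n - 1, 1, mean(values), 0, n,
                         degenerate = TRUE))
    }
    warning("zero variance: t reported as +/-Inf with p = 0")
    return(stat_result(label, sign(mean(values) - mu) * Inf, n - 1, 0,
                       mean(values), 0, n, degenerate = TRUE))
  }
  ht <- t.test(values, mu = mu)
  stat_result(label, unname(ht$statistic), unname(ht$parameter),
              ht$p.value, mean(values), sd(values), n)
}

#' Two-sample t-test
#'
#' Unpaired: pooled-variance (classic equal-variance) t with
#' `df = n1 + n2 - 2`. Paired: one-sample t on the differences. Zero pooled
#' variance (or zero-variance differences) is flagged as in [one_sample_t()].
#'
#' @param a,b numeric samples (`n >= 2` each; equal lengths when paired).
#' @param paired logical.
#' @param label comparison label.
#' @return a `stat_result` list.
#' @export
two_sample_t <- function(a, b, paired = FALSE, label = "two-sample") {
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    res <- one_sample_t(a - b, mu = 0, label = label)
    res$means <- c(mean(a), mean(b))
    res$sds <- c(sd(a), sd(b))
    res$ns <- c(length(a), length(b))
    return(res)
  }
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 in each group")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    d <- mean(a) - mean(b)
    if (d == 0) {
      warning("zero pooled variance and equal means: t reported as 0")
      return(stat_result(label, 0, length(a) + length(b) - 2, 1,
                         c(mean(a), mean(b)), c(0, 0),
                         c(length(a), length(b)), degenerate = TRUE))
    }
    warning("zero pooled variance: t reported as +/-Inf with p = 0")
    return(stat_result(label, sign(d) * Inf, length(a) + length(b) - 2, 0,
                       c(mean(a), mean(b)), c(0, 0),
                       c(length(a), length(b)), degenerate = TRUE))
  }
  ht <- t.test(a, b, var.equal = TRUE)
  stat_result(label, unname(ht$statistic), unname(ht$parameter), ht$p.value,
              c(mean(a), mean(b)), c(sd(a), sd(b)),
              c(length(a), length(b)))
}

#' Planned comparisons over the 2 x 2 design
#'
#' Runs the three pre-specified contrasts — (1) 1500 vs 3000 ms stimulus
#' persistency on no-movement trials, (2) the same on arm-raised trials, and
#' (3) all arm-raised vs all no-movement trials — separately for response
#' amplitude and latency, using unpaired two-sample t-tests (set
#' `paired = TRUE` for the within-subject variant). The per-test critical
#' alpha is `family_alpha / 3` (Bonferroni), displayed rounded to 3 decimals
#' but applied unrounded for the significance flag.
#'
#' @param metrics data.frame with one row per trial and columns
#'   `duration_ms`, `movement`, `amplitude`, `latency_s`.
#' @param family_alpha family-wise error rate (default 0.05, giving a
#'   displayed critical alpha of 0.017).
#' @param paired use paired t-tests (requires matched orderings).
#' @return data.frame of class `planned_comparisons` with columns `contrast`,
#'   `measure`, `t`, `df`, `p`, `mean_1`, `mean_2`, `significant`; attributes
#'   `crit_alpha` (unrounded) and `crit_alpha_display`.
#' @export
planned_comparisons <- function(metrics, family_alpha = 0.05,
                                paired = FALSE) {
  need <- c("duration_ms", "movement", "amplitude", "latency_s")
  if (!all(need %in% names(metrics)))
    stop("metrics must have columns: ", paste(need, collapse = ", "))
  cells <- list(
    `1500_nomove` = metrics$duration_ms == 1500 & !metrics$movement,
    `3000_nomove` = metrics$duration_ms == 3000 & !metrics$movement,
    `1500_move` = metrics$duration_ms == 1500 & metrics$movement,
    `3000_move` = metrics$duration_ms == 3000 & metrics$movement)
  for (cell in names(cells))
    if (!any(cells[[cell]]))
      stop("condition cell '", cell, "' is empty")
  contrasts <- list(
    duration_nomove = list(a = cells$`1500_nomove`, b = cells$`3000_nomove`),
    duration_move = list(a = cells$`1500_move`, b = cells$`3000_move`),
    move_vs_nomove = list(a = metrics$movement, b = !metrics$movement))
  crit <- family_alpha / 3
  rows <- list()
  for (cn in names(contrasts)) {
    for (measure in c("amplitude", "latency_s")) {
      va <- metrics[[measure]][contrasts[[cn]]$a]
      vb <- metrics[[measure]][contrasts[[cn]]$b]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      if (length(va) < 2 || length(vb) < 2) {
        # undefined measure in a group (e.g. latency of all-flat epochs):
        # report an NA row rather than aborting the whole family
        rows[[length(rows) + 1]] <- data.frame(
          contrast = cn, measure = measure, t = NA_real_, df = NA_real_,
          p = NA_real_, mean_1 = NA_real_, mean_2 = NA_real_,
          significant = FALSE)
        next
      }
      res <- two_sample_t(va, vb, paired = paired,
                          label = paste(cn, measure, sep = ":"))
      rows[[length(rows) + 1]] <- data.frame(
        contrast = cn, measure = measure,
        t = res$t, df = res$df, p = res$p,
        mean_1 = res$means[1], mean_2 = res$means[2],
        significant = is.finite(res$p) & res$p < crit)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("planned_comparisons", "data.frame"),
            crit_alpha = crit,
            crit_alpha_display = round(crit, 3))
}

#' Coupling regression between a NIRS trace and MAP
#'
#' Ordinary least-squares regression of the condition-averaged NIRS epoch on
#' the condition-averaged MAP epoch, point-wise across the shared time window
#' (the overlap of the NIRS `[-0.5, 12)` and pressure `[-0.5, 10)` epochs by
#' default). The slope is in signal units per mmHg; `r` is the Pearson
#' correlation with its two-sided p-value.
#'
#' @param nirs,nirs_time_s NIRS mean-epoch values and relative time axis.
#' @param map,map_time_s MAP mean-epoch values and relative time axis.
#' @param window_s shared window; default `c(-0.5, 10)`.
#' @return list of class `regression_result`: `slope`, `intercept`, `r`, `p`,
#'   `n`.
#' @export
coupling_regression <- function(nirs, nirs_time_s, map, map_time_s,
                                window_s = c(-0.5, 10)) {
  stopifnot(length(nirs) == length(nirs_time_s),
            length(map) == length(map_time_s))
  keep_n <- nirs_time_s >= window_s[1] & nirs_time_s < window_s[2]
  tt <- nirs_time_s[keep_n]
  y <- nirs[keep_n]
  x <- approx(map_time_s, map, xout = tt, rule = 2)$y
  if (length(y) < 3) stop("need at least 3 shared time points")
  if (sd(x) == 0) stop("constant MAP regressor: correlation undefined")
  if (sd(y) == 0) stop("constant NIRS trace: correlation undefined")
  fit <- lm(y ~ x)
  ct <- suppressWarnings(cor.test(x, y))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = unname(ct$estimate), p = ct$p.value, n = length(y)),
            class = "regression_result")
}
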