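test_that("response_metrics finds the signed extremum and its latency", {
  fs <- 50
  tt <- seq(-0.5, 12 - 1 / fs, by = 1 / fs)
  pulse <- 0.4 * nirsbp:::gamma_bump(tt, 6.0, 10)
  m <- response_metrics(pulse, tt, "max")
  expect_equal(m$amplitude, 0.4, tolerance = 1e-6)
  expect_equal(m$latency_s, 6.0, tolerance = 1 / fs)
  # negated pulse with polarity = min: amplitude -0.4, same latency
  m2 <- response_metrics(-pulse, tt, "min")
  expect_equal(m2$amplitude, -0.4, tolerance = 1e-6)
  expect_equal(m2$latency_s, 6.0, tolerance = 1 / fs)
  # auto picks the larger |extremum|
  expect_equal(response_metrics(-pulse, tt, "auto")$polarity, "min")
  # pulse + slow ramp: latency matches a brute-force argmax oracle
  y <- pulse + 0.01 * tt
  post <- tt > 0
  brute_t <- tt[post][which.max(y[post])]
  expect_equal(response_metrics(y, tt, "max")$latency_s, brute_t)
  # flat epoch: amplitude 0, latency flagged undefined
  mf <- response_metrics(numeric(length(tt)), tt)
  expect_equal(mf$amplitude, 0)
  expect_true(is.na(mf$latency_s))
  expect_true(mf$flat)
})

test_that("one- and two-sample t-tests match closed-form oracles and handle degeneracy", {
  # symmetric about zero -> t = 0, p = 1
  r <- one_sample_t(c(-2, -1, 0, 1, 2))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # hand-picked n = 5 vs mean/(sd/sqrt(n))
  x <- c(0.3, 1.1, -0.4, 0.8, 0.6)
  r2 <- one_sample_t(x)
  o <- oracle_one_sample_t(x)
  expect_equal(r2$t, o$t, tolerance = 1e-12)
  expect_equal(r2$df, o$df)
  expect_equal(r2$p, o$p, tolerance = 1e-12)
  # constant nonzero values: infinite-t branch, flagged
  expect_warning(rc <- one_sample_t(c(2, 2, 2)), "Inf")
  expect_true(is.infinite(rc$t) && rc$t > 0 && rc$p == 0 && rc$degenerate)
  expect_error(one_sample_t(1), "n >= 2")

  # identical groups -> t = 0
  g <- c(1, 2, 3, 4)
  expect_equal(two_sample_t(g, g)$t, 0)
  # pooled formula on two small hand-built groups
  a <- c(1.2, 0.8, 1.5, 0.9)
  b <- c(0.4, 0.7, 0.2, 0.6, 0.5)
  r3 <- two_sample_t(a, b)
  o3 <- oracle_pooled_t(a, b)
  expect_equal(r3$t, o3$t, tolerance = 1e-12)
  expect_equal(r3$df, o3$df)
  expect_equal(r3$p, o3$p, tolerance = 1e-12)
  # paired mode on (x, x + c): zero-variance differences -> +/-Inf branch
  expect_warning(rp <- two_sample_t(g + 1, g, paired = TRUE), "Inf")
  expect_true(is.infinite(rp$t) && rp$degenerate)
})

test_that("test statistics agree with closed forms on random small samples", {
  set.seed(99)
  for (i in 1:200) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    a <- rnorm(n1, sd = stats::runif(1, 0.5, 3))
    b <- rnorm(n2, mean = stats::runif(1, -1, 1))
    r1 <- one_sample_t(a); o1 <- oracle_one_sample_t(a)
    expect_equal(r1$t, o1$t, tolerance = 1e-10)
    expect_equal(r1$p, o1$p, tolerance = 1e-10)
    r2 <- two_sample_t(a, b); o2 <- oracle_pooled_t(a, b)
    expect_equal(r2$t, o2$t, tolerance = 1e-10)
    expect_equal(r2$p, o2$p, tolerance = 1e-10)
  }
})

test_that("planned_comparisons runs the three contrasts at alpha/3", {
  set.seed(4)
  metrics <- data.frame(
    duration_ms = rep(c(1500, 3000), each = 10, times = 2),
    movement = rep(c(FALSE, TRUE), each = 20),
    amplitude = rnorm(40, 0.3, 0.1),
    latency_s = rnorm(40, 8, 1))
  pc <- planned_comparisons(metrics, family_alpha = 0.05)
  expect_equal(attr(pc, "crit_alpha_display"), 0.017)
  expect_equal(attr(pc, "crit_alpha"), 0.05 / 3)
  expect_equal(nrow(pc), 6)   # 3 contrasts x {amplitude, latency}
  expect_setequal(unique(pc$contrast),
                  c("duration_nomove", "duration_move", "move_vs_nomove"))
  # same arithmetic at a different family alpha
  expect_equal(attr(planned_comparisons(metrics, family_alpha = 0.03),
                    "crit_alpha_display"), 0.010)
  # identical data in every cell: all contrasts t = 0, none significant
  same <- metrics
  same$amplitude <- rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 8)
  same$latency_s <- rep(c(7, 8, 9, 10, 11), 8)
  pc0 <- planned_comparisons(same)
  expect_true(all(abs(pc0$t) < 1e-12))
  expect_false(any(pc0$significant))
  # a missing cell is named
  expect_error(planned_comparisons(metrics[metrics$movement, ]),
               "1500_nomove|nomove")
})

test_that("coupling_regression matches the normal-equations oracle", {
  tt <- seq(-0.5, 10 - 0.02, by = 0.02)
  mapd <- 5 * nirsbp:::gamma_bump(tt, 5.3, 8)
  # exact affine relation: r = 1, slope = 2
  rr <- coupling_regression(2 * mapd + 1, tt, mapd, tt)
  expect_equal(rr$slope, 2, tolerance = 1e-9)
  expect_equal(rr$r, 1, tolerance = 1e-9)
  expect_equal(rr$intercept, 1, tolerance = 1e-9)
  # orthogonal signals over whole periods: r ~ 0
  t2 <- seq(0, 10 - 0.02, by = 0.02)
  ro <- coupling_regression(sin(2 * pi * 0.5 * t2), t2,
                            cos(2 * pi * 0.5 * t2), t2,
                            window_s = c(0, 10))
  expect_lt(abs(ro$r), 1e-6)
  # 20-point hand dataset vs normal equations
  set.seed(21)
  x <- rnorm(20); y <- 0.7 * x + rnorm(20, sd = 0.3)
  tt20 <- seq_len(20)
  rh <- coupling_regression(y, tt20, x, tt20, window_s = c(0, 21))
  oh <- oracle_regression(x, y)
  expect_equal(rh$slope, oh$slope, tolerance = 1e-10)
  expect_equal(rh$intercept, oh$intercept, tolerance = 1e-10)
  expect_equal(rh$r, oh$r, tolerance = 1e-10)
  expect_equal(rh$p, oh$p, tolerance = 1e-10)
  # constant regressor is rejected
  expect_error(coupling_regression(y, tt20, rep(1, 20), tt20,
                                   window_s = c(0, 21)), "constant")
})
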