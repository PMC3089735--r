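# shared fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# a small but complete simulated session (12 trials) for pipeline-level tests
small_config <- function(seed = 5, ...) {
  sim_config(seed = seed, n_per_condition = 3L, ...)
}

small_session <- function() cached("small_session",
                                   simulate_session(small_config()))

# default-config session (60 trials), used where the stated design matters
default_session <- function() cached("default_session",
                                     simulate_session(sim_config(seed = 1)))

ext_tab <- function() cached("ext_tab", extinction_table())
dpf_tab <- function() cached("dpf_tab", dpf_model())

# independent 2x2 solve by Cramer's rule (oracle for od_to_conc)
cramer_2x2 <- function(E, rhs) {
  det0 <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  c((rhs[1] * E[2, 2] - E[1, 2] * rhs[2]) / det0,
    (E[1, 1] * rhs[2] - rhs[1] * E[2, 1]) / det0)
}

# closed-form t-test oracles
oracle_one_sample_t <- function(x, mu = 0) {
  n <- length(x)
  t <- (mean(x) - mu) / (sd(x) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# normal-equations regression oracle
oracle_regression <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(slope = slope, intercept = intercept, r = r,
       p = 2 * pt(-abs(t), n - 2))
}

# digital filter magnitude response |H(e^{i 2 pi f / fs})| from (b, a)
filter_mag <- function(ba, f_hz, fs_hz) {
  z <- exp(-1i * 2 * pi * f_hz / fs_hz)
  npow <- function(coefs) vapply(seq_along(coefs) - 1,
                                 function(k) z^k, complex(1))
  Mod(sum(ba$b * npow(ba$b)) / sum(ba$a * npow(ba$a)))
}

dir_hashes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  vapply(files, function(f) paste(tools::md5sum(f)), character(1))
}
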