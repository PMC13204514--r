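# Independent brute-force oracles used to check the package's fast paths.
# Everything here is written from the defining formulas, not from the
# package internals.

# one-sided amplitude spectrum by direct DFT summation (mean-removed)
oracle_dft <- function(x, tr) {
  n <- length(x)
  x <- x - mean(x)
  K <- n %/% 2
  t <- 0:(n - 1)
  amp <- pwr <- numeric(K)
  for (k in seq_len(K)) {
    re <- sum(x * cos(2 * pi * k * t / n))
    im <- sum(x * sin(2 * pi * k * t / n))
    fac <- if (n %% 2 == 0 && k == K) 1 else 2
    amp[k] <- fac * sqrt(re^2 + im^2) / n
    pwr[k] <- fac * (re^2 + im^2) / n^2
  }
  list(amp = amp, pwr = pwr, freq = seq_len(K) / (n * tr))
}

# Kendall's W from the rank-sum formula with tie correction
oracle_kendall_w <- function(X) {
  n <- nrow(X)
  k <- ncol(X)
  R <- apply(X, 2, rank)
  Ri <- rowSums(R)
  S <- sum((Ri - mean(Ri))^2)
  Tj <- sum(apply(X, 2, function(col) {
    tt <- table(col)
    sum(tt^3 - tt)
  }))
  12 * S / (k^2 * (n^3 - n) - k * Tj)
}

# paired t-test from the difference vector's mean and SD
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  tval <- mean(d) / (sd(d) / sqrt(n))
  list(t = tval, p = 2 * pt(-abs(tval), n - 1))
}

# OLS slope / p / R^2 from the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% b
  n <- length(x)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  tval <- b[2] / se
  list(slope = b[2], p = 2 * pt(-abs(tval), n - 2),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# direct-formula raw statistics
oracle_raw_stats <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  rms <- sqrt(mean(x^2))
  peak <- max(abs(x))
  list(mean = m,
       rms = rms,
       sd = sqrt(sum((x - m)^2) / (n - 1)),
       skewness = mean((x - m)^3) / m2^1.5,
       kurtosis = mean((x - m)^4) / m2^2,
       peak_value = peak,
       minimum = min(x), median = median(x), maximum = max(x),
       q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)),
       iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
       crest_factor = peak / rms,
       impulse_factor = peak / mean(abs(x)),
       clearance_factor = peak / mean(sqrt(abs(x)))^2,
       shape_factor = rms / mean(abs(x)))
}

# a random non-constant window fixture
make_window <- function(T = 64, k = 3, tr = 2, seed = 1) {
  set.seed(seed)
  timeseries_window(matrix(rnorm(T * k), T, k), sampling_interval = tr)
}

# a small, fast cohort config for structural tests (args override defaults)
tiny_config <- function(...) {
  args <- list(n_subjects = 3, n_runs_per_visit = 2, n_frames = 32,
               grid_shape = c(16, 16, 16), n_chronic_completers = 3,
               seed = 11)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}
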