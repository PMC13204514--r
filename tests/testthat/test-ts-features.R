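# Per-window feature extraction: registry, defining examples, oracle
# agreement and invariance properties.

test_that("feature registry has 85 unique names in fixed groups", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 85)
  expect_equal(anyDuplicated(reg$name), 0)
  sizes <- table(reg$group)
  expect_equal(unname(sizes["raw_signal"]), 19)
  expect_equal(unname(sizes["power_spectrum"]), 3)
  expect_equal(unname(sizes["signal_envelope"]), 13)
  expect_equal(unname(sizes["envelope_spectrum"]), 3)
  expect_equal(unname(sizes["ar_fit"]), 9)
  expect_equal(unname(sizes["detrended"]), 20)
  expect_equal(unname(sizes["detrended_ar"]), 10)
  expect_equal(unname(sizes["literature"]), 8)
  expect_equal(sum(sizes) - unname(sizes["literature"]), 77)
})

test_that("raw-signal features match their defining formulas", {
  # degenerate constant input: factors with nonzero denominators come out 1
  const <- raw_signal_features(rep(1, 8))
  expect_equal(unname(const["raw_mean"]), 1)
  expect_equal(unname(const["raw_sd"]), 0)
  expect_equal(unname(const["raw_crest_factor"]), 1)
  expect_equal(unname(const["raw_skewness"]), 0) # zero-denominator sentinel

  alt <- raw_signal_features(rep(c(-1, 1), 6))
  expect_equal(unname(alt["raw_mean"]), 0)
  expect_equal(unname(alt["raw_rms"]), 1)
  expect_equal(unname(alt["raw_peak_value"]), 1)

  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(40, sd = runif(1, 0.5, 3))
    got <- raw_signal_features(x)
    want <- oracle_raw_stats(x)
    for (nm in names(want))
      expect_equal(unname(got[paste0("raw_", nm)]), unname(want[[nm]]),
                   tolerance = 1e-10, label = nm)
  }
  expect_error(raw_signal_features(rep(1, 4)), "at least 8")
})

test_that("power spectrum recovers an on-bin sinusoid exactly", {
  T <- 123; tr <- 2
  for (k in c(3, 7, 20)) {
    A <- runif(1, 0.5, 4)
    x <- A * sin(2 * pi * k * (0:(T - 1)) / T + runif(1, 0, 2 * pi)) + 5
    ps <- power_spectrum_features(x, tr)
    expect_equal(unname(ps["spec_peak_amp"]), A, tolerance = 1e-6)
    expect_equal(unname(ps["spec_peak_freq"]), k / (T * tr), tolerance = 1e-12)
    expect_equal(unname(ps["spec_power"]), A^2 / 2, tolerance = 1e-6)
  }
  # highest admissible frequency is Nyquist = 0.25 Hz at TR = 2 s
  ny <- power_spectrum_features(rnorm(124), 2)
  expect_lte(unname(ny["spec_peak_freq"]), 0.25)

  z <- power_spectrum_features(rep(2, 16), 2)
  expect_equal(unname(z["spec_power"]), 0)
  expect_equal(unname(z["spec_peak_amp"]), 0)
  expect_equal(unname(z["spec_peak_freq"]), 1 / (16 * 2)) # lowest bin
})

test_that("adding a sinusoid to noise raises the spectral peak", {
  set.seed(42)
  T <- 123
  noise <- rnorm(T)
  withsig <- noise + 2 * sin(2 * pi * 10 * (0:(T - 1)) / T)
  expect_gt(power_spectrum_features(withsig, 2)["spec_peak_amp"],
            power_spectrum_features(noise, 2)["spec_peak_amp"])
})

test_that("spectral estimates agree with a brute-force DFT oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(32)
    sp <- strokefuse:::.amp_spectrum(matrix(x), tr = 2)
    or <- oracle_dft(x, 2)
    expect_equal(as.numeric(sp$amp), or$amp, tolerance = 1e-8)
    expect_equal(as.numeric(sp$pwr), or$pwr, tolerance = 1e-8)
    expect_equal(sp$freq, or$freq)
  }
})

test_that("envelope features behave like an analytic-signal envelope", {
  T <- 123; tr <- 2
  # AM signal: envelope spectrum peaks at the modulation frequency
  km <- 4; kc <- 30
  t <- 0:(T - 1)
  x <- (1 + 0.5 * cos(2 * pi * km * t / T)) * cos(2 * pi * kc * t / T)
  ef <- envelope_features(x, tr)
  expect_equal(unname(ef["envspec_peak_freq"]), km / (T * tr),
               tolerance = 1e-12)

  const <- envelope_features(rep(3, 16))
  expect_equal(unname(const["env_sd"]), 0)

  # the envelope bounds the (mean-removed) series pointwise
  set.seed(2)
  y <- rnorm(64, mean = 5)
  env <- strokefuse:::.envelope(matrix(y))
  expect_true(all(env >= abs(y - mean(y)) - 1e-10))
})

test_that("autoregressive features track temporal structure", {
  set.seed(3)
  T <- 200
  x <- as.numeric(arima.sim(list(ar = 0.9), T))
  af <- ar_features(x)
  perm <- sample(x)
  af_perm <- ar_features(perm)
  expect_lt(af["ar_aic"], af_perm["ar_aic"])

  wn <- rnorm(T)
  expect_lt(abs(ar_features(wn)["ar_first_coef"]), 3 / sqrt(T))

  # near-noiseless AR(1): residual MSE goes to 0 with the innovation scale
  x0 <- as.numeric(stats::filter(rnorm(T, sd = 1e-5), 0.9, "recursive"))
  expect_lt(ar_features(x0)["ar_mse"], 1e-8)

  expect_error(ar_features(rnorm(9), max_order = 8), "length")
})

test_that("detrending is an exact projection", {
  t <- 1:40
  lin <- 2 + 0.5 * t
  dv <- detrended_variants(lin)
  expect_lt(abs(dv["dt_maximum"]), 1e-10)
  expect_lt(abs(dv["dt_rms"]), 1e-10)

  set.seed(4)
  x <- rnorm(50) + 0.3 * (1:50)
  d1 <- strokefuse:::.detrend(matrix(x))
  d2 <- strokefuse:::.detrend(d1)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-10)

  # detrended features of x equal raw features of the line-removed series
  line <- lm(x ~ seq_along(x))
  resid <- unname(residuals(line))
  got <- detrended_variants(x)
  want <- raw_signal_features(resid)
  for (nm in c("mean", "rms", "sd", "peak_value", "q1", "iqr"))
    expect_equal(unname(got[paste0("dt_", nm)]),
                 unname(want[paste0("raw_", nm)]), tolerance = 1e-10)
})

test_that("literature features: bands, concordance, and the W oracle", {
  T <- 123; tr <- 2
  t <- 0:(T - 1)
  # pure sinusoid at ~0.02 Hz: all band power in the low band
  x <- sin(2 * pi * 5 * t / T) # 5/(123*2) = 0.0203 Hz
  w <- timeseries_window(cbind(x, x + 1), tr)
  lf <- literature_features(w)
  expect_equal(unname(lf["lit_pratio_low"]), 1, tolerance = 1e-9)
  expect_equal(unname(lf["lit_pratio_mid"]), 0, tolerance = 1e-9)
  expect_equal(unname(lf["lit_pratio_high"]), 0, tolerance = 1e-9)

  # identical series: perfect concordance
  expect_equal(unname(lf["lit_kendall_w"]), 1, tolerance = 1e-12)
  expect_equal(unname(lf["lit_kendall_tau"]), 1, tolerance = 1e-12)

  # Kendall W against the brute-force rank-sum formula
  set.seed(9)
  X <- matrix(rnorm(123 * 27), 123, 27)
  w2 <- timeseries_window(X, tr)
  lf2 <- literature_features(w2)
  expect_equal(unname(lf2["lit_kendall_w"]), oracle_kendall_w(X),
               tolerance = 1e-12)
  # mean pairwise tau against stats::cor
  taus <- cor(X, method = "kendall")
  expect_equal(unname(lf2["lit_kendall_tau"]), mean(taus[lower.tri(taus)]),
               tolerance = 1e-12)

  expect_error(timeseries_window(matrix(rnorm(20), 20, 1)), "at least 2")
})

test_that("assembled feature vector is complete, ordered and reproducible", {
  w <- make_window(T = 123, k = 5, seed = 10)
  fv <- assemble_feature_vector(w)
  expect_length(fv, 85)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, assemble_feature_vector(w))
})

test_that("features are finite on many random non-constant windows", {
  set.seed(123)
  M <- matrix(rnorm(32 * 1000), 32, 1000)
  vl <- replicate(1000, matrix(rnorm(32 * 3), 32, 3), simplify = FALSE)
  vals <- strokefuse:::window_feature_matrix(M, vl, tr = 2)
  expect_true(all(is.finite(vals)))
})

test_that("features scale correctly under positive rescaling", {
  scale_by_c <- c("raw_mean", "raw_rms", "raw_sd", "raw_peak_value",
                  "spec_peak_amp", "lit_amp_low", "lit_amp_mid",
                  "lit_amp_high")
  invariant <- c("raw_crest_factor", "raw_impulse_factor",
                 "raw_clearance_factor", "raw_shape_factor", "raw_skewness",
                 "raw_kurtosis", "lit_pratio_low", "lit_pratio_mid",
                 "lit_pratio_high", "lit_kendall_w", "lit_kendall_tau")
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 3), 40, 3)
    cc <- runif(1, 0.1, 10)
    f1 <- assemble_feature_vector(timeseries_window(X, 2))
    f2 <- assemble_feature_vector(timeseries_window(cc * X, 2))
    expect_equal(unname(f2[scale_by_c]), unname(cc * f1[scale_by_c]),
                 tolerance = 1e-8)
    expect_equal(unname(f2[invariant]), unname(f1[invariant]),
                 tolerance = 1e-8)
  }
})

test_that("band definition validates ordering and Nyquist", {
  b <- band_definition(tr = 2)
  expect_equal(b$nyquist, 0.25)
  expect_error(band_definition(low = c(0.01, 0.05), mid = c(0.04, 0.08)),
               "ordered")
  expect_error(band_definition(high = c(0.08, 0.3), tr = 2), "Nyquist")
})
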