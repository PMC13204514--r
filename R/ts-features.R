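# Sliding-window time-series features.
#
# All heavy lifting is done by internal batched routines operating on a T x W
# matrix (T time points, W windows) so that whole runs are processed with a
# handful of matrix operations; the exported per-series functions are thin
# W = 1 wrappers around the same code path.

#' Nyquist frequency for a given repetition time
#'
#' @param tr sampling interval (repetition time) in seconds.
#' @return Highest resolvable frequency in Hz, `1 / (2 * tr)`.
#' @export
#' @examples
#' nyquist_frequency(2) # 0.25 Hz
nyquist_frequency <- function(tr) {
  stopifnot(is.numeric(tr), tr > 0)
  1 / (2 * tr)
}

#' Frequency bands for the literature rs-fMRI features
#'
#' Low (0.01-0.04 Hz), mid (0.04-0.08 Hz) and high (0.08-0.10 Hz) bands used
#' for the band-limited amplitude-of-fluctuation and power-ratio features.
#' Bands must be ordered, non-overlapping except at shared endpoints, and lie
#' below the Nyquist frequency.
#'
#' @param low,mid,high numeric length-2 band limits in Hz.
#' @param tr repetition time in seconds (for the Nyquist check).
#' @return A list with elements `low`, `mid`, `high`, `nyquist`.
#' @export
band_definition <- function(low = c(0.01, 0.04), mid = c(0.04, 0.08),
                            high = c(0.08, 0.10), tr = 2) {
  nyq <- nyquist_frequency(tr)
  bands <- list(low = low, mid = mid, high = high)
  for (b in bands) {
    if (length(b) != 2 || b[1] >= b[2])
      stop("each band must be an increasing pair of frequencies")
  }
  if (low[2] > mid[1] || mid[2] > high[1])
    stop("bands must be ordered and non-overlapping (shared endpoints allowed)")
  if (high[2] > nyq)
    stop("bands must lie below the Nyquist frequency ", nyq, " Hz")
  c(bands, list(nyquist = nyq))
}

#' Construct a sliding-window time-series bundle
#'
#' @param voxel_series numeric T x k matrix of the window's voxel time series
#'   (k >= 2; the minimum cluster size rule).
#' @param sampling_interval repetition time in seconds.
#' @param mean_series optional window-mean series; defaults to the row means
#'   of `voxel_series`.
#' @return An object of class `timeseries_window`.
#' @export
timeseries_window <- function(voxel_series, sampling_interval = 2,
                              mean_series = NULL) {
  voxel_series <- as.matrix(voxel_series)
  if (ncol(voxel_series) < 2)
    stop("a window needs at least 2 voxel series (minimum cluster size rule)")
  if (!all(is.finite(voxel_series))) stop("voxel series must be finite")
  if (is.null(mean_series)) mean_series <- rowMeans(voxel_series)
  structure(list(mean_series = as.numeric(mean_series),
                 voxel_series = voxel_series,
                 sampling_interval = sampling_interval),
            class = "timeseries_window")
}

# ---- internal batched primitives -------------------------------------------

# one-sided amplitude spectrum / periodogram of each column
.amp_spectrum <- function(M, tr, demean = TRUE) {
  n <- nrow(M)
  if (demean) M <- sweep(M, 2, colMeans(M))
  X <- stats::mvfft(M)
  K <- n %/% 2
  mod <- Mod(X[seq_len(K) + 1L, , drop = FALSE])
  fac <- rep(2, K)
  if (n %% 2 == 0) fac[K] <- 1 # Nyquist bin appears once
  amp <- mod * (fac / n)
  pwr <- (mod^2) * (fac / n^2)
  list(amp = amp, pwr = pwr, freq = seq_len(K) / (n * tr),
       total = colSums(pwr))
}

# SNR / SINAD / THD (dB) from a one-sided periodogram.
# Fundamental = largest line; harmonics = its integer multiples; noise = rest.
# Powers are floored at a relative epsilon so pure tones give large finite dB.
.snr_feats <- function(sp) {
  pwr <- sp$pwr
  W <- ncol(pwr)
  K <- nrow(pwr)
  snr <- sinad <- thd <- numeric(W)
  for (w in seq_len(W)) {
    p <- pwr[, w]
    tot <- sp$total[w]
    floorp <- tot * 1e-15 + .Machine$double.xmin
    kf <- which.max(p)
    ph_idx <- if (2L * kf <= K) seq(2L * kf, K, by = kf) else integer(0)
    pf <- max(p[kf], floorp)
    ph <- max(sum(p[ph_idx]), floorp)
    pn <- max(tot - p[kf] - sum(p[ph_idx]), floorp)
    snr[w] <- 10 * log10(pf / pn)
    sinad[w] <- 10 * log10(pf / (pn + ph))
    thd[w] <- 10 * log10(ph / pf)
  }
  list(snr = snr, sinad = sinad, thd = thd)
}

# the 19 distribution/shape statistics of one column set (+ spectral dB stats)
.stat_feats <- function(M, sp) {
  n <- nrow(M)
  cm <- colMeans(M)
  xc <- sweep(M, 2, cm)
  m2 <- colMeans(xc^2)
  m3 <- colMeans(xc^3)
  m4 <- colMeans(xc^4)
  rms <- sqrt(colMeans(M^2))
  absM <- abs(M)
  peak <- apply(absM, 2, max)
  mabs <- colMeans(absM)
  msqrt <- colMeans(sqrt(absM))
  qs <- apply(M, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE, type = 7)
  if (is.null(dim(qs))) qs <- matrix(qs, nrow = 3)
  dB <- .snr_feats(sp)
  list(mean = cm,
       rms = rms,
       sd = sqrt(colSums(xc^2) / (n - 1)),
       skewness = div0(m3, m2^1.5),
       kurtosis = div0(m4, m2^2),
       peak_value = peak,
       minimum = apply(M, 2, min),
       median = qs[2, ],
       maximum = apply(M, 2, max),
       q1 = qs[1, ],
       q3 = qs[3, ],
       iqr = qs[3, ] - qs[1, ],
       crest_factor = div0(peak, rms),
       impulse_factor = div0(peak, mabs),
       clearance_factor = div0(peak, msqrt^2),
       shape_factor = div0(rms, mabs),
       snr = dB$snr,
       sinad = dB$sinad,
       thd = dB$thd)
}

# analytic-signal magnitude envelope of each column's fluctuation (the mean
# is removed first: a baseline offset would otherwise dominate the analytic
# signal and reduce the envelope to the series itself)
.envelope <- function(M) {
  n <- nrow(M)
  M <- sweep(M, 2, colMeans(M))
  X <- stats::mvfft(M)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::mvfft(X * h, inverse = TRUE) / n)
}

# least-squares linear detrend of each column
.detrend <- function(M) {
  n <- nrow(M)
  X <- cbind(1, seq_len(n))
  M - X %*% solve(crossprod(X), crossprod(X, M))
}

# Burg AR fit of every column for orders 1..max_order; order selected by
# minimum AIC = n*ln(mean(e^2)) + 2*(order+1) with conditional residuals.
.ar_feats <- function(M, tr, max_order = 8, demean = TRUE) {
  n <- nrow(M)
  W <- ncol(M)
  p <- min(max_order, n - 3L)
  if (p < 1) stop("series too short for autoregressive fitting")
  if (demean) M <- sweep(M, 2, colMeans(M))

  coefs <- vector("list", p)
  resid <- vector("list", p)
  aic <- matrix(Inf, p, W)
  fe <- M[-1, , drop = FALSE]
  be <- M[-n, , drop = FALSE]
  for (m in seq_len(p)) {
    den <- colSums(fe^2) + colSums(be^2)
    k <- ifelse(den > 0, 2 * colSums(fe * be) / den, 0)
    if (m == 1) {
      coefs[[1]] <- matrix(k, 1, W)
    } else {
      prev <- coefs[[m - 1]]
      coefs[[m]] <- rbind(prev - sweep(prev[(m - 1):1, , drop = FALSE], 2, k, "*"), k)
    }
    # conditional one-step residuals of the order-m model
    e <- M[(m + 1):n, , drop = FALSE]
    for (i in seq_len(m))
      e <- e - sweep(M[(m + 1 - i):(n - i), , drop = FALSE], 2, coefs[[m]][i, ], "*")
    resid[[m]] <- e
    s2 <- pmax(colMeans(e^2), 1e-300)
    aic[m, ] <- n * log(s2) + 2 * (m + 1)
    if (m < p) {
      L <- nrow(fe)
      fe_new <- fe[-1, , drop = FALSE] - sweep(be[-1, , drop = FALSE], 2, k, "*")
      be <- be[-L, , drop = FALSE] - sweep(fe[-L, , drop = FALSE], 2, k, "*")
      fe <- fe_new
    }
  }

  sel <- apply(aic, 2, which.min)
  first_coef <- first_freq <- damping <- numeric(W)
  mse <- mae <- rmean <- rvar <- rrms <- rkurt <- numeric(W)
  aic_sel <- numeric(W)
  for (w in seq_len(W)) {
    m <- sel[w]
    phi <- coefs[[m]][, w]
    e <- resid[[m]][, w]
    first_coef[w] <- phi[1]
    aic_sel[w] <- aic[m, w]
    mse[w] <- mean(e^2)
    mae[w] <- mean(abs(e))
    rmean[w] <- mean(e)
    rvar[w] <- stats::var(e)
    rrms[w] <- sqrt(mean(e^2))
    m2 <- mean((e - mean(e))^2)
    rkurt[w] <- div0(mean((e - mean(e))^4), m2^2)
    # dominant pole: z^m - phi_1 z^(m-1) - ... - phi_m = 0
    r <- polyroot(c(-rev(phi), 1))
    r <- r[which.max(Mod(r))]
    if (Mod(r) < 1e-12) {
      first_freq[w] <- 0
      damping[w] <- 1
    } else {
      first_freq[w] <- abs(Arg(r)) / (2 * pi * tr)
      s <- log(r) / tr
      damping[w] <- if (Mod(s) < 1e-12) 0 else -Re(s) / Mod(s)
    }
  }
  list(first_coef = first_coef, first_freq = first_freq, damping = damping,
       mse = mse, mae = mae, aic = aic_sel, resid_mean = rmean,
       resid_var = rvar, resid_rms = rrms, resid_kurtosis = rkurt,
       order = sel)
}

# literature band features from a spectrum; bands follow [low, high) except
# the high band which includes its upper edge
.band_feats <- function(sp, bands) {
  f <- sp$freq
  in_low <- f >= bands$low[1] & f < bands$low[2]
  in_mid <- f >= bands$mid[1] & f < bands$mid[2]
  in_high <- f >= bands$high[1] & f <= bands$high[2]
  in_total <- f >= bands$low[1] & f <= bands$high[2]
  csum <- function(idx, X) if (any(idx)) colSums(X[idx, , drop = FALSE]) else
    numeric(ncol(X))
  tot <- csum(in_total, sp$pwr)
  list(amp_low = csum(in_low, sp$amp),
       amp_mid = csum(in_mid, sp$amp),
       amp_high = csum(in_high, sp$amp),
       pratio_low = div0(csum(in_low, sp$pwr), tot),
       pratio_mid = div0(csum(in_mid, sp$pwr), tot),
       pratio_high = div0(csum(in_high, sp$pwr), tot))
}

# full 85-column feature matrix for a batch of windows
# mean_mat: T x W window-mean series; vox_list: length-W list of T x k matrices
window_feature_matrix <- function(mean_mat, vox_list, tr,
                                  bands = band_definition(tr = tr),
                                  max_order = 8) {
  mean_mat <- as.matrix(mean_mat)
  W <- ncol(mean_mat)
  stopifnot(length(vox_list) == W)

  sp_raw <- .amp_spectrum(mean_mat, tr)
  raw <- .stat_feats(mean_mat, sp_raw)

  env <- .envelope(mean_mat)
  sp_env <- .amp_spectrum(env, tr)
  envs <- .stat_feats(env, sp_env)

  dt <- .detrend(mean_mat)
  sp_dt <- .amp_spectrum(dt, tr, demean = FALSE)
  dts <- .stat_feats(dt, sp_dt)

  ar <- .ar_feats(mean_mat, tr, max_order)
  dtar <- .ar_feats(dt, tr, max_order, demean = FALSE)
  lit <- .band_feats(sp_raw, bands)

  kw <- vapply(vox_list, cpp_kendall_w, numeric(1))
  kt <- vapply(vox_list, cpp_kendall_tau_mean, numeric(1))

  peak_freq <- function(sp) sp$freq[max.col(t(sp$amp), ties.method = "first")]
  stat_names <- c("mean", "rms", "sd", "skewness", "kurtosis", "peak_value",
                  "minimum", "median", "maximum", "q1", "q3", "iqr",
                  "crest_factor", "impulse_factor", "clearance_factor",
                  "shape_factor", "snr", "sinad", "thd")
  env_names <- c("mean", "rms", "sd", "skewness", "kurtosis", "peak_value",
                 "crest_factor", "impulse_factor", "clearance_factor",
                 "shape_factor", "snr", "sinad", "thd")
  ar_names <- c("first_coef", "first_freq", "mse", "mae", "aic", "resid_mean",
                "resid_var", "resid_rms", "resid_kurtosis")
  dtar_names <- c("first_coef", "first_freq", "damping", "mse", "mae", "aic",
                  "resid_mean", "resid_var", "resid_rms", "resid_kurtosis")

  out <- cbind(
    do.call(cbind, raw[stat_names]),
    spec_peak_amp = apply(sp_raw$amp, 2, max),
    spec_peak_freq = peak_freq(sp_raw),
    spec_power = sp_raw$total,
    do.call(cbind, envs[env_names]),
    envspec_peak_amp = apply(sp_env$amp, 2, max),
    envspec_peak_freq = peak_freq(sp_env),
    envspec_power = sp_env$total,
    do.call(cbind, ar[ar_names]),
    do.call(cbind, dts[stat_names]),
    dt_power = colMeans(sweep(dt, 2, colMeans(dt))^2),
    do.call(cbind, dtar[dtar_names]),
    lit_amp_low = lit$amp_low,
    lit_amp_mid = lit$amp_mid,
    lit_amp_high = lit$amp_high,
    lit_pratio_low = lit$pratio_low,
    lit_pratio_mid = lit$pratio_mid,
    lit_pratio_high = lit$pratio_high,
    lit_kendall_w = kw,
    lit_kendall_tau = kt)
  colnames(out) <- feature_names()
  out
}

# ---- exported per-series operations ----------------------------------------

.check_series <- function(series, min_len = 8) {
  series <- as.numeric(series)
  if (length(series) < min_len)
    stop("series must have at least ", min_len, " points")
  if (!all(is.finite(series))) stop("series must be finite")
  series
}

#' Raw-signal statistics of one series
#'
#' The 19 raw-signal metrics: mean, RMS, SD, skewness, kurtosis, peak value
#' (max absolute), minimum, median, maximum, Q1, Q3, IQR, crest factor,
#' impulse factor, clearance factor, shape factor, and the spectral SNR,
#' SINAD and THD in dB. Factors with a vanishing denominator (constant
#' series) are reported as 0.
#'
#' @param series numeric vector, length >= 8, finite.
#' @param sampling_interval repetition time in seconds (spectral dB metrics).
#' @return Named numeric vector (names `raw_*` in registry order).
#' @export
raw_signal_features <- function(series, sampling_interval = 2) {
  series <- .check_series(series)
  M <- matrix(series)
  sp <- .amp_spectrum(M, sampling_interval)
  st <- .stat_feats(M, sp)
  stats::setNames(vapply(st, `[`, numeric(1), 1),
                  feature_names("raw_signal"))
}

#' Power-spectrum features of one series
#'
#' One-sided amplitude spectrum of the mean-removed series (single-taper
#' periodogram, no zero padding): spectral peak amplitude over
#' 0 < f <= Nyquist, its frequency, and the total power (biased variance).
#' An all-constant series yields zero power, zero peak amplitude, and the
#' lowest frequency bin as peak frequency.
#'
#' @inheritParams raw_signal_features
#' @return Named numeric vector `spec_peak_amp`, `spec_peak_freq`,
#'   `spec_power`.
#' @export
power_spectrum_features <- function(series, sampling_interval = 2) {
  series <- .check_series(series)
  sp <- .amp_spectrum(matrix(series), sampling_interval)
  c(spec_peak_amp = max(sp$amp),
    spec_peak_freq = sp$freq[which.max(sp$amp)],
    spec_power = sp$total)
}

#' Signal-envelope features of one series
#'
#' Statistics of the analytic-signal magnitude envelope of the mean-removed
#' series (13 shape metrics) plus the envelope-spectrum peak amplitude, peak
#' frequency and power.
#'
#' @inheritParams raw_signal_features
#' @return Named numeric vector (`env_*` then `envspec_*`).
#' @export
envelope_features <- function(series, sampling_interval = 2) {
  series <- .check_series(series)
  env <- .envelope(matrix(series))
  sp <- .amp_spectrum(env, sampling_interval)
  st <- .stat_feats(env, sp)
  keep <- c("mean", "rms", "sd", "skewness", "kurtosis", "peak_value",
            "crest_factor", "impulse_factor", "clearance_factor",
            "shape_factor", "snr", "sinad", "thd")
  c(stats::setNames(vapply(st[keep], `[`, numeric(1), 1),
                    feature_names("signal_envelope")),
    envspec_peak_amp = max(sp$amp),
    envspec_peak_freq = sp$freq[which.max(sp$amp)],
    envspec_power = sp$total)
}

#' Autoregressive-fit features of one series
#'
#' Burg autoregressive fits of order 1..`max_order`; the order with minimum
#' AIC (`T * ln(mean(e^2)) + 2 * (order + 1)`, conditional residuals) is
#' selected. Returns the first AR coefficient, the dominant-pole frequency,
#' the damping ratio of the dominant pole, residual MSE/MAE, the AIC, and
#' residual mean/variance/RMS/kurtosis.
#'
#' @param series numeric vector with more than `max_order + 2` points.
#' @param max_order maximum AR order to consider (default 8).
#' @param sampling_interval repetition time in seconds.
#' @return Named numeric vector (`ar_*`, including `ar_damping`).
#' @export
ar_features <- function(series, max_order = 8, sampling_interval = 2) {
  series <- as.numeric(series)
  if (length(series) <= max_order + 2)
    stop("series length must exceed max_order + 2")
  if (!all(is.finite(series))) stop("series must be finite")
  ar <- .ar_feats(matrix(series), sampling_interval, max_order)
  nm <- c("first_coef", "first_freq", "damping", "mse", "mae", "aic",
          "resid_mean", "resid_var", "resid_rms", "resid_kurtosis")
  stats::setNames(vapply(ar[nm], `[`, numeric(1), 1), paste0("ar_", nm))
}

#' Linearly de-trended feature variants
#'
#' Subtracts the least-squares line and re-applies the raw-signal statistic
#' set (plus the de-trended signal power) and the autoregressive feature set
#' (including the dominant-pole damping ratio) to the residual.
#'
#' @inheritParams ar_features
#' @return Named numeric vector (`dt_*` then `dtar_*`, 30 entries).
#' @export
detrended_variants <- function(series, max_order = 8, sampling_interval = 2) {
  series <- .check_series(series)
  dt <- .detrend(matrix(series))
  sp <- .amp_spectrum(dt, sampling_interval, demean = FALSE)
  st <- .stat_feats(dt, sp)
  stat_names <- c("mean", "rms", "sd", "skewness", "kurtosis", "peak_value",
                  "minimum", "median", "maximum", "q1", "q3", "iqr",
                  "crest_factor", "impulse_factor", "clearance_factor",
                  "shape_factor", "snr", "sinad", "thd")
  ar <- .ar_feats(dt, sampling_interval, max_order, demean = FALSE)
  dtar_names <- c("first_coef", "first_freq", "damping", "mse", "mae", "aic",
                  "resid_mean", "resid_var", "resid_rms", "resid_kurtosis")
  c(stats::setNames(vapply(st[stat_names], `[`, numeric(1), 1),
                    paste0("dt_", stat_names)),
    dt_power = mean((dt - mean(dt))^2),
    stats::setNames(vapply(ar[dtar_names], `[`, numeric(1), 1),
                    paste0("dtar_", dtar_names)))
}

#' Literature rs-fMRI features of one window
#'
#' Six band features of the window-mean series (band amplitude = sum of
#' amplitude-spectrum bins in the band; band power ratio = band power over
#' total 0.01-0.10 Hz power) plus two concordance features across the
#' window's voxel series: Kendall's coefficient of concordance W and the mean
#' pairwise Kendall tau-b.
#'
#' @param window a [timeseries_window()].
#' @param bands a [band_definition()].
#' @return Named numeric vector (`lit_*`, 8 entries).
#' @export
literature_features <- function(window,
                                bands = band_definition(tr = window$sampling_interval)) {
  stopifnot(inherits(window, "timeseries_window"))
  if (ncol(window$voxel_series) < 2)
    stop("concordance features need at least 2 voxel series")
  sp <- .amp_spectrum(matrix(window$mean_series), window$sampling_interval)
  bf <- .band_feats(sp, bands)
  c(lit_amp_low = bf$amp_low, lit_amp_mid = bf$amp_mid,
    lit_amp_high = bf$amp_high,
    lit_pratio_low = bf$pratio_low, lit_pratio_mid = bf$pratio_mid,
    lit_pratio_high = bf$pratio_high,
    lit_kendall_w = cpp_kendall_w(window$voxel_series),
    lit_kendall_tau = cpp_kendall_tau_mean(window$voxel_series))
}

#' Assemble the full 85-entry feature vector of one window
#'
#' Concatenates all seven automated metric groups and the literature group in
#' canonical registry order.
#'
#' @inheritParams literature_features
#' @param max_order maximum AR order (default 8).
#' @return Named numeric vector of length 85, names equal to
#'   [feature_names()].
#' @export
assemble_feature_vector <- function(window,
                                    bands = band_definition(tr = window$sampling_interval),
                                    max_order = 8) {
  stopifnot(inherits(window, "timeseries_window"))
  out <- window_feature_matrix(matrix(window$mean_series),
                               list(window$voxel_series),
                               window$sampling_interval, bands, max_order)
  stats::setNames(as.numeric(out[1, ]), colnames(out))
}
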