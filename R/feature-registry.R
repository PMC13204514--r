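#' The 85-entry rs-fMRI feature registry
#'
#' Fixed, ordered catalogue of every feature emitted per sliding window: 77
#' automated signal-processing metrics in seven groups (raw signal, power
#' spectrum, signal envelope, envelope spectrum, autoregressive fit, linearly
#' de-trended, de-trended + autoregressive) plus 8 literature rs-fMRI features
#' (band-limited amplitudes of fluctuation, band power ratios, Kendall W and
#' mean pairwise Kendall tau). The registry order is the canonical feature
#' order everywhere in the package and breaks ties in Fisher ranking.
#'
#' @return A data.frame with columns `name`, `group`, `formula` (a short
#'   human-readable definition), one row per feature, in canonical order.
#' @export
#' @examples
#' nrow(feature_registry())  # 85
#' table(feature_registry()$group)
feature_registry <- function() {
  stat19 <- function(prefix, on) {
    data.frame(
      name = paste0(prefix, c(
        "mean", "rms", "sd", "skewness", "kurtosis", "peak_value",
        "minimum", "median", "maximum", "q1", "q3", "iqr",
        "crest_factor", "impulse_factor", "clearance_factor", "shape_factor",
        "snr", "sinad", "thd")),
      formula = c(
        paste0("mean(", on, ")"),
        paste0("sqrt(mean(", on, "^2))"),
        paste0("sd(", on, ") (n-1 denominator)"),
        "m3/m2^1.5 (moment skewness)",
        "m4/m2^2 (non-excess kurtosis)",
        paste0("max(|", on, "|)"),
        paste0("min(", on, ")"),
        paste0("median(", on, ")"),
        paste0("max(", on, ")"),
        "25% quantile (type 7)", "75% quantile (type 7)", "Q3 - Q1",
        "peak/RMS", "peak/mean(|x|)", "peak/(mean(sqrt(|x|)))^2",
        "RMS/mean(|x|)",
        "10*log10(P_fund/P_noise) dB", "10*log10(P_fund/(P_noise+P_harm)) dB",
        "10*log10(P_harm/P_fund) dB"),
      stringsAsFactors = FALSE)
  }
  spec3 <- function(prefix, on) data.frame(
    name = paste0(prefix, c("peak_amp", "peak_freq", "power")),
    formula = c(
      paste0("max one-sided amplitude spectrum of ", on, " (0 < f <= Nyquist)"),
      "frequency (Hz) of the spectral peak",
      paste0("mean((", on, " - mean)^2), total periodogram power")),
    stringsAsFactors = FALSE)
  ar9 <- function(prefix, on) data.frame(
    name = paste0(prefix, c("first_coef", "first_freq", "mse", "mae", "aic",
                            "resid_mean", "resid_var", "resid_rms",
                            "resid_kurtosis")),
    formula = c(
      paste0("phi_1 of min-AIC Burg AR fit to ", on),
      "dominant-pole frequency (Hz) of the selected AR model",
      "mean squared one-step residual", "mean absolute one-step residual",
      "T*ln(mean(e^2)) + 2*(order+1)",
      "mean residual", "residual variance", "residual RMS",
      "residual non-excess kurtosis"),
    stringsAsFactors = FALSE)

  raw <- stat19("raw_", "x")
  raw$group <- "raw_signal"
  sp <- spec3("spec_", "x")
  sp$group <- "power_spectrum"
  env <- stat19("env_", "envelope")[c(1:6, 13:19), ] # 13: no min/median/max/Q1/Q3/IQR
  env$group <- "signal_envelope"
  es <- spec3("envspec_", "envelope")
  es$group <- "envelope_spectrum"
  ar <- ar9("ar_", "x")
  ar$group <- "ar_fit"
  dt <- stat19("dt_", "detrended x")
  dt <- rbind(dt, data.frame(name = "dt_power",
                             formula = "mean(detrended x ^2), signal power",
                             stringsAsFactors = FALSE))
  dt$group <- "detrended"
  dtar <- ar9("dtar_", "detrended x")
  dtar <- rbind(dtar[1:2, ],
                data.frame(name = "dtar_damping",
                           formula = "damping ratio of the dominant AR pole",
                           stringsAsFactors = FALSE),
                dtar[3:9, ])
  dtar$group <- "detrended_ar"
  lit <- data.frame(
    name = c("lit_amp_low", "lit_amp_mid", "lit_amp_high",
             "lit_pratio_low", "lit_pratio_mid", "lit_pratio_high",
             "lit_kendall_w", "lit_kendall_tau"),
    formula = c(
      "sum of amplitude-spectrum bins, 0.01-0.04 Hz",
      "sum of amplitude-spectrum bins, 0.04-0.08 Hz",
      "sum of amplitude-spectrum bins, 0.08-0.10 Hz",
      "band power / total 0.01-0.10 Hz power (low band)",
      "band power / total 0.01-0.10 Hz power (mid band)",
      "band power / total 0.01-0.10 Hz power (high band)",
      "Kendall coefficient of concordance across window voxel series",
      "mean pairwise Kendall tau-b across window voxel series"),
    stringsAsFactors = FALSE)
  lit$group <- "literature"

  out <- rbind(raw, sp, env, es, ar, dt, dtar, lit)
  rownames(out) <- NULL
  out[, c("name", "group", "formula")]
}

#' Canonical feature names
#'
#' @param group optional group label to subset by.
#' @return Character vector of feature names in registry order.
#' @export
feature_names <- function(group = NULL) {
  reg <- feature_registry()
  if (!is.null(group)) reg <- reg[reg$group %in% group, ]
  reg$name
}

#' Export the feature registry as JSON
#'
#' Writes the name/group/formula catalogue so downstream consumers can map
#' feature columns without loading the package.
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry_json <- function(path) {
  jsonlite::write_json(feature_registry(), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
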