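# Spectral estimation of cardiac and respiratory gradient components.
#
# Each accepted 6-minute window is Fourier-transformed; the single-sided
# amplitude spectrum is normalised so a stationary sinusoid of amplitude a
# appears as a peak of height a at its frequency (resolution 1/360 Hz).
# Components above the low-pass cutoff (15 Hz) are zeroed. A decreasing
# exponential fitted to the low-frequency floor — energy injected below
# 0.1 Hz by slow drift and small posture changes — is subtracted before the
# band peaks are read off: the cardiac amplitude is the maximum in
# 0.7-1.6 Hz (42-96 beats/min) and the respiratory amplitude the maximum in
# 0.15-0.4 Hz (9-24 breaths/min).

#' Spectral analysis configuration
#'
#' @param lowpass_cutoff Hz; spectral components above this are zeroed
#'   (default 15).
#' @param cardiac_band,resp_band closed frequency bands, Hz; must be
#'   disjoint and below the cutoff.
#' @param lowfreq_threshold Hz; energy below this is regarded as drift
#'   (default 0.1).
#' @param calibration_C multiplier applied to extracted band-peak
#'   amplitudes. With this package's amplitude normalisation a stationary
#'   sinusoid is recovered exactly at `C = 1` (the default); the clinical
#'   pipeline this reproduces used a heuristic `C = 7` to map its
#'   power-spectrum peaks to raw-signal scale. `C` cancels in every
#'   cardiac/respiratory ratio.
#' @return object of class `spectral_config`.
#' @export
spectral_config <- function(lowpass_cutoff = 15,
                            cardiac_band = c(0.7, 1.6),
                            resp_band = c(0.15, 0.4),
                            lowfreq_threshold = 0.1,
                            calibration_C = 1.0) {
  stopifnot(length(cardiac_band) == 2, length(resp_band) == 2,
            cardiac_band[1] < cardiac_band[2], resp_band[1] < resp_band[2],
            calibration_C > 0)
  if (resp_band[2] >= cardiac_band[1])
    stop("spectral_config: bands must be disjoint with the respiratory ",
         "band below the cardiac band")
  if (lowpass_cutoff <= cardiac_band[2])
    stop("spectral_config: lowpass_cutoff must lie above the cardiac band")
  structure(list(lowpass_cutoff = lowpass_cutoff,
                 cardiac_band = cardiac_band, resp_band = resp_band,
                 lowfreq_threshold = lowfreq_threshold,
                 calibration_C = calibration_C),
            class = "spectral_config")
}

#' Single-sided amplitude spectrum of a gradient window
#'
#' FFT-based amplitude spectrum normalised so a pure sinusoid of amplitude
#' `a` whose frequency falls on a bin yields a peak of height `a`
#' (`2 |X_k| / N` for positive frequencies). The DC bin is excluded
#' (windows are zero-mean). Bins above the low-pass cutoff are zeroed.
#'
#' @param window a `gradient_window` from [extract_windows()], or any list
#'   with fields `dicp` and `sampling_rate`.
#' @param config a [spectral_config()].
#' @return data.frame with columns `freq_Hz` and `amplitude` (same units as
#'   the input series, mmHg/m), frequency resolution `1/duration` Hz.
#' @export
amplitude_spectrum <- function(window, config = spectral_config()) {
  x <- window$dicp
  fs <- window$sampling_rate
  if (any(!is.finite(x))) stop("amplitude_spectrum: series contains ",
                               "non-finite samples")
  n <- length(x)
  X <- stats::fft(x)
  k <- seq_len(floor(n / 2))              # positive frequencies, DC excluded
  freq <- k * fs / n
  amp <- 2 * Mod(X[k + 1]) / n
  amp[freq > config$lowpass_cutoff] <- 0
  data.frame(freq_Hz = freq, amplitude = amp)
}

#' Remove the low-frequency exponential trend from a spectrum
#'
#' Fits a decreasing exponential `A exp(-b f)` (`A, b >= 0`) to the
#' spectrum over the bins below the cardiac band, excluding the respiratory
#' band (so genuine respiratory peaks do not inflate the fitted floor), and
#' subtracts the fitted curve over the whole axis, clamping negative results
#' to zero. The fit is linear least squares on log-amplitudes of the
#' positive bins; if too few positive bins exist or the fit fails, the
#' spectrum is returned unchanged with a warning. Because drift slightly
#' overlaps the respiratory band, the respiratory amplitude is if anything
#' conservatively (under-) estimated by this correction.
#'
#' @param spectrum data.frame from [amplitude_spectrum()].
#' @param config a [spectral_config()].
#' @return data.frame of the same shape with corrected `amplitude`.
#' @export
remove_lowfreq_trend <- function(spectrum, config = spectral_config()) {
  f <- spectrum$freq_Hz
  a <- spectrum$amplitude
  fit_idx <- f < config$cardiac_band[1] &
    !(f >= config$resp_band[1] & f <= config$resp_band[2]) & a > 0
  if (sum(fit_idx) < 3) {
    if (any(spectrum$amplitude > 0))
      warning("remove_lowfreq_trend: too few positive low-frequency bins; ",
              "spectrum returned unchanged")
    return(spectrum)
  }
  fit <- tryCatch(stats::lm.fit(cbind(1, f[fit_idx]), log(a[fit_idx])),
                  error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients))) {
    warning("remove_lowfreq_trend: trend fit failed; spectrum returned ",
            "unchanged")
    return(spectrum)
  }
  A <- exp(fit$coefficients[1])
  b <- -fit$coefficients[2]
  if (b < 0) b <- 0                       # constrained to a decreasing trend
  corrected <- pmax(a - A * exp(-b * f), 0)
  corrected[a == 0] <- 0
  spectrum$amplitude <- corrected
  spectrum
}

#' Extract cardiac and respiratory band peaks
#'
#' Locates the maximum bin inside the closed cardiac and respiratory bands
#' of a (trend-corrected) amplitude spectrum; ties break toward the lower
#' frequency. Peak amplitudes are multiplied by the calibration factor `C`.
#' A band whose maximum is zero is flagged (`*_found = FALSE`) and reported
#' with amplitude 0.
#'
#' @param spectrum data.frame from [amplitude_spectrum()] /
#'   [remove_lowfreq_trend()].
#' @param config a [spectral_config()].
#' @param window_ref identifier carried through to the summary.
#' @return object of class `spectrum_summary`: list with `f0_cardiac`,
#'   `a0_cardiac`, `cardiac_found`, `f1_resp`, `a1_resp`, `resp_found`,
#'   `calibration_C`, `window_ref`. Amplitudes in mmHg/m.
#' @export
extract_band_peaks <- function(spectrum, config = spectral_config(),
                               window_ref = NA) {
  tol <- 1e-9 * max(spectrum$amplitude)   # numerical zero, not FFT round-off
  peak_in <- function(band) {
    idx <- which(spectrum$freq_Hz >= band[1] & spectrum$freq_Hz <= band[2])
    if (length(idx) == 0) return(list(f = NA_real_, a = 0, found = FALSE))
    a <- spectrum$amplitude[idx]
    j <- idx[which.max(a)]                # which.max -> first = lowest freq
    found <- spectrum$amplitude[j] > tol
    list(f = spectrum$freq_Hz[j],
         a = if (found) spectrum$amplitude[j] else 0,
         found = found)
  }
  pc <- peak_in(config$cardiac_band)
  pr <- peak_in(config$resp_band)
  structure(list(
    f0_cardiac = pc$f,
    a0_cardiac = pc$a * config$calibration_C,
    cardiac_found = pc$found,
    f1_resp = pr$f,
    a1_resp = pr$a * config$calibration_C,
    resp_found = pr$found,
    calibration_C = config$calibration_C,
    window_ref = window_ref), class = "spectrum_summary")
}

#' Full spectral analysis of one window
#'
#' Convenience chain: [amplitude_spectrum()], [remove_lowfreq_trend()],
#' [extract_band_peaks()].
#'
#' @param window a `gradient_window`.
#' @param config a [spectral_config()].
#' @return a `spectrum_summary`.
#' @export
analyze_window <- function(window, config = spectral_config()) {
  sp <- amplitude_spectrum(window, config)
  sp <- remove_lowfreq_trend(sp, config)
  extract_band_peaks(sp, config,
                     window_ref = paste0(window$patient_id, ":",
                                         window$window_index))
}
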