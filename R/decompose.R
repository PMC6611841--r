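# Peak/valley decomposition of an arbitrary flow-rate series into cardiac
# and respiratory components.
#
# The cardiac oscillation rides on the slower respiratory one, so the
# midpoints (Qp + Qv)/2 of successive peak/valley pairs of Q(t) trace the
# respiratory component. The respiratory interpolant through those
# midpoints is realised as the mean of the peak and valley envelopes
# (pointwise it passes through the per-pair midpoints), refined by a second
# pass on the remainder; the cardiac component is Q_c = Q - Q_r. PVFs are
# (max - min)/2 of each component, and per-cycle volumes are the
# trapezoidal integral of |Q_i|/2 between the first and last peak of the
# component divided by the number of full cycles.
#
# The construction requires the cardiac extrema to be visible throughout:
# when the respiratory slope exceeds the cardiac slope amplitude the
# composite is locally monotone, extrema vanish, and the decomposition
# degrades (a warning is emitted when peak spacing becomes irregular).

# Alternating local extrema of y, pruned so that every retained
# peak/valley pair differs by at least prominence_frac * range(y).
find_extrema <- function(y, prominence_frac = 0.1) {
  n <- length(y)
  if (n < 3) return(list(peaks = integer(0), valleys = integer(0)))
  d <- sign(diff(y))
  idx <- which(d != 0)                    # collapse flats
  if (length(idx) < 2) return(list(peaks = integer(0), valleys = integer(0)))
  turns <- idx[which(diff(d[idx]) != 0)] + 1L
  if (length(turns) == 0)
    return(list(peaks = integer(0), valleys = integer(0)))
  kind <- ifelse(y[turns] >= y[pmax(turns - 1L, 1L)], 1L, -1L)
  thresh <- prominence_frac * (max(y) - min(y))
  keep <- seq_along(turns)
  repeat {                                # drop smallest adjacent swings
    if (length(keep) < 2) break
    dy <- abs(diff(y[turns[keep]]))
    j <- which.min(dy)
    if (dy[j] >= thresh) break
    keep <- keep[-c(j, j + 1L)]
  }
  turns <- turns[keep]; kind <- kind[keep]
  if (length(turns) > 1) {                # restore alternation
    sel <- logical(length(turns)); sel[1] <- TRUE
    last <- 1L
    for (i in seq_along(turns)[-1]) {
      if (kind[i] != kind[last]) { sel[i] <- TRUE; last <- i }
      else if ((kind[i] == 1L && y[turns[i]] > y[turns[last]]) ||
               (kind[i] == -1L && y[turns[i]] < y[turns[last]])) {
        sel[last] <- FALSE; sel[i] <- TRUE; last <- i
      }
    }
    turns <- turns[sel]; kind <- kind[sel]
  }
  list(peaks = turns[kind == 1L], valleys = turns[kind == -1L])
}

# Mean of the peak and valley envelopes of y on grid t; envelopes are
# interpolants through the extrema, extended by constant values beyond the
# first/last extremum. Returns NULL if too few extrema.
envelope_mean <- function(t, y, prominence_frac, interpolant) {
  ex <- find_extrema(y, prominence_frac)
  if (length(ex$peaks) < 2 || length(ex$valleys) < 2) return(NULL)
  interp <- function(ki) {
    kt <- t[ki]; ky <- y[ki]
    s <- if (interpolant == "linear")
      stats::approx(kt, ky, xout = t, rule = 2)$y
    else stats::spline(kt, ky, xout = t, method = "natural")$y
    s[t < kt[1]] <- ky[1]
    s[t > kt[length(kt)]] <- ky[length(ky)]
    s
  }
  list(mean = (interp(ex$peaks) + interp(ex$valleys)) / 2,
       peaks = ex$peaks, valleys = ex$valleys,
       covered = range(t[sort(c(ex$peaks, ex$valleys))]))
}

#' Decompose a flow-rate series into cardiac and respiratory components
#'
#' Implements the peak/valley-midpoint procedure: all peaks and valleys of
#' `Q(t)` are located (local extrema, small swings below `prominence_frac`
#' of the series range pruned as noise); the respiratory component `Q_r(t)`
#' is the continuous interpolant through the peak/valley midpoints
#' `(Qp + Qv)/2`, realised as the mean of the peak and valley envelopes
#' (natural cubic spline by default, piecewise linear selectable; constant
#' extension beyond the outermost extrema) and refined by `n_sift - 1`
#' further passes on the remainder; the cardiac component is
#' `Q_c = Q - Q_r`. Component PVFs are `(max - min)/2` over the analysis
#' interval, which is intersected with the extremum-covered region so the
#' envelopes are never extrapolated.
#'
#' The construction assumes separated timescales with the cardiac
#' oscillation steep enough to produce extrema throughout; warnings are
#' emitted when the estimated cardiac/respiratory frequency ratio falls
#' below 2 and when irregular peak spacing suggests cardiac extrema are
#' swallowed by steep respiratory slopes.
#'
#' @param time seconds (uniform grid).
#' @param q flow rate, m^3/s (any consistent unit; outputs inherit it).
#' @param interval length-2 numeric analysis interval `[t0, t1]`; default
#'   the final 10 s of the series. The full series is always used to build
#'   the envelopes.
#' @param prominence_frac extrema with amplitude swing below this fraction
#'   of the series range are treated as noise (default 0.02; raise it for
#'   noisy measured series — cardiac swings shrink relative to the full
#'   range when the respiratory component dominates, so an aggressive
#'   threshold can swallow genuine cardiac extrema).
#' @param interpolant `"spline"` (default) or `"linear"` envelope family.
#' @param n_sift number of envelope-mean passes (default 2; the second pass
#'   removes most of the respiratory curvature leaking into `Q_c`).
#' @return object of class `decomposition_result`: list with `time`, `q`,
#'   `resp_component`, `cardiac_component` (series on the analysis
#'   interval), `cardiac_pvf`, `resp_pvf`, `n_cardiac_cycles`,
#'   `n_resp_cycles`, `cardiac_peak_times`, `resp_peak_times`,
#'   `analysis_interval`.
#' @export
decompose_flow <- function(time, q, interval = NULL, prominence_frac = 0.02,
                           interpolant = c("spline", "linear"),
                           n_sift = 2L) {
  interpolant <- match.arg(interpolant)
  if (is.null(interval)) interval <- c(max(time) - 10, max(time))
  env <- envelope_mean(time, q, prominence_frac, interpolant)
  if (is.null(env) || length(env$peaks) < 2)
    stop("decompose_flow: fewer than 2 cardiac peaks detected; cardiac ",
         "component unresolvable")
  # irregular spacing of composite peaks: cardiac extrema missing on steep
  # respiratory slopes
  if (length(env$peaks) >= 4) {
    gaps <- diff(time[env$peaks])
    if (max(gaps) > 1.8 * stats::median(gaps))
      warning("decompose_flow: irregular peak spacing; cardiac extrema ",
              "appear to be swallowed by steep slow-component slopes and ",
              "the decomposition may be inaccurate")
  }
  qr <- env$mean
  qc <- q - qr
  for (s in seq_len(max(n_sift - 1L, 0L))) {
    env2 <- envelope_mean(time, qc, prominence_frac, interpolant)
    if (is.null(env2)) break
    qr <- qr + env2$mean
    qc <- qc - env2$mean
  }
  lo <- max(interval[1], env$covered[1])
  hi <- min(interval[2], env$covered[2])
  sel <- time >= lo & time <= hi
  t <- time[sel]; y <- q[sel]; qrs <- qr[sel]; qcs <- qc[sel]

  exc <- find_extrema(qcs, prominence_frac)
  exr <- find_extrema(qrs, prominence_frac)
  n_card <- max(length(exc$peaks) - 1L, 0L)
  n_resp <- max(length(exr$peaks) - 1L, 0L)
  cardiac_pvf <- (max(qcs) - min(qcs)) / 2
  resp_pvf <- (max(qrs) - min(qrs)) / 2

  if (n_card >= 1L && n_resp >= 1L && resp_pvf > 0.05 * cardiac_pvf) {
    f_card <- n_card / diff(range(t[exc$peaks]))
    f_resp <- n_resp / diff(range(t[exr$peaks]))
    if (is.finite(f_card) && is.finite(f_resp) && f_card / f_resp < 2)
      warning("decompose_flow: cardiac/respiratory frequency ratio below ",
              "2; the midpoint decomposition assumes separated timescales ",
              "and may be inaccurate")
  }
  structure(list(
    time = t, q = y,
    resp_component = qrs, cardiac_component = qcs,
    cardiac_pvf = cardiac_pvf, resp_pvf = resp_pvf,
    n_cardiac_cycles = n_card, n_resp_cycles = n_resp,
    cardiac_peak_times = t[exc$peaks], resp_peak_times = t[exr$peaks],
    analysis_interval = c(lo, hi)), class = "decomposition_result")
}

#' Per-cycle volumes of the decomposed components
#'
#' For each component, the trapezoidal integral of `|Q_i(t)|/2` from the
#' first to the last peak of that component, divided by the number of full
#' cycles between them. For a pure sinusoid of amplitude `A` and frequency
#' `f` this converges to `A/(pi f)` — the same per-cycle volume the
#' analytical model assigns via [harmonic_volume()].
#'
#' @param result a [decompose_flow()] result.
#' @return list with `asv` and `arv` in the cubed unit of the input flow
#'   (m^3 for m^3/s input); a component with no full cycle gives `NA`.
#' @export
cycle_volumes <- function(result) {
  vol_of <- function(series, peak_times, n_cycles) {
    if (n_cycles < 1L) return(NA_real_)
    t0 <- min(peak_times); t1 <- max(peak_times)
    sel <- result$time >= t0 & result$time <= t1
    pracma::trapz(result$time[sel], abs(series[sel]) / 2) / n_cycles
  }
  list(asv = vol_of(result$cardiac_component, result$cardiac_peak_times,
                    result$n_cardiac_cycles),
       arv = vol_of(result$resp_component, result$resp_peak_times,
                    result$n_resp_cycles))
}

#' Construct a representative respiratory gradient from a cardiac one
#'
#' When only the cardiac gradient component is known (e.g. derived from
#' cardiac-gated flow measurements), a representative respiratory component
#' is constructed using the cohort-average cardiac-to-respiratory ratios
#' from the ICP-gradient analysis: amplitude 2.85 times smaller and
#' frequency 4.11 times lower than the cardiac component.
#'
#' @param cardiac_amplitude cardiac gradient amplitude (any unit; >= 0).
#' @param cardiac_freq cardiac frequency, Hz (> 0).
#' @param amplitude_ratio cardiac/respiratory amplitude ratio (default 2.85).
#' @param freq_ratio cardiac/respiratory frequency ratio (default 4.11).
#' @return list with `amplitude` and `freq_Hz` of the respiratory component.
#' @export
construct_resp_gradient <- function(cardiac_amplitude, cardiac_freq,
                                    amplitude_ratio = 2.85,
                                    freq_ratio = 4.11) {
  stopifnot(cardiac_amplitude >= 0, cardiac_freq > 0,
            amplitude_ratio > 0, freq_ratio > 0)
  list(amplitude = cardiac_amplitude / amplitude_ratio,
       freq_Hz = cardiac_freq / freq_ratio)
}
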