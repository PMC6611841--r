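# Dual-sensor ICP recordings: the differential pressure gradient, 6-minute
# window extraction with the 2 mmHg acceptance rule, and circadian labelling.

#' Dual-sensor ICP recording
#'
#' Two co-sampled intracranial pressure channels on a uniform time grid:
#' one intraventricular (IV) and one subdural or parenchymal (SD/PAR),
#' separated by a known distance `L`. The differential pressure divided by
#' `L` is the proxy for the axial CSF pressure gradient.
#'
#' @param time seconds from recording start, uniform grid.
#' @param icp_iv intraventricular ICP, mmHg.
#' @param icp_sd_or_par subdural (or parenchymal) ICP, mmHg; parenchymal
#'   sensors are handled identically.
#' @param sampling_rate Hz.
#' @param sensor_distance_L sensor separation, metres.
#' @param start_clock wall-clock time of the first sample, "HH:MM:SS" (or
#'   `NULL` if unknown; windows are then labelled `"unknown"`).
#' @param patient_id label.
#' @return object of class `icp_recording`.
#' @export
icp_recording <- function(time, icp_iv, icp_sd_or_par, sampling_rate,
                          sensor_distance_L, start_clock = NULL,
                          patient_id = "unknown") {
  if (length(icp_iv) != length(icp_sd_or_par) ||
      length(time) != length(icp_iv))
    stop("icp_recording: time and both pressure series must have equal length")
  stopifnot(sampling_rate > 0, sensor_distance_L > 0)
  if (length(time) > 1) {
    dt <- diff(time)
    if (max(abs(dt - dt[1])) > 1e-6 * max(abs(time)))
      stop("icp_recording: time grid must be uniform")
  }
  structure(list(time = time, icp_iv = icp_iv,
                 icp_sd_or_par = icp_sd_or_par,
                 sampling_rate = sampling_rate,
                 sensor_distance_L = sensor_distance_L,
                 start_clock = start_clock, patient_id = patient_id),
            class = "icp_recording")
}

#' Differential ICP gradient
#'
#' `dICP = (ICP_SD - ICP_IV) / L` in mmHg/m, element-wise on the shared time
#' grid. Any common-mode pressure (the large shared ICP pulsation) cancels in
#' the subtraction; what remains is the small differential signal.
#'
#' @param rec an [icp_recording()].
#' @return numeric vector, mmHg/m.
#' @export
compute_dicp <- function(rec) {
  (rec$icp_sd_or_par - rec$icp_iv) / rec$sensor_distance_L
}

# "HH:MM:SS" -> seconds since midnight
parse_clock <- function(x) {
  if (is.null(x) || is.na(x)) return(NA_real_)
  p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(p) == 2) p <- c(p, 0)
  if (length(p) != 3 || any(!is.finite(p))) stop("bad clock string: ", x)
  p[1] * 3600 + p[2] * 60 + p[3]
}

#' Circadian state of a window start time
#'
#' A window is labelled `"sleeping"` if its start falls between midnight and
#' 06:00 (half-open interval `[00:00, 06:00)`), `"awake"` otherwise, and
#' `"unknown"` when no wall-clock time is available (such windows are
#' excluded from sleep/awake comparisons).
#'
#' @param start_clock recording start, "HH:MM:SS" or `NULL`.
#' @param offset_s window start offset from recording start, seconds.
#' @return `"sleeping"`, `"awake"` or `"unknown"`.
#' @export
categorize_state <- function(start_clock, offset_s = 0) {
  s0 <- tryCatch(parse_clock(start_clock), error = function(e) NA_real_)
  if (is.na(s0)) return("unknown")
  tod <- (s0 + offset_s) %% 86400
  if (tod >= 0 && tod < 6 * 3600) "sleeping" else "awake"
}

#' Extract and vet 6-minute gradient windows
#'
#' Splits the recording into consecutive non-overlapping windows (default
#' 360 s, the typical duration of a cardiac-gated PC-MRI acquisition; a
#' trailing partial window is discarded). A window is accepted when the
#' range (max - min) of the raw pressure difference `ICP_SD - ICP_IV` — in
#' mmHg, before division by `L` and before any mean shift — is strictly
#' below the acceptance threshold (default 2 mmHg), which rejects windows
#' contaminated by posture-change steps. Windows containing missing samples
#' are rejected. Accepted windows are mean-shifted to zero (the recordings
#' carry no body-position information, so any static or hydrostatic offset
#' is removed) and labelled by circadian state from their start time.
#'
#' @param rec an [icp_recording()].
#' @param window_s window duration, seconds (default 360).
#' @param accept_mmHg acceptance threshold on the raw difference range, mmHg
#'   (default 2).
#' @return list of `gradient_window` objects, each with fields `dicp`
#'   (zero-mean mmHg/m series for accepted windows; raw for rejected),
#'   `time` (seconds, recording clock), `start_offset`, `duration`, `state`,
#'   `accepted`, `raw_difference_range` (mmHg), `sampling_rate`,
#'   `patient_id`, `window_index`. Empty list if the recording is shorter
#'   than one window.
#' @export
extract_windows <- function(rec, window_s = 360, accept_mmHg = 2) {
  n_per <- round(window_s * rec$sampling_rate)
  n_win <- floor(length(rec$time) / n_per)
  if (n_win < 1) return(list())
  diff_raw <- rec$icp_sd_or_par - rec$icp_iv
  dicp <- diff_raw / rec$sensor_distance_L
  out <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * n_per + 1):(w * n_per)
    seg_diff <- diff_raw[idx]
    complete <- all(is.finite(seg_diff))
    rng <- if (complete) max(seg_diff) - min(seg_diff) else NA_real_
    accepted <- complete && rng < accept_mmHg
    seg <- dicp[idx]
    if (accepted) seg <- seg - mean(seg)
    offset <- rec$time[idx[1]]
    out[[w]] <- structure(list(
      dicp = seg,
      time = rec$time[idx],
      start_offset = offset,
      duration = window_s,
      state = categorize_state(rec$start_clock, offset),
      accepted = accepted,
      raw_difference_range = rng,
      sampling_rate = rec$sampling_rate,
      patient_id = rec$patient_id,
      window_index = w), class = "gradient_window")
  }
  out
}

#' Window index table
#'
#' One row per extracted window: patient id, index, start offset, circadian
#' state, acceptance flag and raw difference range in mmHg. This is the
#' bookkeeping table written alongside the per-window spectral summaries.
#'
#' @param windows list of `gradient_window` objects from [extract_windows()].
#' @return data.frame.
#' @export
window_index_table <- function(windows) {
  data.frame(
    patient_id = vapply(windows, `[[`, "", "patient_id"),
    window_index = vapply(windows, `[[`, 1L, "window_index"),
    start_offset_s = vapply(windows, `[[`, 1, "start_offset"),
    state = vapply(windows, `[[`, "", "state"),
    accepted = vapply(windows, `[[`, TRUE, "accepted"),
    raw_range_mmHg = vapply(windows, `[[`, 1, "raw_difference_range"))
}
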