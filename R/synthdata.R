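# Synthetic dual-sensor ICP recordings with known ground truth.
#
# Real dual-sensor recordings consist of two channels sharing a large
# common-mode pulsatile ICP (cardiac amplitude typically 4-5 mmHg) on top of
# which rides a small differential signal: a cardiac sinusoid, a respiratory
# sinusoid, slow drift, occasional step artifacts from posture changes, and
# broadband sensor noise. The generator reproduces exactly that structure so
# every downstream stage can be tested against known component parameters.

# run expr with a private RNG stream; global .Random.seed is untouched
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic dual-sensor ICP recording
#'
#' @param duration recording length, seconds.
#' @param sampling_rate Hz (default 200, the clinical acquisition rate).
#' @param sensor_distance_L sensor separation, metres.
#' @param common_mode_amplitude amplitude of the shared cardiac ICP
#'   pulsation, mmHg (typically 4-5); a respiratory common-mode component of
#'   a quarter of this amplitude is added as well. Identical in both
#'   channels, so it cancels exactly in the difference.
#' @param cardiac_grad_amplitude,cardiac_freq differential cardiac component:
#'   gradient amplitude in mmHg/m and frequency in Hz (0.7-1.6).
#' @param resp_grad_amplitude,resp_freq differential respiratory component:
#'   mmHg/m and Hz (0.15-0.4).
#' @param drift_amplitude,drift_freq slow differential drift (pressure units
#'   mmHg/m on the gradient scale; frequency below 0.1 Hz).
#' @param noise_sd standard deviation of independent Gaussian white noise
#'   added to each channel, mmHg.
#' @param artifact_times,artifact_steps step artifacts (posture changes):
#'   onset times in seconds and step heights in mmHg, added to the SD
#'   channel at and after each onset.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param patient_id,start_clock metadata attached to the recording;
#'   `start_clock` is "HH:MM:SS" wall-clock time of the first sample.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration,
                           sampling_rate = 200,
                           sensor_distance_L = 0.06,
                           common_mode_amplitude = 4.5,
                           cardiac_grad_amplitude = 1.46,
                           cardiac_freq = 62 / 60,
                           resp_grad_amplitude = 0.52,
                           resp_freq = 15 / 60,
                           drift_amplitude = 0,
                           drift_freq = 0.02,
                           noise_sd = 0,
                           artifact_times = numeric(0),
                           artifact_steps = numeric(0),
                           seed = 1L,
                           patient_id = "synthetic",
                           start_clock = "22:00:00") {
  spec <- structure(as.list(environment()), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  amps <- c(spec$common_mode_amplitude, spec$cardiac_grad_amplitude,
            spec$resp_grad_amplitude, spec$drift_amplitude, spec$noise_sd)
  if (any(amps < 0)) stop("synthetic_spec: all amplitudes must be >= 0")
  if (spec$duration <= 0 || spec$sampling_rate <= 0 ||
      spec$sensor_distance_L <= 0)
    stop("synthetic_spec: duration, sampling_rate and sensor_distance_L ",
         "must be positive")
  if (spec$cardiac_freq < 0.7 || spec$cardiac_freq > 1.6)
    stop("synthetic_spec: cardiac_freq must lie in [0.7, 1.6] Hz")
  if (spec$resp_freq < 0.15 || spec$resp_freq > 0.4)
    stop("synthetic_spec: resp_freq must lie in [0.15, 0.4] Hz")
  if (spec$drift_freq >= 0.1)
    stop("synthetic_spec: drift_freq must be below 0.1 Hz")
  fmax <- max(spec$cardiac_freq, spec$resp_freq, spec$drift_freq)
  if (spec$sampling_rate <= 2 * fmax)
    stop("synthetic_spec: sampling_rate must exceed twice the highest ",
         "generated frequency")
  if (length(spec$artifact_times) != length(spec$artifact_steps))
    stop("synthetic_spec: artifact_times and artifact_steps must have ",
         "equal length")
  invisible(spec)
}

#' Generate a synthetic dual-sensor ICP recording
#'
#' Channel IV (intraventricular) carries the common-mode ICP plus noise;
#' channel SD (subdural) carries the common mode plus `L` times the
#' specified differential gradient waveform (cardiac + respiratory + drift),
#' step artifacts, and its own independent noise. The exact ground-truth
#' component parameters are attached as attribute `ground_truth`.
#'
#' @param spec a [synthetic_spec()].
#' @return an [icp_recording()] with attribute `ground_truth`.
#' @export
generate_recording <- function(spec) {
  validate_synthetic_spec(spec)
  n <- round(spec$duration * spec$sampling_rate)
  t <- (seq_len(n) - 1) / spec$sampling_rate
  common <- spec$common_mode_amplitude * sin(2 * pi * spec$cardiac_freq * t) +
    (spec$common_mode_amplitude / 4) * sin(2 * pi * spec$resp_freq * t)
  grad <- spec$cardiac_grad_amplitude * sin(2 * pi * spec$cardiac_freq * t) +
    spec$resp_grad_amplitude * sin(2 * pi * spec$resp_freq * t) +
    spec$drift_amplitude * sin(2 * pi * spec$drift_freq * t)
  steps <- numeric(n)
  for (k in seq_along(spec$artifact_times))
    steps[t >= spec$artifact_times[k]] <-
      steps[t >= spec$artifact_times[k]] + spec$artifact_steps[k]
  noise <- with_local_seed(spec$seed, {
    list(iv = stats::rnorm(n, 0, spec$noise_sd),
         sd = stats::rnorm(n, 0, spec$noise_sd))
  })
  rec <- icp_recording(
    time = t,
    icp_iv = common + noise$iv,
    icp_sd_or_par = common + spec$sensor_distance_L * grad + steps + noise$sd,
    sampling_rate = spec$sampling_rate,
    sensor_distance_L = spec$sensor_distance_L,
    start_clock = spec$start_clock,
    patient_id = spec$patient_id)
  attr(rec, "ground_truth") <- list(
    cardiac = list(amplitude_mmHg_m = spec$cardiac_grad_amplitude,
                   freq_Hz = spec$cardiac_freq),
    resp = list(amplitude_mmHg_m = spec$resp_grad_amplitude,
                freq_Hz = spec$resp_freq),
    drift = list(amplitude_mmHg_m = spec$drift_amplitude,
                 freq_Hz = spec$drift_freq),
    noise_sd_mmHg = spec$noise_sd,
    artifact_times = spec$artifact_times,
    artifact_steps = spec$artifact_steps)
  rec
}

#' Write / read a recording as tabular text
#'
#' The on-disk format is a comma-separated file with header
#' `time_s,icp_iv_mmHg,icp_sd_mmHg` plus a JSON side-car
#' (`<path>.meta.json`) holding the sampling rate, sensor separation, start
#' wall-clock time, patient id and, for synthetic recordings, the
#' ground-truth component record.
#'
#' @param rec an [icp_recording()].
#' @param path CSV file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an [icp_recording()].
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time_s = rec$time, icp_iv_mmHg = rec$icp_iv,
                   icp_sd_mmHg = rec$icp_sd_or_par)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(sampling_rate = rec$sampling_rate,
               sensor_distance_L = rec$sensor_distance_L,
               start_clock = rec$start_clock,
               patient_id = rec$patient_id,
               ground_truth = attr(rec, "ground_truth"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "icp_iv_mmHg", "icp_sd_mmHg")
  if (!all(need %in% names(df)))
    stop("recording file must have columns ", paste(need, collapse = ", "))
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop("missing side-car metadata file ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  rec <- icp_recording(
    time = df$time_s, icp_iv = df$icp_iv_mmHg, icp_sd_or_par = df$icp_sd_mmHg,
    sampling_rate = meta$sampling_rate,
    sensor_distance_L = meta$sensor_distance_L,
    start_clock = meta$start_clock,
    patient_id = meta$patient_id)
  if (!is.null(meta$ground_truth)) attr(rec, "ground_truth") <- meta$ground_truth
  rec
}
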