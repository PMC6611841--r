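# Pipeline orchestration: configuration, simulate and analyze entry points,
# stage-level logging. A thin command-line wrapper around these functions
# lives in inst/scripts/aqueflow-cli.R.

#' Pipeline configuration
#'
#' Gathers every tunable constant of the analysis in one place: spectral
#' settings (bands, 15 Hz cutoff, calibration C), window length (360 s) and
#' acceptance threshold (2 mmHg), the sleep interval, geometry (R = 2 mm)
#' and fluid properties (rho = 1000 kg/m^3, mu = 0.7e-3 Pa s), and
#' decomposition settings. Stage logic reads constants only from here. A
#' warning is issued for departures from the reference values so
#' non-standard runs are visible in logs.
#'
#' @param spectral a [spectral_config()].
#' @param geometry an [aqueduct_geometry()].
#' @param fluid a [fluid_properties()].
#' @param window_s window length, seconds.
#' @param accept_mmHg window acceptance threshold on the raw pressure
#'   difference, mmHg.
#' @param min_windows minimum accepted windows for patient inclusion.
#' @param decomposition list of [decompose_flow()] settings
#'   (`prominence_frac`, `interpolant`).
#' @param seed integer seed for any randomised stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(spectral = spectral_config(),
                            geometry = aqueduct_geometry(),
                            fluid = fluid_properties(),
                            window_s = 360,
                            accept_mmHg = 2,
                            min_windows = 2L,
                            decomposition = list(prominence_frac = 0.1,
                                                 interpolant = "linear"),
                            seed = 1L) {
  ref <- list(window_s = 360, accept_mmHg = 2, radius_R = 2e-3,
              density_rho = 1000, viscosity_mu = 0.7e-3, lowpass_cutoff = 15)
  got <- list(window_s = window_s, accept_mmHg = accept_mmHg,
              radius_R = geometry$radius_R, density_rho = fluid$density_rho,
              viscosity_mu = fluid$viscosity_mu,
              lowpass_cutoff = spectral$lowpass_cutoff)
  for (nm in names(ref)) if (!isTRUE(all.equal(ref[[nm]], got[[nm]])))
    warning("pipeline_config: ", nm, " = ", got[[nm]],
            " departs from the reference value ", ref[[nm]])
  structure(list(spectral = spectral, geometry = geometry, fluid = fluid,
                 window_s = window_s, accept_mmHg = accept_mmHg,
                 min_windows = min_windows, decomposition = decomposition,
                 seed = seed), class = "pipeline_config")
}

#' Simulate a synthetic cohort to disk
#'
#' Generates one recording per [synthetic_spec()] and writes each as CSV
#' plus JSON side-car under `out_dir`.
#'
#' @param specs list of [synthetic_spec()] objects.
#' @param out_dir output directory (created if needed).
#' @return character vector of written CSV paths, invisibly.
#' @export
run_simulate <- function(specs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(specs, function(sp) {
    rec <- generate_recording(sp)
    p <- file.path(out_dir, paste0(sp$patient_id, ".csv"))
    write_recording(rec, p)
    message("simulate: wrote ", p, " (", length(rec$time), " samples)")
    p
  }, "")
  invisible(paths)
}

#' Analyse a set of recordings end to end
#'
#' For each recording: form the differential gradient, extract and vet
#' 6-minute windows, run the spectral analysis on accepted windows, map
#' each window's cardiac and respiratory components through the Womersley
#' model, then aggregate to patient and cohort summaries and run the
#' sleep-vs-awake comparison. Counts of accepted/rejected windows and
#' patient exclusions are logged via `message()`.
#'
#' @param recordings list of [icp_recording()] objects, or character paths
#'   to recording CSVs readable by [read_recording()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the window index,
#'   per-window spectral/flow table, patient and cohort tables are written
#'   there as CSV (units in the column names).
#' @return list with `windows` (index table), `window_results` (per-window
#'   spectral + flow quantities), `patients`, `cohort`, `sleep_test`.
#' @export
run_analyze <- function(recordings, config = pipeline_config(),
                        out_dir = NULL) {
  if (is.character(recordings)) recordings <- lapply(recordings, read_recording)
  idx_all <- list(); res_all <- list(); pat_all <- list()
  for (rec in recordings) {
    wins <- extract_windows(rec, config$window_s, config$accept_mmHg)
    idx <- window_index_table(wins)
    idx_all[[length(idx_all) + 1L]] <- idx
    acc <- Filter(function(w) w$accepted, wins)
    message("analyze: patient ", rec$patient_id, ": ", length(acc),
            " accepted / ", length(wins) - length(acc), " rejected windows")
    if (length(acc) == 0L) next
    rows <- lapply(acc, function(w) {
      summ <- analyze_window(w, config$spectral)
      fl <- summarize_window_flow(summ, config$geometry, config$fluid)
      data.frame(patient_id = w$patient_id, window_index = w$window_index,
                 state = w$state,
                 heart_rate = summ$f0_cardiac * 60,
                 resp_rate = summ$f1_resp * 60,
                 cardiac_amp = summ$a0_cardiac, resp_amp = summ$a1_resp,
                 amp_ratio = if (summ$resp_found)
                   summ$a0_cardiac / summ$a1_resp else NA_real_,
                 cardiac_pvf = fl$cardiac_pvf_mL_s,
                 resp_pvf = fl$resp_pvf_mL_s,
                 asv = fl$asv_uL, arv = fl$arv_uL,
                 pvf_ratio = fl$pvf_ratio, volume_ratio = fl$volume_ratio)
    })
    res <- do.call(rbind, rows)
    res_all[[length(res_all) + 1L]] <- res
    ps <- summarize_patient(res, config$min_windows)
    if (!is.null(ps)) pat_all[[length(pat_all) + 1L]] <- ps
  }
  if (length(res_all) == 0L)
    stop("run_analyze: no accepted windows in any recording")
  windows <- do.call(rbind, idx_all)
  window_results <- do.call(rbind, res_all)
  patients <- if (length(pat_all)) do.call(rbind, pat_all) else NULL
  cohort <- if (!is.null(patients)) summarize_cohort(patients) else NULL
  sleep <- if (!is.null(patients) && nrow(patients) >= 2)
    sleep_vs_awake_test(patients) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(windows, file.path(out_dir, "window_index.csv"),
                     row.names = FALSE)
    wr <- window_results
    names(wr) <- c("patient_id", "window_index", "state",
                   "heart_rate_bpm", "resp_rate_bpm",
                   "cardiac_amp_mmHg_per_m", "resp_amp_mmHg_per_m",
                   "amp_ratio", "cardiac_pvf_mL_s", "resp_pvf_mL_s",
                   "asv_uL", "arv_uL", "pvf_ratio", "volume_ratio")
    utils::write.csv(wr, file.path(out_dir, "window_results.csv"),
                     row.names = FALSE)
    if (!is.null(patients))
      utils::write.csv(patients, file.path(out_dir, "patients.csv"),
                       row.names = FALSE)
    if (!is.null(cohort))
      utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                       row.names = FALSE)
    if (!is.null(sleep))
      utils::write.csv(sleep, file.path(out_dir, "sleep_vs_awake.csv"),
                       row.names = FALSE)
  }
  list(windows = windows, window_results = window_results,
       patients = patients, cohort = cohort, sleep_test = sleep)
}
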