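# Replay of a per-patient summary table through the analytical model: the
# published per-patient average gradient amplitudes and rates are inputs
# enough to recompute flow rates, volumes and their ratios without access
# to the underlying recordings.

#' Published per-patient ICP-gradient summary table
#'
#' The nine-patient summary of the dICP analysis (per-patient window counts,
#' sensor separations, mean heart and respiratory rates, mean cardiac and
#' respiratory gradient amplitudes and their ratio), shipped with the
#' package as plain CSV. These per-patient averages are the inputs for
#' [replay_cohort_table()].
#'
#' @param path CSV path; defaults to the shipped table.
#' @return data.frame, one row per patient.
#' @export
icp_cohort_table <- function(path = system.file("extdata",
                                                "icp_cohort_summary.csv",
                                                package = "aqueflow")) {
  utils::read.csv(path)
}

#' Recompute flow summaries from a per-patient summary table
#'
#' For each row, applies the Womersley model to the cardiac component
#' (amplitude `cardiac_amp_mmHg_m` at `heart_rate_bpm`) and the respiratory
#' component (`resp_amp_mmHg_m` at `resp_rate_bpm`), computes per-cycle
#' volumes `V = A/(pi f)`, and forms per-patient ratios; a cohort row (mean
#' +/- sd across patients) is appended.
#'
#' @param table data.frame with columns `heart_rate_bpm`, `resp_rate_bpm`,
#'   `cardiac_amp_mmHg_m`, `resp_amp_mmHg_m` (and optionally `patient_id`,
#'   `amp_ratio`); e.g. [icp_cohort_table()]. Malformed rows (non-finite or
#'   non-positive rates/amplitudes) are skipped with a warning.
#' @param geom,fluid geometry and fluid properties.
#' @return data.frame with one row per valid patient plus a final
#'   `"cohort_mean"` row and a `"cohort_sd"` row; columns
#'   `cardiac_pvf_mL_s`, `resp_pvf_mL_s`, `asv_uL`, `arv_uL`, `pvf_ratio`,
#'   `volume_ratio`, `amp_ratio`, `period_ratio`, `heart_rate_bpm`,
#'   `resp_rate_bpm`.
#' @export
replay_cohort_table <- function(table, geom = aqueduct_geometry(),
                                fluid = fluid_properties()) {
  need <- c("heart_rate_bpm", "resp_rate_bpm",
            "cardiac_amp_mmHg_m", "resp_amp_mmHg_m")
  if (!all(need %in% names(table)))
    stop("replay_cohort_table: table must have columns ",
         paste(need, collapse = ", "))
  if (nrow(table) == 0L) return(table[0, ])
  rows <- lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    vals <- unlist(r[need])
    if (any(!is.finite(vals)) || any(vals <= 0)) {
      warning("replay_cohort_table: skipping malformed row ", i)
      return(NULL)
    }
    summ <- list(f0_cardiac = r$heart_rate_bpm / 60,
                 a0_cardiac = r$cardiac_amp_mmHg_m,
                 f1_resp = r$resp_rate_bpm / 60,
                 a1_resp = r$resp_amp_mmHg_m)
    fl <- summarize_window_flow(summ, geom, fluid)
    data.frame(
      patient_id = if ("patient_id" %in% names(r))
        as.character(r$patient_id) else as.character(i),
      heart_rate_bpm = r$heart_rate_bpm,
      resp_rate_bpm = r$resp_rate_bpm,
      amp_ratio = if ("amp_ratio" %in% names(r)) r$amp_ratio
        else r$cardiac_amp_mmHg_m / r$resp_amp_mmHg_m,
      period_ratio = r$resp_rate_bpm / r$heart_rate_bpm,
      cardiac_pvf_mL_s = fl$cardiac_pvf_mL_s,
      resp_pvf_mL_s = fl$resp_pvf_mL_s,
      asv_uL = fl$asv_uL, arv_uL = fl$arv_uL,
      pvf_ratio = fl$pvf_ratio, volume_ratio = fl$volume_ratio)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(table[0, ])
  num <- names(out)[vapply(out, is.numeric, TRUE)]
  mean_row <- out[1, ]; mean_row$patient_id <- "cohort_mean"
  sd_row <- out[1, ]; sd_row$patient_id <- "cohort_sd"
  for (cn in num) {
    mean_row[[cn]] <- mean(out[[cn]])
    sd_row[[cn]] <- if (nrow(out) >= 2) stats::sd(out[[cn]]) else NA_real_
  }
  rbind(out, mean_row, sd_row)
}
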