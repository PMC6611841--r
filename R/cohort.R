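# Per-patient and cohort aggregation, and the sleep-vs-awake comparison.
#
# Aggregation convention: windows average to patient means first; cohort
# statistics are mean +/- sample sd across the patient means, never across
# pooled windows. Ratio quantities are averaged as per-window ratios.

quantity_cols <- c("heart_rate", "resp_rate", "cardiac_amp", "resp_amp",
                   "amp_ratio", "cardiac_pvf", "resp_pvf", "asv", "arv",
                   "pvf_ratio", "volume_ratio")

#' Summarise one patient's accepted windows
#'
#' Arithmetic mean and sample (n-1) standard deviation per quantity over a
#' patient's accepted windows, plus sleep/awake sub-means. Ratios are
#' averaged as per-window ratios, not ratios of means. Patients with fewer
#' than `min_windows` accepted windows are excluded (returns `NULL` with a
#' message), mirroring the exclusion of subjects whose recordings yield
#' almost no clean windows.
#'
#' @param windows data.frame of per-window results; recognised quantity
#'   columns are `heart_rate`, `resp_rate`, `cardiac_amp`, `resp_amp`,
#'   `amp_ratio`, `cardiac_pvf`, `resp_pvf`, `asv`, `arv`, `pvf_ratio`,
#'   `volume_ratio` (any subset), plus optional `state`
#'   (`"sleeping"`/`"awake"`) and `patient_id`.
#' @param min_windows minimum accepted windows for inclusion (default 2).
#' @return one-row data.frame with `<q>_mean` and `<q>_sd` columns, plus
#'   `<q>_sleep` / `<q>_awake` sub-means where state labels exist, or `NULL`
#'   if the patient is excluded. SDs are `NA` for a single window.
#' @export
summarize_patient <- function(windows, min_windows = 2L) {
  if (nrow(windows) < 1L) {
    message("patient excluded: no accepted windows")
    return(NULL)
  }
  if (nrow(windows) < min_windows) {
    message("patient ", windows$patient_id[1], " excluded: only ",
            nrow(windows), " accepted window(s)")
    return(NULL)
  }
  cols <- intersect(quantity_cols, names(windows))
  out <- list(patient_id = if ("patient_id" %in% names(windows))
    windows$patient_id[1] else NA_character_,
    n_windows = nrow(windows))
  for (q in cols) {
    x <- windows[[q]]
    out[[paste0(q, "_mean")]] <- mean(x, na.rm = TRUE)
    out[[paste0(q, "_sd")]] <- if (sum(is.finite(x)) >= 2)
      stats::sd(x, na.rm = TRUE) else NA_real_
    if ("state" %in% names(windows)) {
      for (st in c("sleeping", "awake")) {
        xs <- x[windows$state == st]
        out[[paste0(q, "_", sub("ing$", "", st))]] <-
          if (length(xs) > 0) mean(xs, na.rm = TRUE) else NA_real_
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Cohort summary across patient means
#'
#' Mean and sample standard deviation of each `<q>_mean` column across
#' patients. With a single patient only means are reported.
#'
#' @param patients data.frame of patient summaries (rows from
#'   [summarize_patient()]).
#' @return one-row data.frame with `<q>_mean`, `<q>_sd` and `n_patients`.
#' @export
summarize_cohort <- function(patients) {
  stopifnot(nrow(patients) >= 1L)
  out <- list(n_patients = nrow(patients))
  for (col in grep("_mean$", names(patients), value = TRUE)) {
    q <- sub("_mean$", "", col)
    x <- patients[[col]]
    out[[paste0(q, "_mean")]] <- mean(x, na.rm = TRUE)
    out[[paste0(q, "_sd")]] <- if (nrow(patients) >= 2L)
      stats::sd(x, na.rm = TRUE) else NA_real_
  }
  as.data.frame(out)
}

#' Paired sleep-versus-awake comparison
#'
#' Two-sided paired t-test per quantity on the per-patient sleep and awake
#' sub-means. Patients missing either state are excluded pairwise. With
#' fewer than two complete pairs, or a zero-variance difference (degenerate
#' for the t-test), the quantity is reported as not testable.
#'
#' @param patients data.frame of patient summaries containing `<q>_sleep`
#'   and `<q>_awake` columns.
#' @param quantities character vector of quantity names to test; default all
#'   with both sub-mean columns present.
#' @return data.frame with columns `quantity`, `n_pairs`, `t`, `p`,
#'   `mean_diff` (sleep minus awake), `note`.
#' @export
sleep_vs_awake_test <- function(patients, quantities = NULL) {
  if (is.null(quantities)) {
    sl <- sub("_sleep$", "", grep("_sleep$", names(patients), value = TRUE))
    aw <- sub("_awake$", "", grep("_awake$", names(patients), value = TRUE))
    quantities <- intersect(sl, aw)
  }
  rows <- lapply(quantities, function(q) {
    s <- patients[[paste0(q, "_sleep")]]
    a <- patients[[paste0(q, "_awake")]]
    ok <- is.finite(s) & is.finite(a)
    d <- s[ok] - a[ok]
    n <- length(d)
    if (n < 2)
      return(data.frame(quantity = q, n_pairs = n, t = NA_real_,
                        p = NA_real_, mean_diff = NA_real_,
                        note = "fewer than 2 complete pairs"))
    if (stats::sd(d) == 0) {
      note <- if (all(d == 0)) "no difference (t = 0, p = 1)"
        else "zero-variance nonzero difference; t undefined"
      return(data.frame(quantity = q, n_pairs = n,
                        t = if (all(d == 0)) 0 else NA_real_,
                        p = if (all(d == 0)) 1 else NA_real_,
                        mean_diff = mean(d), note = note))
    }
    tt <- stats::t.test(s[ok], a[ok], paired = TRUE)
    data.frame(quantity = q, n_pairs = n, t = unname(tt$statistic),
               p = tt$p.value, mean_diff = mean(d), note = "")
  })
  do.call(rbind, rows)
}

#' Cardiac-to-respiratory period ratio
#'
#' Per patient, the respiratory rate divided by the heart rate — identically
#' the length of the cardiac cycle as a fraction of the respiratory cycle —
#' then cohort mean and sample sd. A small ratio (about 0.25) means the
#' respiratory half-period over which momentum accumulates is about four
#' cardiac half-periods long.
#'
#' @param patients data.frame with `heart_rate_mean` and `resp_rate_mean`
#'   columns (or `heart_rate` / `resp_rate`).
#' @return list with `per_patient`, `mean`, `sd`.
#' @export
period_ratio <- function(patients) {
  hr <- patients[["heart_rate_mean"]] %||% patients[["heart_rate"]]
  rr <- patients[["resp_rate_mean"]] %||% patients[["resp_rate"]]
  if (is.null(hr) || is.null(rr))
    stop("period_ratio: heart and respiratory rate columns required")
  ratio <- rr / hr
  list(per_patient = ratio, mean = mean(ratio),
       sd = if (length(ratio) >= 2) stats::sd(ratio) else NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
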