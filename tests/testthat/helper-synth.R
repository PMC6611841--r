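# Shared fixtures, built in code.

# A gradient window object directly from a signal function, bypassing the
# recording layer, for fast spectral tests. f(t) in mmHg/m.
make_window <- function(signal, duration = 360, fs = 40,
                        patient_id = "w", window_index = 1L) {
  t <- (seq_len(duration * fs) - 1) / fs
  x <- signal(t)
  structure(list(dicp = x - mean(x), time = t, start_offset = 0,
                 duration = duration, state = "awake", accepted = TRUE,
                 raw_difference_range = NA_real_, sampling_rate = fs,
                 patient_id = patient_id, window_index = window_index),
            class = "gradient_window")
}

# Forcing frequency that yields a given Womersley number for the default
# geometry/fluid: alpha = R sqrt(2 pi f rho / mu).
freq_for_alpha <- function(alpha, geom = aqueduct_geometry(),
                           fluid = fluid_properties()) {
  alpha^2 * fluid$viscosity_mu / (2 * pi * fluid$density_rho *
                                    geom$radius_R^2)
}

# The nine-patient published summary used by replay tests.
cohort_tab <- function() icp_cohort_table()
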