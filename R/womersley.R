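# Analytical Womersley solution: oscillatory laminar flow of a Newtonian
# fluid in a rigid cylinder driven by a sinusoidal axial pressure gradient.
#
# For dp/dz(t) = a sin(omega t + phi) the axial velocity is
#   v(r, t) = Re{ (i a / (rho omega)) [1 - J0(Lam r/R)/J0(Lam)]
#                 e^{i(omega t + phi - pi/2)} }
# with Lam = alpha i^{3/2} and Womersley number alpha = R sqrt(omega rho/mu).
# Integrating over the cross-section gives the flow rate
#   Q(t) = Re{ pi R^2 (i a / (rho omega)) [1 - (2/Lam) J1(Lam)/J0(Lam)]
#              e^{i(omega t + phi - pi/2)} }
# whose amplitude A (the peak volumetric flow rate, PVF) is the modulus of
# the complex prefactor. The volume swept in one direction per cycle is
#   V = A / (pi f),
# so for equal flow amplitudes the slower (respiratory) component carries
# proportionally more volume per cycle than the faster (cardiac) one — low
# frequency lets momentum accumulate over the long half-period.

#' Aqueduct geometry
#'
#' The cerebral aqueduct is idealised as a rigid straight cylinder. The
#' default radius of 2 mm corresponds to a cross-sectional area of about
#' 14 mm^2, the median reported for iNPH patients.
#'
#' @param radius_R radius in metres (default `2e-3`).
#' @return object of class `aqueduct_geometry`.
#' @export
aqueduct_geometry <- function(radius_R = 2e-3) {
  stopifnot(is.numeric(radius_R), length(radius_R) == 1L, radius_R > 0)
  structure(list(radius_R = radius_R), class = "aqueduct_geometry")
}

#' CSF fluid properties
#'
#' Density and dynamic viscosity of cerebrospinal fluid, which is close to
#' water at body temperature: rho = 1000 kg/m^3, mu = 0.7e-3 Pa s.
#'
#' @param density_rho density in kg/m^3.
#' @param viscosity_mu dynamic viscosity in Pa s.
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(density_rho = 1000, viscosity_mu = 0.7e-3) {
  stopifnot(density_rho > 0, viscosity_mu > 0)
  structure(list(density_rho = density_rho, viscosity_mu = viscosity_mu),
            class = "fluid_properties")
}

#' Multi-component sinusoidal pressure gradient
#'
#' A pressure gradient expressed as a sum of pure sine components
#' `a sin(2 pi f t + phase)`. Amplitudes are given in mmHg/m (the clinical
#' unit) and stored internally in Pa/m. A component with `freq_Hz = 0` is a
#' constant (steady) gradient of magnitude `a`.
#'
#' @param amplitude_mmHg_m numeric vector of component amplitudes, mmHg/m.
#' @param freq_Hz numeric vector of component frequencies, Hz.
#' @param phase numeric vector of phases in radians (default all 0).
#' @return object of class `harmonic_gradient`: a data.frame with columns
#'   `a_Pa_m`, `freq_Hz`, `phase`.
#' @export
harmonic_gradient <- function(amplitude_mmHg_m, freq_Hz, phase = 0) {
  stopifnot(length(amplitude_mmHg_m) == length(freq_Hz))
  if (any(amplitude_mmHg_m < 0)) stop("component amplitudes must be >= 0")
  if (any(freq_Hz < 0)) stop("component frequencies must be >= 0")
  phase <- rep_len(phase, length(freq_Hz))
  structure(
    data.frame(a_Pa_m = mmhg_to_pa(amplitude_mmHg_m),
               freq_Hz = freq_Hz, phase = phase),
    class = c("harmonic_gradient", "data.frame"))
}

#' Womersley solution for one sinusoidal gradient component
#'
#' Maps a sinusoidal pressure-gradient component of amplitude `a` (Pa/m) and
#' frequency `f` (Hz) to the complex oscillatory flow-rate solution in a
#' rigid cylinder. The returned amplitude is the peak volumetric flow rate
#' (PVF) of that component.
#'
#' @param a_Pa_m gradient amplitude in Pa/m (>= 0).
#' @param f frequency in Hz (> 0; use [poiseuille_static_gradient()] and its
#'   inverse relation for steady flow).
#' @param geom an [aqueduct_geometry()].
#' @param fluid a [fluid_properties()].
#' @return object of class `harmonic_flow_solution`: list with `omega`
#'   (rad/s), `womersley_alpha`, `Lambda` (complex), `pvf_amplitude_A`
#'   (m^3/s), `flow_phase` (rad, phase of the complex flow-rate prefactor
#'   relative to e^{i omega t} for a sine forcing), `freq_Hz`, `a_Pa_m`.
#' @export
womersley_solution <- function(a_Pa_m, f, geom = aqueduct_geometry(),
                               fluid = fluid_properties()) {
  stopifnot(a_Pa_m >= 0)
  if (f <= 0)
    stop("womersley_solution requires f > 0; for a steady gradient use ",
         "poiseuille_static_gradient()")
  R <- geom$radius_R
  rho <- fluid$density_rho
  mu <- fluid$viscosity_mu
  omega <- 2 * pi * f
  alpha <- R * sqrt(omega * rho / mu)
  Lambda <- alpha * exp(1i * 3 * pi / 4)   # alpha * i^{3/2}
  ratio <- besselJ_ratio10(Lambda)          # J1(Lambda)/J0(Lambda)
  # complex flow-rate prefactor for forcing a e^{i omega t}
  Qhat <- pi * R^2 * (1i * a_Pa_m / (rho * omega)) * (1 - (2 / Lambda) * ratio)
  structure(list(
    omega = omega,
    womersley_alpha = alpha,
    Lambda = Lambda,
    pvf_amplitude_A = Mod(Qhat),
    flow_phase = Arg(Qhat),
    freq_Hz = f,
    a_Pa_m = a_Pa_m
  ), class = "harmonic_flow_solution")
}

#' Flow-rate time series from a multi-component gradient
#'
#' Superposes the Womersley responses of each sinusoidal component of a
#' [harmonic_gradient()] on a time grid. The governing equation is linear, so
#' the response to the sum of components is the sum of responses.
#'
#' @param gradient a [harmonic_gradient()] with all frequencies > 0.
#' @param geom,fluid geometry and fluid properties.
#' @param time numeric vector of times in seconds.
#' @return numeric vector, flow rate in m^3/s on `time`.
#' @export
flow_rate_series <- function(gradient, geom = aqueduct_geometry(),
                             fluid = fluid_properties(), time) {
  q <- numeric(length(time))
  if (nrow(gradient) == 0L) return(q)
  if (any(gradient$freq_Hz <= 0))
    stop("flow_rate_series requires all component frequencies > 0")
  for (k in seq_len(nrow(gradient))) {
    sol <- womersley_solution(gradient$a_Pa_m[k], gradient$freq_Hz[k],
                              geom, fluid)
    # forcing a sin(omega t + phase) = Re{a e^{i(omega t + phase - pi/2)}}
    ph <- gradient$phase[k] - pi / 2
    q <- q + sol$pvf_amplitude_A *
      cos(sol$omega * time + ph + sol$flow_phase)
  }
  q
}

#' Flow volume of one harmonic component
#'
#' Volume displaced in one direction over one cycle of a sinusoidal flow
#' component of amplitude `A` and frequency `f`:
#' `V = integral of A sin(2 pi f t) over the positive half-period = A/(pi f)`.
#' Applied to the cardiac component this is the aqueductal stroke volume
#' (ASV); applied to the respiratory component, the aqueductal respiratory
#' volume (ARV).
#'
#' @param sol a `harmonic_flow_solution` (or a list with fields
#'   `pvf_amplitude_A` and `freq_Hz`).
#' @return volume in m^3.
#' @export
harmonic_volume <- function(sol) {
  stopifnot(sol$freq_Hz > 0)
  sol$pvf_amplitude_A / (pi * sol$freq_Hz)
}

#' Womersley velocity profile
#'
#' Axial velocity at radius `r` and time `t` for a single sinusoidal
#' gradient component `a sin(2 pi f t)`. Satisfies no-slip at the wall
#' (`v(R, t) = 0`) and integrates over the cross-section to the flow rate of
#' [flow_rate_series()].
#'
#' @param a_Pa_m gradient amplitude, Pa/m.
#' @param f frequency, Hz (> 0).
#' @param geom,fluid geometry and fluid properties.
#' @param r radii in metres, all in `[0, R]`.
#' @param t times in seconds.
#' @return matrix of velocities (m/s), `length(r)` rows by `length(t)`
#'   columns (dropped to a vector if either has length 1).
#' @export
velocity_profile <- function(a_Pa_m, f, geom = aqueduct_geometry(),
                             fluid = fluid_properties(), r, t) {
  R <- geom$radius_R
  if (any(r < 0) || any(r > R)) stop("radii must lie in [0, R]")
  rho <- fluid$density_rho
  omega <- 2 * pi * f
  alpha <- R * sqrt(omega * rho / fluid$viscosity_mu)
  if (alpha > 20)
    stop("velocity_profile supports Womersley numbers up to 20 ",
         "(series evaluation of J0); got alpha = ", signif(alpha, 4))
  Lambda <- alpha * exp(1i * 3 * pi / 4)
  J0L <- besselJ01c(Lambda)$J0
  prof <- 1 - besselJ01c(Lambda * r / R)$J0 / J0L    # radial shape, complex
  pref <- (1i * a_Pa_m / (rho * omega)) * prof
  # sine forcing: multiply by e^{i(omega t - pi/2)} and take the real part
  out <- outer(pref, exp(1i * (omega * t - pi / 2)))
  drop(Re(out))
}

#' Static pressure gradient by Poiseuille's law
#'
#' The steady axial pressure gradient required to drive a net flow `Q_net`
#' through a rigid cylinder: `dp/dz = 8 mu Q_net / (pi R^4)`. Used to compare
#' the tiny gradient implied by bulk CSF production (~500 mL/day, the
#' classical "third circulation") with the measured pulsatile gradients.
#'
#' @param Q_net net flow in m^3/s (>= 0).
#' @param geom,fluid geometry and fluid properties.
#' @return list with `gradient_Pa_m` and `gradient_mmHg_m`.
#' @export
poiseuille_static_gradient <- function(Q_net, geom = aqueduct_geometry(),
                                       fluid = fluid_properties()) {
  stopifnot(Q_net >= 0)
  g <- 8 * fluid$viscosity_mu * Q_net / (pi * geom$radius_R^4)
  list(gradient_Pa_m = g, gradient_mmHg_m = pa_to_mmhg(g))
}

#' Flow summary for one analysed window
#'
#' Applies the Womersley model to the cardiac and respiratory gradient
#' components of a [spectrum_summary()] and reports peak volumetric flow
#' rates (PVF, mL/s), aqueductal stroke and respiratory volumes (ASV/ARV,
#' uL) and their ratios.
#'
#' @param summary a `spectrum_summary` (fields `f0_cardiac`, `a0_cardiac`
#'   (mmHg/m), `f1_resp`, `a1_resp` (mmHg/m); a flagged-absent respiratory
#'   peak gives `NA` ratios).
#' @param geom,fluid geometry and fluid properties.
#' @return object of class `flow_summary`: list with `cardiac_pvf_mL_s`,
#'   `resp_pvf_mL_s`, `asv_uL`, `arv_uL`, `pvf_ratio`, `volume_ratio`.
#' @export
summarize_window_flow <- function(summary, geom = aqueduct_geometry(),
                                  fluid = fluid_properties()) {
  sc <- womersley_solution(mmhg_to_pa(summary$a0_cardiac), summary$f0_cardiac,
                           geom, fluid)
  asv <- harmonic_volume(sc)
  resp_ok <- is.finite(summary$a1_resp) && summary$a1_resp > 0 &&
    is.finite(summary$f1_resp) && summary$f1_resp > 0
  if (resp_ok) {
    sr <- womersley_solution(mmhg_to_pa(summary$a1_resp), summary$f1_resp,
                             geom, fluid)
    arv <- harmonic_volume(sr)
    resp_pvf <- sr$pvf_amplitude_A
  } else {
    arv <- NA_real_
    resp_pvf <- NA_real_
  }
  structure(list(
    cardiac_pvf_mL_s = sc$pvf_amplitude_A * 1e6,
    resp_pvf_mL_s = resp_pvf * 1e6,
    asv_uL = asv * 1e9,
    arv_uL = arv * 1e9,
    pvf_ratio = if (resp_ok && resp_pvf > 0) sc$pvf_amplitude_A / resp_pvf
                else NA_real_,
    volume_ratio = if (resp_ok && arv > 0) asv / arv else NA_real_
  ), class = "flow_summary")
}
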