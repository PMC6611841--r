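# Radial finite-difference solver for axisymmetric oscillatory pipe flow:
#   rho dv/dt = mu (d2v/dr2 + (1/r) dv/dr) - dp/dz(t),  0 <= r <= R,
# with no-slip v(R) = 0, symmetry dv/dr = 0 at the axis, start from rest.
# Crank-Nicolson in time (unconditionally stable), second order in space.
# Serves as an independent numerical oracle for the analytical Womersley
# solution; it shares no code with it.

#' Radial grid for the finite-difference solver
#'
#' @param n_points number of radial points including axis and wall (>= 16;
#'   default 65, i.e. 64 intervals).
#' @param n_periods number of periods of the lowest forcing frequency to
#'   simulate before the analysis period (>= 2; the solver may extend this
#'   so the start-from-rest transient has decayed).
#' @param steps_per_period time steps per period of the highest forcing
#'   frequency (>= 100).
#' @return object of class `radial_grid`.
#' @export
radial_grid <- function(n_points = 65L, n_periods = 6L,
                        steps_per_period = 200L) {
  stopifnot(n_points >= 16L, n_periods >= 2L, steps_per_period >= 100L)
  structure(list(n_points = as.integer(n_points),
                 n_periods = as.integer(n_periods),
                 steps_per_period = as.integer(steps_per_period)),
            class = "radial_grid")
}

# Spatial operator (mu/rho) * (d2/dr2 + (1/r) d/dr) on a uniform grid with
# Dirichlet wall and symmetry axis. At r = 0 the operator limits to
# 2 d2v/dr2 (L'Hopital); with the ghost point v(-dr) = v(dr) this gives
# 4 (v1 - v0) / dr^2.
radial_operator <- function(n, dr, nu) {
  A <- matrix(0, n, n)                       # interior + axis rows; wall excluded
  A[1, 1] <- -4 / dr^2
  A[1, 2] <- 4 / dr^2
  for (j in 2:n) {                           # r_j = (j-1) dr
    r <- (j - 1) * dr
    A[j, j - 1] <- 1 / dr^2 - 1 / (2 * r * dr)
    A[j, j] <- -2 / dr^2
    if (j < n) A[j, j + 1] <- 1 / dr^2 + 1 / (2 * r * dr)
    # wall neighbour (j = n, r_{n+1} = R) is Dirichlet zero: term dropped
  }
  nu * A
}

#' Solve oscillatory pipe flow by radial finite differences
#'
#' Integrates the reduced axisymmetric momentum equation driven by a
#' [harmonic_gradient()] (components with `freq_Hz = 0` are steady forcing)
#' from rest, discards the start-up transient, and returns the velocity
#' field and flow-rate series over the final period of the slowest
#' component, together with fitted per-component flow amplitudes. The
#' momentum balance carries `-dp/dz`, so a positive steady gradient drives
#' flow in the negative axial direction (amplitudes are sign-free).
#'
#' The simulated time is the larger of `grid$n_periods` forcing periods and
#' seven e-folding times of the slowest viscous decay mode (rate
#' `mu j01^2 / (rho R^2)`, `j01 = 2.405`), so the periodic state is reached
#' to well under 1 percent before analysis.
#'
#' @param gradient a [harmonic_gradient()].
#' @param geom,fluid geometry and fluid properties.
#' @param grid a [radial_grid()].
#' @return list: `r` radii (m), `time` analysis times (s), `v` velocity
#'   matrix (radii x times, m/s), `q` flow rate (m^3/s), and `amplitudes`, a
#'   data.frame with the least-squares flow amplitude (m^3/s) at each
#'   oscillatory forcing frequency.
#' @export
solve_radial_flow <- function(gradient, geom = aqueduct_geometry(),
                              fluid = fluid_properties(),
                              grid = radial_grid()) {
  R <- geom$radius_R
  rho <- fluid$density_rho
  mu <- fluid$viscosity_mu
  n <- grid$n_points
  dr <- R / (n - 1)
  radii <- seq(0, R, length.out = n)

  freqs <- gradient$freq_Hz
  osc <- freqs > 0
  forcing <- function(t) {               # dp/dz(t), vectorised in t
    g <- 0
    for (k in seq_len(nrow(gradient))) {
      g <- g + if (osc[k])
        gradient$a_Pa_m[k] * sin(2 * pi * freqs[k] * t + gradient$phase[k])
      else gradient$a_Pa_m[k]
    }
    g
  }

  if (any(osc)) {
    p_slow <- 1 / min(freqs[osc])
    dt <- 1 / (max(freqs[osc]) * grid$steps_per_period)
  } else {
    p_slow <- rho * R^2 / mu             # viscous timescale for steady runs
    dt <- p_slow / grid$steps_per_period
  }
  tau1 <- rho * R^2 / (mu * 2.405^2)     # slowest decay mode from rest
  t_total <- max(grid$n_periods * p_slow, 7 * tau1 + p_slow)
  n_steps <- ceiling(t_total / dt)
  t_total <- n_steps * dt

  Aop <- radial_operator(n - 1L, dr, mu / rho)   # unknowns: axis..wall-1
  I <- diag(n - 1L)
  Minv <- solve(I - (dt / 2) * Aop)
  Mexp <- I + (dt / 2) * Aop

  v <- numeric(n - 1L)                   # start from rest
  scale_ref <- max(sum(gradient$a_Pa_m) * R^2 / (4 * mu), .Machine$double.eps)
  t_analysis_start <- t_total - p_slow
  keep_t <- c(); keep_v <- list()
  tn <- 0
  for (s in seq_len(n_steps)) {
    gmid <- forcing(tn + dt / 2)
    v <- Minv %*% (Mexp %*% v - dt * gmid / rho)
    tn <- s * dt
    if (max(abs(v)) > 10 * scale_ref)
      stop("solve_radial_flow: instability detected (solution exceeds 10x ",
           "the forcing scale)")
    if (tn >= t_analysis_start - 1e-12) {
      keep_t[[length(keep_t) + 1L]] <- tn
      keep_v[[length(keep_v) + 1L]] <- as.numeric(v)
    }
  }
  tt <- unlist(keep_t)
  V <- do.call(cbind, keep_v)            # (n-1) x n_kept
  V <- rbind(V, 0)                       # wall row, no-slip
  # flow rate by radial trapezoid of 2 pi r v(r)
  q <- apply(V, 2, function(col) pracma::trapz(radii, 2 * pi * radii * col))

  amps <- data.frame(freq_Hz = numeric(0), amplitude = numeric(0))
  if (any(osc)) {
    X <- do.call(cbind, lapply(freqs[osc], function(f)
      cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))))
    fit <- stats::lm.fit(cbind(1, X), q)
    cf <- fit$coefficients[-1]
    amp <- sqrt(cf[seq(1, length(cf), 2)]^2 + cf[seq(2, length(cf), 2)]^2)
    amps <- data.frame(freq_Hz = freqs[osc], amplitude = as.numeric(amp))
  }
  list(r = radii, time = tt, v = V, q = q, amplitudes = amps)
}
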