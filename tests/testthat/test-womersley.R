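test_that("complex Bessel ratio agrees with the power series at moderate arguments", {
  zs <- c(0.5 + 0i, 2 - 1i, 3 + 4i, 7 * exp(1i * 3 * pi / 4),
          12 * exp(1i * 3 * pi / 4))
  for (z in zs) {
    s <- besselJ01c(z)
    expect_equal(besselJ_ratio10(z), s$J1 / s$J0, tolerance = 1e-10)
  }
  # real axis against base R's Bessel functions
  for (x in c(0.3, 1.7, 5.1)) {
    expect_equal(Re(besselJ_ratio10(x + 0i)),
                 besselJ(x, 1) / besselJ(x, 0), tolerance = 1e-10)
  }
})

test_that("flow amplitude is zero for zero forcing and linear in the amplitude", {
  f <- 1.0
  expect_equal(womersley_solution(0, f)$pvf_amplitude_A, 0)
  A1 <- womersley_solution(100, f)$pvf_amplitude_A
  A3 <- womersley_solution(300, f)$pvf_amplitude_A
  expect_equal(A3, 3 * A1, tolerance = 1e-12)
  expect_error(womersley_solution(100, 0), "Poiseuille|poiseuille")
})

test_that("the low-frequency limit recovers the Poiseuille amplitude", {
  geom <- aqueduct_geometry(); fl <- fluid_properties()
  a <- mmhg_to_pa(1.5)
  A <- womersley_solution(a, 1e-4, geom, fl)$pvf_amplitude_A
  poiseuille <- pi * geom$radius_R^4 * a / (8 * fl$viscosity_mu)
  expect_equal(A, poiseuille, tolerance = 1e-4)
})

test_that("flow amplitude decreases with frequency and approaches the inertial limit", {
  geom <- aqueduct_geometry(); fl <- fluid_properties()
  a <- mmhg_to_pa(1.5)
  fs <- c(0.1, 0.3, 0.85, 2, 5, 20)
  As <- vapply(fs, function(f)
    womersley_solution(a, f, geom, fl)$pvf_amplitude_A, 1)
  expect_true(all(diff(As) < 0))
  # alpha > 50: A -> pi R^2 a / (rho omega)
  f_hi <- freq_for_alpha(60)
  sol <- womersley_solution(a, f_hi, geom, fl)
  expect_gt(sol$womersley_alpha, 50)
  expect_equal(sol$pvf_amplitude_A,
               pi * geom$radius_R^2 * a / (fl$density_rho * sol$omega),
               tolerance = 0.02)
})

test_that("patient-2 average gradients give the published cardiac flow amplitude", {
  sol <- womersley_solution(mmhg_to_pa(1.52), 51 / 60)
  expect_equal(sol$pvf_amplitude_A * 1e6, 0.38, tolerance = 0.10)
})

test_that("harmonic volume equals A/(pi f) and matches half-period quadrature", {
  sol <- womersley_solution(mmhg_to_pa(1.52), 51 / 60)
  V <- harmonic_volume(sol)
  expect_equal(V * 1e9, 144.4, tolerance = 0.05)
  # quadrature oracle: integral of A sin(2 pi f t) over the half period
  A <- sol$pvf_amplitude_A; f <- sol$freq_Hz
  tq <- seq(0, 1 / (2 * f), length.out = 10001)
  expect_equal(pracma::trapz(tq, A * sin(2 * pi * f * tq)), V,
               tolerance = 1e-6)
  expect_equal(harmonic_volume(list(pvf_amplitude_A = 0, freq_Hz = 1)), 0)
})

test_that("the flow-rate series superposes components linearly", {
  geom <- aqueduct_geometry(); fl <- fluid_properties()
  t <- seq(0, 20, by = 0.01)
  g1 <- harmonic_gradient(1.52, 0.85)
  q1 <- flow_rate_series(g1, geom, fl, t)
  A1 <- womersley_solution(mmhg_to_pa(1.52), 0.85, geom, fl)$pvf_amplitude_A
  expect_equal((max(q1) - min(q1)) / 2, A1, tolerance = 1e-3)
  g2 <- harmonic_gradient(c(1.52, 0.46), c(0.85, 0.25))
  q2 <- flow_rate_series(g2, geom, fl, t)
  q2b <- q1 + flow_rate_series(harmonic_gradient(0.46, 0.25), geom, fl, t)
  expect_equal(q2, q2b, tolerance = 1e-12)
  gd <- harmonic_gradient(c(2 * 1.52, 0.46), c(0.85, 0.25))
  qd <- flow_rate_series(gd, geom, fl, t)
  expect_equal(qd - q2, q1, tolerance = 1e-10)
  expect_equal(flow_rate_series(harmonic_gradient(numeric(0), numeric(0)),
                                geom, fl, t), rep(0, length(t)))
})

test_that("band-filtered amplitudes of a two-component series match each A", {
  geom <- aqueduct_geometry(); fl <- fluid_properties()
  fs <- 40; t <- (0:(360 * fs - 1)) / fs
  g <- harmonic_gradient(c(1.52, 0.46), c(0.85, 0.25))
  q <- flow_rate_series(g, geom, fl, t)
  X <- fft(q); n <- length(q)
  amp <- 2 * Mod(X[2:(n / 2)]) / n
  fr <- (1:(n / 2 - 1)) * fs / n
  Ac <- womersley_solution(mmhg_to_pa(1.52), 0.85, geom, fl)$pvf_amplitude_A
  Ar <- womersley_solution(mmhg_to_pa(0.46), 0.25, geom, fl)$pvf_amplitude_A
  expect_equal(max(amp[fr > 0.7 & fr < 1.6]), Ac, tolerance = 1e-6)
  expect_equal(max(amp[fr > 0.15 & fr < 0.4]), Ar, tolerance = 1e-6)
})

test_that("velocity profile satisfies no-slip and integrates to the flow rate", {
  geom <- aqueduct_geometry(); fl <- fluid_properties()
  a <- mmhg_to_pa(1.52); f <- 51 / 60
  t <- seq(0, 1 / f, length.out = 25)
  vR <- velocity_profile(a, f, geom, fl, r = geom$radius_R, t = t)
  expect_true(all(abs(vR) < 1e-15))
  expect_error(velocity_profile(a, f, geom, fl, r = 1.1 * geom$radius_R,
                                t = 0), "\\[0, R\\]")
  r <- seq(0, geom$radius_R, length.out = 401)
  V <- velocity_profile(a, f, geom, fl, r, t)
  q_int <- apply(V, 2, function(col) pracma::trapz(r, 2 * pi * r * col))
  q_ana <- flow_rate_series(harmonic_gradient(1.52, f), geom, fl, t)
  expect_lt(max(abs(q_int - q_ana)) / max(abs(q_ana)), 1e-3)
})

test_that("cohort-average gradients give centimetre-per-second peak velocities", {
  geom <- aqueduct_geometry(); fl <- fluid_properties()
  r <- seq(0, geom$radius_R, length.out = 81)
  t <- seq(0, 8, by = 0.02)
  v <- velocity_profile(mmhg_to_pa(1.46), 62 / 60, geom, fl, r, t) +
    velocity_profile(mmhg_to_pa(0.52), 15 / 60, geom, fl, r, t)
  vmax <- max(abs(v)) * 100                      # cm/s
  # each component contributes a cross-sectional peak mean of 2-3 cm/s;
  # the local peak of the zero-phase sum lands in the 5-9 cm/s decade
  expect_gt(vmax, 5); expect_lt(vmax, 9)
  g <- harmonic_gradient(c(1.46, 0.52), c(62 / 60, 15 / 60))
  q <- flow_rate_series(g, geom, fl, t)
  vmean <- max(abs(q)) / (pi * geom$radius_R^2) * 100
  expect_gt(vmean, 2.5); expect_lt(vmean, 6)
  expect_lt(vmean, vmax)                         # profile peaking
})

test_that("Poiseuille's law gives the third-circulation static gradient", {
  Q <- 500e-6 / 86400                            # 500 mL/day in m^3/s
  g <- poiseuille_static_gradient(Q)
  expect_equal(g$gradient_mmHg_m, 0.0045, tolerance = 0.10)
  expect_equal(poiseuille_static_gradient(0)$gradient_Pa_m, 0)
  half <- poiseuille_static_gradient(Q, aqueduct_geometry(1e-3))
  expect_equal(half$gradient_Pa_m / g$gradient_Pa_m, 16, tolerance = 1e-10)
})

test_that("window flow summaries reproduce published per-patient ratios", {
  p2 <- summarize_window_flow(list(f0_cardiac = 51 / 60, a0_cardiac = 1.52,
                                   f1_resp = 15 / 60, a1_resp = 0.46))
  expect_equal(p2$pvf_ratio, 1.18, tolerance = 0.10)
  p1 <- summarize_window_flow(list(f0_cardiac = 78 / 60, a0_cardiac = 1.59,
                                   f1_resp = 17 / 60, a1_resp = 0.72))
  expect_equal(p1$volume_ratio, 0.13, tolerance = 0.15)
  # symmetric inputs give exactly unit ratios
  sym <- summarize_window_flow(list(f0_cardiac = 1, a0_cardiac = 1,
                                    f1_resp = 1, a1_resp = 1))
  expect_equal(sym$pvf_ratio, 1, tolerance = 1e-12)
  expect_equal(sym$volume_ratio, 1, tolerance = 1e-12)
  # a flagged-absent respiratory peak yields missing ratios
  none <- summarize_window_flow(list(f0_cardiac = 1, a0_cardiac = 1,
                                     f1_resp = 0.25, a1_resp = 0))
  expect_true(is.na(none$pvf_ratio) && is.na(none$volume_ratio))
})
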