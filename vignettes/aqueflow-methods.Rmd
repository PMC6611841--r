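---
title: "From intracranial pressure gradients to aqueductal CSF flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From intracranial pressure gradients to aqueductal CSF flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqueflow)
```

## Overview

`aqueflow` models how pulsatile intracranial pressure (ICP) gradients drive
cerebrospinal-fluid (CSF) flow through the cerebral aqueduct. The pipeline
has three layers: signal analysis of dual-sensor ICP recordings (gradient
formation, window vetting, spectral estimation of the cardiac and
respiratory components), an analytical oscillatory-flow model mapping those
components to flow rates and volumes, and cohort aggregation. A seeded
synthetic-data generator stands in for clinical recordings, and a radial
finite-difference solver independently validates the analytical model.

The scientific point the package makes quantitative is a momentum argument:
the flow volume carried by a sinusoidal flow component of amplitude $A$ and
frequency $f$ is $V = A/(\pi f)$, so at comparable flow amplitudes the slow
respiratory component (~0.25 Hz) displaces about four times the volume per
cycle of the fast cardiac component (~1 Hz). A cardiac-dominated *pressure*
gradient therefore yields a respiration-dominated *flow volume*.

## The differential pressure gradient

Two co-sampled sensors (intraventricular, and subdural or parenchymal —
treated identically) a distance $L$ apart give

$$\mathrm{dICP}(t) = \frac{\mathrm{ICP_{SD}}(t) - \mathrm{ICP_{IV}}(t)}{L}
\quad [\mathrm{mmHg/m}],$$

with the assumption that pressure varies linearly between the sensors and
that this gradient also applies along the aqueduct. The large common-mode
ICP pulsation cancels in the subtraction; what remains is two orders of
magnitude smaller, so sensor noise and posture artifacts matter.

Recordings are cut into consecutive, non-overlapping 360 s windows (the
duration of a typical cardiac-gated PC-MRI acquisition). Overlap is not
used: it would only correlate adjacent summary rows without adding
information. A window is accepted when the range of the *raw pressure
difference* — in mmHg, before division by $L$ and before any mean shift —
is strictly below 2 mmHg. The threshold is dimensionally a pressure, which
is why it is applied before the division; evaluating it before detrending
means a posture-change step anywhere in the window rejects it, which is the
intent. Windows containing missing samples are rejected. Accepted windows
are shifted to zero mean: body position was not recorded, so any static or
hydrostatic offset is unidentifiable and is removed rather than modelled.
Windows are labelled *sleeping* if they start within [00:00, 06:00) by
wall clock — a half-open interval, so a window starting exactly at 06:00 is
awake — and *awake* otherwise; this is a circadian proxy, not sleep staging.

## Spectral estimation

Each accepted window is Fourier-transformed without tapering, giving a
frequency resolution of $1/360$ Hz. The package defines a calibrated
single-sided **amplitude** spectrum, normalised as $2|X_k|/N$ so that a
stationary sinusoid of amplitude $a$ on a bin centre is read off as a peak
of height exactly $a$. Bins above the 15 Hz cutoff are zeroed (the low-pass
is applied to the spectrum, not as a time-domain filter). The cardiac
estimate is the maximum bin in the closed band 0.7–1.6 Hz (42–96
beats/min), the respiratory estimate the maximum in 0.15–0.4 Hz (9–24
breaths/min); ties break toward the lower frequency, and a band whose
maximum is numerically zero (below $10^{-9}$ of the spectrum maximum) is
flagged rather than reported as a peak.

Slow drift and small posture changes inject energy below 0.1 Hz whose
skirts reach into the respiratory band. A decreasing exponential
$A e^{-b f}$ ($A, b \ge 0$) is fitted by linear least squares on
log-amplitudes over the bins below the cardiac band, excluding the
respiratory band so genuine respiratory peaks do not inflate the floor, and
subtracted everywhere with negative results clamped to zero. Because the
drift skirt overlaps the respiratory band, the respiratory amplitude is if
anything conservatively (under-)estimated.

Two numerical caveats are deliberate consequences of this design and are
inherited from the clinical pipeline the package reproduces:

* **Calibration `C`.** Peak-reading a power-type spectrum underestimates
  time-domain amplitudes; the clinical analysis multiplied extracted
  amplitudes by a heuristic $C = 7$ to restore raw-signal scale. With this
  package's amplitude normalisation a bin-centred stationary sinusoid is
  exact at $C = 1$, which is therefore the default; `C` is exposed in
  `spectral_config()` and cancels in every cardiac/respiratory ratio, which
  is what the downstream conclusions rest on.
* **Scalloping.** With no taper and single-bin readout, a sinusoid halfway
  between bins loses up to 36 % of its amplitude ($|\mathrm{sinc}(\delta)|$
  for bin offset $\delta$). Parameter-recovery tests draw frequencies on
  the bin grid to test the pipeline rather than this known leakage floor;
  for real signals, whose frequencies also wander within a window, the `C`
  calibration absorbs the average loss. Amplitude *ratios* are far less
  affected since both bands lose comparably.

The synthetic generator's parameter-recovery suite (50 seeded windows,
gradient signal-to-noise ratio 5) recovers amplitudes with median error
below 5 % and frequencies within one bin.

## The analytical flow model

The aqueduct is idealised as a rigid straight cylinder of radius
$R = 2\ \mathrm{mm}$ (cross-section ~14 mm², the median reported for iNPH
patients). For axisymmetric, fully developed laminar flow the
incompressible Navier–Stokes equations reduce to

$$\rho \frac{\partial v}{\partial t}
 - \frac{\mu}{r}\frac{\partial v}{\partial r}
 - \mu \frac{\partial^2 v}{\partial r^2} = -\frac{dp}{dz}(t),$$

and for a sinusoidal gradient $a\sin(2\pi f t)$ the flow rate is the
classical Womersley solution with amplitude

$$A = \left|\pi R^2 \frac{i a}{\rho\omega}
 \left[1 - \frac{2}{\Lambda}\frac{J_1(\Lambda)}{J_0(\Lambda)}\right]\right|,
 \qquad \Lambda = \alpha\, i^{3/2},\quad
 \alpha = R\sqrt{\omega\rho/\mu}.$$

$\alpha$ is the Womersley number; cardiac forcing sits near $\alpha
\approx 6$ (inertia-limited), respiratory near $\alpha \approx 3$. Note the
sign convention: the momentum balance carries $-dp/dz$, so a positive
steady gradient drives flow in the negative axial direction; amplitudes and
volumes are sign-free. As $\omega \to 0$ the amplitude tends to the
Poiseuille value $\pi R^4 a/(8\mu)$, and as $\alpha \to \infty$ to the
inertial limit $\pi R^2 a/(\rho\omega)$ — both verified in tests. Each
window's two spectral components are mapped through this formula
(superposition is exact in the linear model) to cardiac and respiratory
peak volumetric flow rates (PVF), and to per-cycle volumes
$V = A/(\pi f)$: the aqueductal stroke volume (ASV, cardiac) and
respiratory volume (ARV).

Defaults: $\rho = 1000\ \mathrm{kg/m^3}$, $\mu = 0.7\times10^{-3}$ Pa s
(CSF is close to water at body temperature; no measured values accompany
the recordings). All internal computation is SI with a single conversion
constant 133.322 Pa/mmHg. Component phases default to zero (pure sines):
relative phase does not enter PVF, ASV or ARV, only waveform plots and the
instantaneous peak velocity — which is why the maximum pointwise velocity of
a zero-phase two-component sum (~8 cm/s for cohort-average inputs) exceeds
the "typical" 5–6 cm/s quoted for per-component contributions.

Complex Bessel evaluation: $J_0, J_1$ use the power series for $|z| \le
20$; the ratio $J_1/J_0$ that the amplitude needs uses the standard
backward recurrence $h_\nu = 1/(2\nu/z - h_{\nu+1})$, stable to $\alpha$ of
at least 100. `velocity_profile()` needs $J_0$ itself and is limited to
$\alpha \le 20$, well beyond the physiological range.

The steady "third circulation" comparison uses Poiseuille's law:
$dp/dz = 8\mu Q/(\pi R^4) \approx 0.0048$ mmHg/m for 500 mL/day — about two
orders of magnitude below the measured pulsatile gradients.

## The finite-difference oracle

`solve_radial_flow()` integrates the reduced momentum equation directly:
Crank–Nicolson in time (unconditionally stable — the boundary layer at
$\alpha \approx 6$ is thin), second-order central differences on a uniform
radial grid (default 65 points), no-slip at the wall, and the axis
singularity handled by the symmetry expansion: at $r = 0$ the operator
limits to $2\mu\,\partial^2 v/\partial r^2$, discretised with a ghost point
as $4(v_1 - v_0)/\Delta r^2$. The solver starts from rest and simulates the
larger of six slow-component periods and seven e-folding times of the
slowest viscous decay mode ($\rho R^2/(\mu j_{01}^2)$, $j_{01} = 2.405$),
then analyses the final slow period, fitting sine/cosine pairs at each
forcing frequency to extract amplitudes. It shares no code with the
analytical route and agrees with it to better than 1 % across
$\alpha \in [1, 10]$, with grid-halving changes below 0.5 %.

## Peak/valley flow decomposition

To decompose an arbitrary flow-rate curve (e.g. from a 3D simulation or a
measured flux series), the cardiac oscillation is treated as riding on the
slower respiratory one: the midpoints $(Q_p + Q_v)/2$ of successive
peak/valley pairs trace the respiratory component $Q_r(t)$, and
$Q_c = Q - Q_r$. Three realisation choices were genuinely open and were
settled as follows:

* **Interpolant.** The midpoint interpolant is realised as the mean of the
  peak and valley envelopes (natural cubic splines through the extrema,
  constant beyond the outermost ones; piecewise-linear selectable). A
  single pass leaves a residual of the respiratory curvature in $Q_c$ —
  a plain linear midpoint chain attenuates the respiratory amplitude by
  roughly $\cos(\pi f_r / 2 f_c)$ (~7–10 %) and inflates the cardiac PVF by
  kink harmonics — so a second pass re-extracts the envelope mean of the
  remainder (`n_sift = 2`). This drops worst-case component-PVF errors from
  ~17 % to under 8 % across frequency ratios ≥ 3.
* **Analysis interval.** Defaults to the final 10 s of the series, but the
  envelopes are always built from the full series and the interval is
  intersected with the extremum-covered region, so envelopes are never
  extrapolated — extrapolated spline tails otherwise dominate the component
  extrema.
* **Peak detection.** Local extrema, with adjacent swings below 2 % of the
  series range pruned as noise. The threshold is deliberately small:
  cardiac swings shrink relative to the total range when respiration
  dominates, and an aggressive threshold (10 %) can swallow genuine cardiac
  extrema entirely. Raise `prominence_frac` (to ~0.05) for noisy measured
  series.

Per-cycle volumes follow the trapezoidal rule: $\int |Q_i|/2\,dt$ from the
first to the last peak of the component, divided by the number of full
cycles; on a pure sinusoid this converges to $A/(\pi f)$ to $10^{-4}$
relative at fine sampling, matching the analytical volume definition.

The method requires the cardiac extrema to be visible throughout: where the
respiratory slope exceeds the cardiac slope amplitude
($A_r\,2\pi f_r > A_c\,2\pi f_c$) the composite is locally monotone,
extrema vanish, and no interpolant can recover the hidden component.
`decompose_flow()` warns when the estimated frequency ratio falls below 2
and when irregular peak spacing signals swallowed extrema. Within the
slope-dominated regime, round-trip tests against the analytical model
recover PVFs within 10 % and volumes within 15 %.

When only a cardiac gradient is known (e.g. from cardiac-gated flow
measurements), `construct_resp_gradient()` builds a representative
respiratory component using the cohort-average ratios: amplitude 2.85 times
smaller, frequency 4.11 times lower.

## Cohort aggregation

Windows average to patient means first; cohort statistics are mean ±
sample (n−1) standard deviation across patient means, never across pooled
windows — patients contribute equally regardless of how many clean windows
they yield. Ratio quantities are averaged as per-window ratios, not ratios
of means. Patients with fewer than two accepted windows are excluded (a
single window gives no within-patient variability). The sleep/awake
comparison is a two-sided paired t-test per quantity on patient sub-means,
with pairwise exclusion of patients missing a state and explicit reporting
of degenerate (zero-variance) cases; no multiple-comparison correction is
applied, matching the descriptive use of the test. The period ratio is
respiratory rate over heart rate per patient (≈ 0.25: a cardiac cycle is a
quarter of a respiratory cycle).

## The synthetic generator

`synthetic_spec()`/`generate_recording()` emulate the structure of real
dual-sensor recordings: a shared common-mode pulsation (cardiac amplitude
4.5 mmHg by default, mid-range of the typical 4–5 mmHg, plus a quarter-
amplitude respiratory term) that cancels exactly in the difference; a
differential gradient with cardiac (default 1.46 mmHg/m at 62/min) and
respiratory (0.52 mmHg/m at 15/min) sinusoids — the cohort-average
conditions — plus optional sub-0.1 Hz drift; step artifacts for posture
changes; and independent Gaussian white noise per channel (the sensor noise
spectrum is uncharacterised; white is the minimal assumption and is flagged
as such). Generation is deterministic for a fixed seed and leaves the
global RNG untouched.

What the generator does *not* emulate bounds what green tests prove:
no physiological waveform morphology (percussion/tidal/dicrotic sub-peaks,
so no harmonics above the fundamentals), no heart-rate variability within a
window, no correlated or 1/f sensor noise, no sensor-pair systematic
offsets. Passing recovery tests show the pipeline is correct for signals of
the assumed two-sine-plus-drift structure, not that the spectral estimates
are unbiased for real waveforms.

## Problem sizes and numerical tolerances

Test and validation runs use: 360 s windows at 40–200 Hz sampling (50
windows at 200 Hz for the recovery suite), finite-difference grids of
33–65 radial points with 100–400 steps per period, and decomposition grids
of 5 ms over 30–40 s. These sizes put every advertised tolerance (1 %
oracle agreement, 0.1 % steady profile, 5 % spectral recovery, 10 %/15 %
decomposition round-trip) comfortably inside their asymptotic regimes.
Key numeric guards: spectra treat values below $10^{-9}$ of the maximum as
zero; the trend fit falls back to the identity (with a warning) on
degenerate spectra; the finite-difference solver aborts if the solution
exceeds ten times the quasi-static forcing scale.

## Known limitations

* The rigid, straight, constant-radius cylinder ignores aqueduct curvature,
  stenosis, wall compliance and entrance effects; absolute flow values
  scale strongly with the assumed radius ($R^4$ at low, $R^2$ at high
  $\alpha$), while cardiac/respiratory *ratios* are much less sensitive.
* Zero-mean shifting removes any static (including hydrostatic) gradient,
  so net bulk flow is outside the model by construction.
* The circadian label is a clock proxy; "sleeping" windows mix sleep and
  sleep-independent circadian effects.
* Spectral amplitudes for off-bin frequencies are biased low by scalloping
  (see above); amplitude ratios largely cancel the bias.
* The decomposition assumes separated timescales with visible cardiac
  extrema; it degrades — with warnings — outside that regime.
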