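---
title: "Model-based synthetic ECG generation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based synthetic ECG generation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(ecgsim)
```

`ecgsim` synthesizes normal and pathological electrocardiogram (ECG)
waveforms — including full 12-lead profiles — by numerically integrating four
dynamical models of macroscopic heartbeat dynamics. The package targets users
who need controllable, reproducible reference waveforms: for exercising ECG
signal-processing pipelines (filtering, QRS detection, rhythm classification),
for teaching arrhythmia morphology, and for testing waveform I/O in clinical
data formats. It deliberately does *not* fit models to clinical recordings and
does not model transmembrane ionic currents; the models are phenomenological
descriptions of the conduction system at the organ scale.

## The four models

### A heterogeneous network for the conduction system

The cardiac conduction cascade — sinoatrial (SA) node, atrioventricular (AV)
node, His–Purkinje (HP) system — is represented by three modified Van der Pol
oscillators coupled unidirectionally with transport delays:

$$\dot x_i = y_i, \qquad
  \dot y_i = -a_i\,(x_i^2 - u)\,y_i - f_i\,x_i (x_i + d)(x_i + e_i)
             + K\,\bigl(y_{up}(t-\tau) - y_i\bigr),$$

where the SA node is autonomous, the AV node receives the delayed SA velocity,
and the HP system receives the delayed AV velocity. The electrical responses
of the working muscle — one excitable unit each for the P wave, the atrial
repolarization (Ta) wave, the QRS complex and the T wave — are modified
FitzHugh–Nagumo systems

$$\dot z_j = k_j\bigl(-c_j z_j (z_j - w_{j1})(z_j - w_{j2}) - b_j v_j
            - g_j v_j z_j + I_j\bigr), \qquad
  \dot v_j = k_j h_j (z_j - v_j),$$

driven by stimulation currents $I_j = C_j Y_j H(Y_j)$ gated by the unit step,
with $Y_1 = y_1$, $Y_2 = -y_1$ (atrial channels follow the SA velocity) and
$Y_3 = y_3$, $Y_4 = -y_3$ (ventricular channels follow the HP velocity). A
lead channel is the linear composition
$z_0 + \alpha_1 z_1 - \alpha_2 z_2 + \alpha_3 z_3 + \alpha_4 z_4$.

Two conduction blocks ship as presets: setting the SA→AV coupling to zero
(complete SA–AV block) lets the AV node free-run, so atrial and ventricular
rhythms dissociate; setting AV→HP to zero (complete AV–HP block) leaves the
atria normal while the ventricles escape at the slow intrinsic HP rate.

*Step-function convention.* $H(0) = 0$: currents switch on only for strictly
positive drive. The trajectory spends measure-zero time at zero so the choice
is dynamically immaterial, but fixing it makes runs bit-reproducible.

*Per-lead weights.* The clinically fitted per-lead $\alpha$ weights are not
distributed with the package. The shipped `default_lead_weights()` table is a
**synthetic** replacement, chosen so lead II carries the canonical morphology
and V1–V6 follow the textbook precordial R-wave progression; every value is
user-overridable, and users with fitted weights should substitute them.

### A discretized reaction–diffusion network

Spatially discretizing the BVAM reaction–diffusion system yields four coupled
ordinary differential equations:

$$\begin{aligned}
\dot x_1 &= x_1 - x_2 - C x_1 x_2 - x_1 x_2^2,\\
\dot x_2 &= H x_1 - 3 x_2 + C x_1 x_2 + x_1 x_2^2 + \beta (x_4 - x_2),\\
\dot x_3 &= x_3 - x_4 - C x_3 x_4 - x_3 x_4^2,\\
\dot x_4 &= H x_3 - 3 x_4 + C x_3 x_4 + x_3 x_4^2 + 2\beta (x_2 - x_4),
\end{aligned}$$

with ECG read-out $K_1 x_1 + \dots + K_4 x_4$. The rhythm class is selected by
$H$ and the mixing weights; $C$ and $\beta$ are shared with the normal row.

*Initial condition.* The origin is an equilibrium, and numerically its
neighborhood is attracting along near-uniform directions: small symmetric
kicks such as $(0.01, 0.01, 0.01, 0.01)$ decay back to rest, and the system
also possesses stable non-oscillatory fixed points for several tabulated $H$
values. The package therefore starts from the asymmetric unit kick
$(1, 0, 0, 0)$, which reaches the large oscillatory attractor for every
shipped parameter row; this was verified numerically over long horizons for
all five presets.

### A ring of three delay-coupled oscillators

Each pacemaker is a modified Van der Pol oscillator with position $x$ and
velocity $v$,

$$\dot v = -a\,v\,(x - w_1)(x - w_2) + \rho \sin(\omega t)
           - \frac{x (x - d)(x - e)}{d\,e}
           - \sum_Y k_{X\text{–}Y}\,\bigl(x - x_Y(t - \tau_{X\text{–}Y})\bigr),$$

with six directed delayed difference couplings and the affine read-out
$(\alpha_0 + \alpha_1 x_1 + \alpha_3 x_3 + \alpha_5 x_5)\,\beta_G$.

Two reconstruction choices deserve explanation, because the published
parameter tables for this model family are typographically ambiguous:

* **Cubic normalization.** The restoring cubic is implemented as
  $x(x-d)(x-e)/(de)$, the convention of the delay-coupled three-oscillator
  family this model derives from, giving each node a small-amplitude natural
  frequency of about 1 rad per model time unit. Without the normalization the
  natural frequency is $\sqrt{de} \approx 3.7$ rad/unit and every tabulated
  rhythm lands at 230–460 beats/min after time compression — faster than any
  physiological rhythm and inside the R-peak detector's refractory window.
* **Drive frequency units.** The tabulated sinusoidal drive frequencies are
  interpreted in the *un-normalized* oscillator's time base (for the
  fibrillation row, $\omega = 7.33 \approx 2\sqrt{de}$ — a 2:1 parametric
  resonance). The derivative converts them by $1/\sqrt{|de|}$, preserving the
  drive-to-natural frequency ratio of the printed parameter set. With this,
  the fibrillation preset is disorganized (relative RR spread ≈ 0.6) while
  the undriven rhythms ($\omega = 0$) are untouched.
* **Drive entry.** The drive enters additively, $+\rho\sin(\omega t)$, the
  natural parse of the source equations; at an instant where $\sin = 1$ it
  contributes exactly $\rho$ to the velocity derivative.

The HP-node oscillator coefficients are absent from the published tables; the
shipped defaults ($a = 5$, $w_{1,2} = \pm 1$, $d = 3$, $e = 7$, zero HP–AV
delay) are synthetic, chosen once so that the four shipped ring rhythms fall
in their nominal classes (bradycardia slowest, flutter rapid, fibrillation
irregular), and documented here so they can be replaced.

### A quasi-periodic Gaussian-kernel model

A planar oscillator with an attracting unit limit cycle,
$\dot x = \alpha x - \omega y$, $\dot y = \alpha y + \omega x$,
$\alpha = 1 - \sqrt{x^2 + y^2}$, carries three waveform channels $P$, $C$
(QRS) and $T$. Seven Gaussian kernels ($P^-, P^+, Q, R, S, T^-, T^+$) at
angular positions $\theta_i$ push and pull their channel as the trajectory
angle passes:

$$\dot P = -\!\!\sum_{i \in \{P^-,P^+\}}\!\! a_i\,\Delta\theta_i\,
  e^{-\Delta\theta_i^2 / 2 b_i^2} - (P - P_0), \qquad
  \Delta\theta_i = \mathrm{wrap}(\theta - \theta_i) \in [-\pi, \pi),$$

and likewise for $C$ (kernels $Q, R, S$) and $T$. The common baseline
$P_0 = C_0 = T_0 = A \sin(2\pi f_r t)$ couples all channels to respiration;
the ECG is $P + C + T$.

Three design notes:

* **Rotation sign.** As commonly printed, the second planar equation reads
  $\dot y = \alpha y - \omega x$, which is not a rotation (the linear part is
  then a shear with real eigenvalues, and no closed orbit exists). The
  package implements $\dot y = \alpha y + \omega x$, the unique sign choice
  that yields the attracting unit limit cycle the model is built around.
* **Angular frequency.** $\omega = 2\pi \cdot \mathrm{HR}/60$ with a
  per-preset heart rate; because the published arrhythmia kernel tables carry
  no rates, the defaults (normal 60, bradycardia 45, tachycardia 130,
  ventricular tachycardia 150, ventricular flutter 270 beats/min) were fixed
  once from the standard clinical definitions of those rhythm classes
  (bradycardia < 60, ventricular tachycardia > 120, flutter 250–300) and are
  user-overridable. Atrial fibrillation instead draws beat-to-beat intervals
  from a seeded RR tachogram (below).
* **Amplitude convention.** Kernel amplitudes are used exactly as given in
  the preset tables. The alternative convention $a_i \mapsto a_i b_i^2$ used
  by a related model family is available behind the `a_transform` flag
  (default off, since the shipped tables are calibrated for direct use).

*RR tachogram.* `rr_tachogram_spec()` describes heart-period variability as
a Gaussian process with the classic bimodal spectrum: a low-frequency band
(default center 0.1 Hz, the Mayer wave) and a high-frequency respiratory band
(0.25 Hz), band widths 0.01 Hz, LF/HF power ratio 0.5. Realizations are
synthesized in the frequency domain with uniformly random phases under a
caller-supplied seed, rescaled to the requested heart-rate mean and standard
deviation, and clamped to the physiological interval [0.2 s, 3 s]. The atrial
fibrillation preset uses mean 100 beats/min with standard deviation 15 — a
deliberately coarse surrogate: real fibrillation is not a stationary Gaussian
process, and passing the irregularity checks here says nothing about
detecting clinical fibrillation.

## Numerical integration

All models are advanced with the classical fixed-step fourth-order
Runge–Kutta scheme (`rk4_step()`, compiled cores in C++). The step is
$h = 10^{-3}$ model time units for every model — halving it changes a 30 s
trajectory by well under 0.1% RMS for all shipped presets — and must not
exceed the smallest positive coupling delay.

Delayed couplings are resolved from a sample buffer: the delayed value is the
stored sample at offset $\mathrm{round}(\tau/h)$, it is **frozen across the
four stages of a step** (looked up once at the step start), and lookups
reaching before the start of the run return the constant initial state (the
standard constant-history convention for delay differential equations). A
dense-history oracle that interpolates the delayed value linearly in time is
kept in the test suite; at $h = 10^{-3}$ the two agree to well below the
$10^{-3}$ RMS level over 10 s of ring-model time, and exactly when
$\tau/h$ is an integer. A pure-R mirror of the whole integrator
(`integrate_reference()`) reproduces the compiled trajectories to better than
$10^{-12}$ and serves as the readable reference implementation.

Integration aborts with a diagnostic (time and last finite state) if any
state becomes non-finite; exact equilibria are preserved bitwise (every term
of the heterogeneous and reaction–diffusion right-hand sides carries a state
factor, so the zero state yields exactly zero derivatives in floating point).

## From trajectory to waveform

`render_trace()` applies the model's composition map pointwise, divides the
time axis by the preset's time-scale factor ($\Gamma_t$ for the
reaction–diffusion model, $\beta_T$ for the ring; both interpreted as
*compression* factors, so $\Gamma_t = 21$ beats three times faster than
$\Gamma_t = 7$), discards the start-up transient (default 20% of the run,
capped at 5 s of output time), resamples by linear interpolation onto a
uniform grid (default 500 Hz, a typical clinical rate), and scales the
amplitude so the largest excursion from the median baseline equals the
preset's gain (default 1 mV, confined to the 0.5–4 mV range of a calibration
device's output stage). A flat composed signal falls back to unit scale with
a warning. For 12-lead sets one common scale factor (calibrated on lead II)
is applied to all channels, preserving inter-lead amplitude ratios.

## Lead algebra

The heterogeneous model is the one model that produces a full 12-lead
profile. Leads I and II are composed directly from their weight rows; the
limb electrode potentials are recovered under the gauge
$\mathrm{RA} + \mathrm{LA} + \mathrm{LL} = 0$ (Wilson central terminal at
zero), and III, aVR, aVL, aVF follow from the exact Einthoven and Goldberger
relations — so $II = I + III$ and $\mathrm{aVR} + \mathrm{aVL} +
\mathrm{aVF} = 0$ hold to rounding error by construction. V1–V6 are composed
directly against the zero Wilson terminal. The other three models reproduce
the single standard Einthoven lead II.

## Beat-rate estimation

`estimate_beat_rate()` detects R peaks on the absolute baseline-corrected
signal (several presets have negative-dominant deflections) with an adaptive
threshold — 0.6 of the 98th-percentile magnitude of candidate local maxima —
and a 0.2 s refractory window keeping the largest excursion per window; the
rate is $60/\mathrm{median}(RR)$. The threshold is referenced to candidate
*peak* magnitudes rather than to all samples because for sparse QRS
complexes the sample-level 98th percentile sits at T-wave level and
double-counts T waves. A rhythm is flagged irregular when
$\mathrm{IQR}(RR)/\mathrm{median}(RR) > 0.1$; fewer than two detected peaks
give an undefined-rate flag. These defaults detect R peaks across all shipped
presets except the fibrillation rhythms, where the irregular/undefined flag
is the intended behavior.

## What the shipped presets do and do not show

The 18 shipped presets encode the published parameter rows for the four
models (normal rhythm plus conduction blocks, tachycardias, flutters and
fibrillation), stored as JSON with arrhythmias expressed as sparse overrides
of their normal base row — so "an arrhythmia changes only the listed fields"
is a machine-checkable property. Every preset integrates 30 s of output
stably, with bounded pre-gain output and a nonconstant waveform.

These are *synthetic* waveforms from low-dimensional deterministic models:
they contain no measurement noise, no electrode motion artifacts, no
beat-to-beat morphology variability (outside the tachogram mode), and no
inter-patient variation. Passing the package's checks demonstrates the
dynamical and algebraic properties of the models, not clinical fidelity of
any downstream algorithm.

## Problem sizes

The test suite and the acceptance script run each preset for 30 s of output
time at the default step ($h = 10^{-3}$; up to $6.3\times10^5$ RK4 steps for
the most compressed preset), use 1000 random electrode triples for the lead
identities, 10 s of model time for the delay-buffer oracle comparison, and
three step-halvings for the RK4 order check — sizes at which every quantity
reported is stable to well inside its stated tolerance.

```{r example, eval = FALSE}
library(ecgsim)
ecg <- simulate_ecg("quasi_periodic", "normal", duration = 10, seed = 1)
estimate_beat_rate(ecg)
leads <- simulate_leads12("normal", duration = 10)
ggplot2::autoplot(leads)
```
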