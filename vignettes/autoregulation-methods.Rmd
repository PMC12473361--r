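---
title: "Methods: REG-based assessment of dynamic cerebral autoregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: REG-based assessment of dynamic cerebral autoregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement and the model

Rheoencephalography (REG) measures the electrical impedance of a head segment;
impedance falls as pulsatile blood volume rises, so the detrended impedance
waveform tracks cardiac-cycle cerebral blood-volume dynamics. Paired with
continuous arterial pressure, both at 200 Hz, it supports two views of dynamic
cerebral autoregulation.

## Systems level

Poiseuille flow through the cerebral bed gives $Q(t) = P(t)/R(t)$, neglecting
venous pressure (typically a few mmHg against an arterial mean near 80 mmHg;
the package represents this only as a documented omission). Autoregulation is
modeled as proportional negative feedback of the resistance toward a target
flow $Q_0$:

$$\frac{dR}{dt} = k\left(\frac{P}{R} - Q_0\right)$$

This is nonlinear in $R$. First-order Taylor expansion about the operating
point $(P_0, R_0, Q_0 = P_0/R_0)$, dropping quadratic perturbation terms,
yields a first-order linear time-invariant model in the perturbations:

$$\tau\,\frac{d\Delta Q}{dt} + \Delta Q = G\,\frac{d\Delta P}{dt},
\qquad \tau = \frac{R_0}{k\,Q_0},\qquad G = \frac{1}{k\,Q_0}.$$

$\tau$ (seconds) is the speed of the regulatory response; $G$ (Ω/mmHg, since
$\Delta Q$ is observed through impedance) its sensitivity to the *rate* of
pressure change. Note $\tau/G = R_0$ identically. `simulate_nonlinear()`
integrates the feedback law with classical RK4; the package's property tests
confirm the linearization is second-order accurate (nonlinear-vs-linear
divergence scales as $\varepsilon^2$ in the perturbation size).

The model's validity assumptions — operation near a steady point, resistance
as the only actuator, venous pressure negligible — are reasonable for seated
or standing rest but not during large maneuvers; the transient itself is
therefore analyzed at the temporal level instead.

## Temporal level

The standardized REG waveform is the ensemble average of time-normalized
cycles from a pre-maneuver baseline window (default the first 60 s, roughly 75
cycles at rest). Each later cycle, time-normalized to the template length, is
Pearson-correlated with the template; the per-cycle $r$ versus time is the
recovery curve, and the count of cycles from maneuver onset until $r$ stays at
or above $\theta$ for $m$ consecutive cycles is the cycles-to-recovery. The
onset is an explicit input (the stand command is logged in any protocol of
this kind), not auto-detected.

# Estimation choices

## Discretization and identification

The LTI model is discretized by backward Euler with step $h = 1/f_s$:
$y_n = \alpha y_{n-1} + \beta (x_n - x_{n-1})$, $\alpha = \tau/(\tau+h)$,
$\beta = G/(\tau+h)$, $y_0 = 0$. Step-response error against the closed form
$(GA/\tau)e^{-t/\tau}$ halves when $h$ halves (first-order convergence),
which the test suite asserts.

`fit_lti()` first estimates $(\alpha, \beta)$ by ordinary least squares on the
regression $y_n \sim y_{n-1} + \Delta x_n$ (an intercept absorbs centering
constants; the fit is invariant to offsets in either series). On noise-free
data this is exact. On measured data it is not: white measurement noise on the
output enters the lagged regressor $y_{n-1}$, attenuating $\hat\alpha$
(classical errors-in-variables bias), and the map
$\tau = \alpha h/(1-\alpha)$ amplifies that attenuation by
$h/(1-\alpha)^2$ — about a factor 8 at $\tau = 0.2$ s and 200 Hz. At the
headband's own noise floor this bias reaches ~10% of $\tau$, which is
scientifically material. The default estimator therefore refines $(\tau, G)$
by Levenberg–Marquardt minimization of the *free-run* prediction error
(output-error method; `minpack.lm`), which is consistent under additive white
output noise. `method = "arx"` retains the plain least-squares estimator.

Goodness of fit is always computed on the free-run prediction — the model
simulated from pressure alone, never fed the measured output — because
one-step-ahead errors at 200 Hz are trivially small for any $\alpha$ near 1.
The first 2 s (`warmup_s`) are excluded to wash out the $y_0 = 0$ initial
condition. Estimates with $\alpha$ outside $(0,1)$ are reported and flagged,
never clamped; a zero-variance output yields $G = 0$ with a degenerate-$\tau$
warning.

## Tunable parameters

| Parameter | Default | Units | Rationale |
| --- | --- | --- | --- |
| `cutoff_hz` | 0.5 | Hz | baseline drift is sub-cardiac; 0.5 Hz sits below the slowest physiological heart rate (~36 bpm) |
| `order` | 8 | – | steep transition so the 1–2 Hz pulse band is untouched (squared magnitude at 1.2 Hz ≈ 8·10⁻⁷) |
| `width_range` | (0.5, 1.5)×median | – | symmetric cycle-duration screen tolerant of sinus arrhythmia |
| `amp_range` | (0.5, 2)×median | – | rejects low-amplitude fragments and spikes |
| `min_rise_frac` | 0.3 | – | sustained upstroke requirement; robust to dicrotic secondary peaks |
| `step_mult` | 5× the 99th percentile of the slew distribution | – | conservative, rate-free step/spike artifact rule |
| `M` | round(mean period × fs) | samples | template phase grid equals the mean-duration cycle |
| `theta` | 0.98 | – | "returned to equilibrium" correlation threshold |
| `m` | 3 | cycles | persistence; prevents a single template-like cycle from ending the count |
| `warmup_s` | 2 | s | free-run initial-condition washout |

$\theta$ and $m$ have no canonical values in the literature; both are reported
in every output so results are interpretable.

# Numerical design

**Zero-phase filtering.** An 8th-order Butterworth at 0.5 Hz on 200 Hz data
has a normalized cutoff of 0.005; in single-polynomial transfer-function form
its eight poles cluster so near $z = 1$ that filtering diverges in double
precision (observed overflow ~10⁴¹). The filter is therefore realized as a
cascade of four biquad sections, each the bilinear transform (with cutoff
prewarping) of one conjugate analog pole pair, applied forward and backward.
Bidirectional application squares the magnitude response and cancels phase
distortion exactly; the operator commutes with time reversal to rounding
error. Records are padded by odd reflection (30 s, capped at the record
length) with the DC offset removed before filtering, making constants exact
fixed points. As with any finite-record zero-phase filter, the outermost few
seconds carry boundary error of order the endpoint's deviation from the local
mean; tests of steady-state attenuation therefore evaluate the interior, and
the identification pipeline is unaffected (its warm-up exclusion covers the
edge).

**Cycle segmentation.** The fundamental period is first estimated from the
autocorrelation maximum in the 30–240 bpm lag range; peak picking then
enforces a minimum separation of 0.55 periods, so dicrotic bumps and
derivative side lobes are never counted as cycles. Cycle boundaries are the
signal minima between retained peaks, localized on a 20 ms moving-average
smoothed copy because the diastolic valley is shallow relative to measurement
noise. Cycles are half-open trough-to-trough segments, each containing one
systolic peak, so the AUC reference minimum is the segment's own trough.

**Boundary-jitter-robust correlation.** Even with smoothed localization,
detected boundaries jitter by a sample or two, which would shift a
time-normalized cycle against the template and depress the correlation of a
morphologically intact cycle (observed: clean cycles dropping to $r \approx
0.9$). `recovery_curve()` therefore evaluates the correlation over a small
window of candidate boundary shifts (±1.5% of the template length) and reports
the value at the highest-magnitude alignment. The statistic remains a
per-cycle Pearson correlation — bounded in $[-1, 1]$, amplitude- and
offset-invariant — and an exactly inverted cycle still reports $r = -1$.

**AUC.** The per-cycle area uses the trapezoid rule above the cycle minimum,
$s_i = (Q_i + Q_{i+1})/2 - \min Q$ in sample units, summed and divided by
$f_s$ to give Ω·s. It is non-negative by construction, invariant to constant
offsets, and equivariant under positive scaling.

# The synthetic-data generator

`gen_abp()` builds pressure as a slow sit-to-stand trajectory — seated plateau
at 76.1 mmHg, a transient dip (default depth 15 mmHg, the typical initial
orthostatic MAP drop) at the stand, exponential settling 13.1 mmHg above
baseline — plus a per-beat pulse at 55.8 mmHg pulse pressure (108.7/52.9) and
75 beats/min with ±3% per-beat interval jitter. Beat morphology is a
log-normal systolic bump plus a smaller delayed dicrotic bump on a diastolic
arch. The per-beat time average equals the slow trajectory, so beat averaging
recovers it.

`gen_reg_from_abp()` couples REG to pressure *through the LTI model itself*
($\Delta Q$ = `simulate_linear` of the pressure perturbation), so sample-level
identification is exactly well-specified, then adds the 212.2 Ω baseline
impedance, slow drift (0.02 Hz sinusoid plus a bounded smoothed random walk,
amplitude 1 Ω), and white noise at σ = 0.005 Ω — the headband's stated
absolute impedance error. Defaults for $\tau$ use the young-adult value
0.0696 s. The default gain is 0.001 Ω/mmHg: the young-group reported gain
(~3·10⁻⁹ Ω/mmHg) is numerically zero, under which the REG output would
contain no pressure-coupled component at all and $\tau$ would be
unidentifiable from any estimator; the six-order-of-magnitude spread between
group gains has no stated explanation, and this package reports gains as
estimated without attempting to reconcile that scale.

`gen_recovery_scenario()` instead builds REG directly from cycle morphologies:
clean two-bump cycles before the onset, then exactly `perturb_cycles` cycles
blended toward a single-bump morphology (blend factor chosen deterministically
so each perturbed cycle correlates below 0.9 with the clean shape, with a 1.3×
amplitude fluctuation), then clean again. The diastolic arch term
$\sin(\pi\phi)^{1/2}$ in all morphologies keeps the waveform descending
steeply into the end-diastolic minimum; without it the cycle tail is flat and
boundary localization under noise jitters enough to break exact recovery
counting. Ground truth (onset time and cycle, injected count, blend factor)
rides along with every output, and regeneration under a fixed seed is
bit-identical.

`gen_cohort()` draws per-subject $(\tau, G)$ from group-wise normals (young:
0.0696 ± 0.005 s; middle-aged: 0.2006 ± 0.0045 s; $\tau$ truncated positive
by redraw) for group-statistics work.

**What the generator does not emulate:** respiratory modulation, baroreflex
heart-rate coupling, nonstationary cycle morphology drift, electrode-motion
artifacts, the Finapres device's self-calibration steps, and any nonlinearity
in the pressure-to-impedance pathway (an amplitude-modulation stress mode is
deliberately out of scope). Passing tests on generated data therefore
demonstrate correctness of the algorithms under the stated model, not
field performance on recordings with these confounds.

# Packet format

Capture files are hex text of framed packets: start byte `0x68`, a 2-byte
payload length, function code (`0x27` = left hemisphere), 4 bytes per sample,
a 2-byte checksum, end byte `0x16`. The device documentation fixes none of
the CRC algorithm, byte order, or ADC-to-Ω scale, so all are configuration:
defaults are CRC-16/CCITT-FALSE over function code through payload,
little-endian integers, and 0.001 Ω per raw unit, never inferred from data.
Corrupt packets are skipped with a message rather than aborting a long
capture; framing errors identify the byte offset.

# Problem sizes and reproducibility

Validation runs use the study-scale conditions throughout: 300 s recordings
at 200 Hz (60,000 samples), 30-recording batches for parameter-recovery
means, 30 + 30 subject cohorts, and an exhaustive 0–20-cycle perturbation
sweep for recovery counting; the cross-$\tau$ recovery property in the unit
suite uses 8 seeds per $\tau$ to keep the default test run brisk. All
randomness descends from single integer seeds; `run_pipeline()` re-runs are
byte-identical.

# Known limitations

- $G$ is reported in Ω/mmHg as observed through impedance; no conversion to
  volumetric flow units is attempted, so gains are comparable within-device
  only.
- The two-level report is descriptive. No normal/abnormal cutoffs for $\tau$,
  $G$ or cycles-to-recovery are emitted, because none are established.
- The recovery count is quantized to whole cycles and depends on $\theta$ and
  $m$; both are echoed in every result.
- `align_series()` pairs by nearest timestamp and does not model the variable
  physiological latency between systemic pressure and cerebral impedance
  responses; that latency is part of what $\tau$ measures.
- Very short records (< ~6 filter time constants) leave visible boundary
  error in the baseline estimate; the implementation guards only against
  inputs shorter than the filter's minimal settling length.
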