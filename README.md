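# regcar

**Dynamic cerebral autoregulation assessment from rheoencephalography (REG).**

Cerebral autoregulation is the negative-feedback adjustment of cerebrovascular
resistance that holds cerebral blood flow near a set point despite changes in
perfusion pressure. `regcar` assesses it non-invasively from two continuously
recorded signals: pulsatile cerebral bioimpedance (REG) from a wearable
headband and continuous arterial blood pressure, both sampled at 200 Hz. It is
aimed at physiological-signal researchers studying orthostatic challenges such
as the sit-to-stand maneuver.

The package provides two complementary analysis levels:

**Temporal level — the recovery curve.** A standardized REG waveform is built
from a pre-maneuver baseline window (cycle detection, cubic-spline time
normalization to the mean cycle duration *T*, ensemble averaging). Each
subsequent cardiac cycle is correlated against this template; the per-cycle
Pearson correlation *r* forms the recovery curve, with *r* = 1 indicating full
return to the pre-maneuver equilibrium morphology. The number of cycles between
the maneuver onset and the first sustained run of *r* ≥ θ (default θ = 0.98
over m = 3 cycles) is the cycles-to-recovery count.

**Systems level — a first-order LTI model.** With flow Q(t) = P(t)/R(t) and
resistance driven by negative feedback dR/dt = k(P/R − Q₀), linearization about
the operating point yields

```
τ · dΔQ/dt + ΔQ = G · dΔP/dt,    τ = R₀/(k·Q₀),    G = 1/(k·Q₀)
```

where ΔQ is the detrended REG (Ω) and ΔP the pressure perturbation (mmHg). The
time constant τ (s) is the speed of the regulatory response — smaller is
faster — and the gain G (Ω/mmHg) its sensitivity to the rate of pressure
change — near zero means intact regulation. `fit_lti()` identifies (τ, G) from
a recording via ARX(1,1) least squares on the backward-Euler form with
output-error refinement, and evaluates the fit by *free-run* prediction (the
model driven by pressure alone), reporting RMSE and R².

Because no public recordings exist for this measurement setup, the package
includes a seeded generator of coupled pressure/REG recordings with known
ground truth (τ, G, maneuver timing, injected recovery duration); every
generated dataset carries the truth it was built from, which is how the whole
stack is validated.

## Worked example

```r
library(regcar)

params <- synth_params(seed = 1)          # 300 s at 200 Hz, sit-to-stand at 150 s
rec    <- gen_recording(params)           # coupled pressure + impedance, truth attached

sig      <- detrend_reg(rec$reg[c("time_s", "z")])          # remove baseline drift
cycles   <- detect_cycles(sig)                              # validated cardiac cycles
template <- standardize_waveform(sig, baseline_s = 60)      # standardized REG waveform
template
#> <reg_template> 160 points, averaged over 74 cycles, mean period 0.801 s

fit <- fit_lti(rec$bp$p, sig$q, fs = 200)                   # identify (tau, G)
fit
#> <lti_fit> first-order autoregulation model
#>   tau  = 0.06977 s
#>   gain = 0.001002 ohm/mmHg
#>   free-run rmse = 0.009129 ohm, R2 = 0.9951  (oe, n = 60000, warm-up 2 s)

curve    <- recovery_curve(sig, cycles, template)           # per-cycle correlation
recovery <- detect_recovery(curve, onset_time = params$stand_time)
grade_assessment(recovery, fit, config = list(seed = 1))
#> <assessment_report>
#>   temporal level:
#>     cycles to recovery: 0 (0.62 s)
#>   systems level:
#>     tau = 0.06977 s, gain = 0.001002 ohm/mmHg (free-run rmse 0.009129, R2 0.9951)
#>   descriptive report; no normative thresholds defined
```

The recording was generated with τ = 0.0696 s and G = 0.001 Ω/mmHg — the fit
recovers both to three digits. Zero cycles-to-recovery is correct here: the
coupled recording perturbs pressure, not REG morphology. A scenario with a
morphological disturbance spanning, say, 9 cycles
(`gen_recovery_scenario(synth_params(perturb_cycles = 9))`) yields a detected
count of exactly 9.

`autoplot()` methods display templates, recovery curves and fits; `tidy()` and
`glance()` return tibble summaries. A command-line front end lives at
`inst/cli/regcar` (`decode`, `simulate`, `analyze`), and `run_pipeline()` runs
the whole chain from a YAML config, writing CSV intermediates and a JSON
report.

## Package layout

| Area | Functions |
| --- | --- |
| Capture decoding & I/O | `parse_packet`, `encode_packet`, `read_capture`, `read_signal_csv`, `write_signal_csv`, `align_series` |
| Preprocessing | `extract_baseline`, `detrend_reg`, `detect_cycles`, `normalize_cycles`, `build_template`, `standardize_waveform` |
| Features | `cycle_auc`, `auc_series`, `beat_metrics`, `resample_beats` |
| Recovery curve | `recovery_curve`, `detect_recovery` |
| LTI model | `simulate_linear`, `simulate_nonlinear`, `physio_constants`, `physio_params`, `fit_lti`, `goodness` |
| Synthetic data | `synth_params`, `gen_abp`, `gen_reg_from_abp`, `gen_recording`, `gen_recovery_scenario`, `gen_cohort`, `cohort_profiles` |
| Statistics & report | `normality_test`, `compare_groups`, `grade_assessment` |
| Pipeline | `run_pipeline`, `inst/cli/regcar` |

See the methods vignette (`vignettes/autoregulation-methods.Rmd`) for the
model derivation, estimator choice, generator design and known limitations.
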