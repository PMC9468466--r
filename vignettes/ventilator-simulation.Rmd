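---
title: "Modelling a turbine-based emergency ventilator in closed loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a turbine-based emergency ventilator in closed loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventsim)
```

`ventsim` is a behavioural simulator for a low-cost, turbine-driven emergency
ventilator of the kind built from a centrifugal blower, a servo-actuated
pressure release mechanism (PRM), a one-way valve and a passive
pilot-operated PEEP valve, controlled by microcontroller firmware and
exercised against a mechanical test lung. The package reproduces the
device's computational core — its pneumatic pressure balance, sensor
calibration and filtration, feed-forward plus proportional control, and the
PRVC / PCV / SIMV mode logic with alarms — as a closed-loop simulation, so
that the firmware's algorithms can be studied, re-tuned and regression-tested
without hardware.

## The synthetic test lung

The patient side is the standard linear one-compartment equation of motion.
With volume above FRC $V$ (ml), compliance $C$ (ml/cmH2O), resistance $R$
(cmH2O per L/s), baseline pressure $P_0$ and muscle pressure $P_{mus}(t) \le 0$:

$$P_{aw}(t) = R\,Q(t) + \frac{V(t)}{C} + P_0 + P_{mus}(t).$$

Defaults are typical adult values, $C = 50$ ml/cmH2O and $R = 5$
cmH2O/(L/s), giving a mechanical time constant $\tau = RC = 0.25$ s. The
real device was validated against a commercial mechanical test lung whose
mechanics are not published; the linear one-compartment model is the
standard stand-in and is labelled synthetic throughout.

Integration is explicit fixed-step Euler at `dt = 1` ms, deliberately
mirroring a firmware control loop rather than using an adaptive ODE solver.
`step_lung()` refuses steps larger than $0.1\,\tau$ (the explicit scheme's
comfortable stability region), and the test suite checks the integrator
against the analytic first-order step response and for convergence under
`dt` halving.

Spontaneous breathing is emulated with half-sine inspiratory-effort pulses
(`effort_half_sine()`). The default amplitude is $-10$ cmH2O with 0.6 s
duration: a vigorous effort, comparable to manually pulling a test lung,
and strong enough to open the one-way valve against the expiratory-phase
circuit pressures so a flow trigger is physically possible. Scenarios
(`make_scenario()`) add leak events — a disconnection is modelled as a leak
path of 2000 ml/s per cmH2O, i.e. an essentially open port — and optional
step changes in compliance used by the adaptation tests.

## The pneumatic circuit

Four component models are wired into one synchronous update
(`step_circuit()`):

* **Turbine.** Only the operating extremes are specified by the hardware
  (70 cmH2O stall pressure, 240 L/min free flow at full command), so fan
  affinity laws interpolate: stall pressure scales with the square of the
  0–255 speed command, free flow linearly. The operating point droops
  linearly between stall and free flow; the delivered-flow term uses the
  previous step's lung flow (a one-step lag at 1 ms), which avoids a second
  fixed-point solve per step and is negligible at breath timescales.
* **PRM.** The inlet pressure obeys the additive balance
  $P_1 = P_2 + P_3 + P_4$ (patient branch, vented branch, PEEP-pilot
  branch). The vented share is $g_v/(g_v + g_f)$ with the vent conductance
  $g_v$ proportional to the servo open fraction; the remainder is split
  between patient and pilot branches by fixed fractions (default 0.85:0.15,
  patient branch much the larger). The balance is enforced exactly in
  floating point by computing $P_4$ as the complement, and every simulation
  records all four node pressures so the invariant is checkable at every
  sample.
* **One-way valve.** An orifice law with a 5 cmH2O cracking threshold
  (configurable): zero flow at or below cracking, linear above, never
  negative. Whether the quoted 5 cmH2O is a cracking pressure or a tested
  operating pressure is ambiguous in the source material; it is read here
  as the operating threshold.
* **PEEP valve.** A pilot-operated diaphragm: sealed while the patient-side
  pressure does not exceed the effective pilot pressure, linearly conducting
  above it. Because the pilot branch carries only 15% of the PRM remainder
  while the valve must stay sealed against the full inspiratory pressure,
  the diaphragm is given a mechanical-advantage factor (`pilot_gain`,
  default 6): the pilot acts over a larger area than the patient port, as in
  real mushroom-diaphragm PEEP valves. During exhalation the airway floors
  at the effective pilot pressure, which is how the PEEP level is set by
  turbine speed alone.

The airway node couples these: inflow through the one-way valve must equal
lung flow plus PEEP-valve flow plus any leak. That balance is piecewise
linear and monotone in the airway pressure, so `step_circuit()` solves it
exactly by checking the four valve on/off combinations. A hard cap relieves
the solved airway pressure at `p_max` (default 60 cmH2O), so the safety
limit holds mechanically in every mode.

## Sensing

The pressure chain models an MPX2010DP bridge sensor, amplifier and 10-bit
ADC: counts are the true pressure through the inverse calibration plus
Gaussian analog noise (default SD 1 count), rounded and clipped. The
calibration is linear, `pressure = (analog - offset) * C`. Two conversion
constants are packaged (`mpx2010_constants`): the default 0.208879, the
ordinary-least-squares slope (with intercept — through-origin does not
reproduce the published constant) of the packaged 21-point water-column
table, and 0.20916 from the original mean-of-increments syringe experiment.
The flow sensor (an SFM3300-class thermal flow meter) needs no calibration
and is modelled as identity plus noise (default SD 2 ml/s), clipped at
±250 slm.

The firmware's **outlier-band filtration** (`band_filter()`) computes, over
a window of $n$ samples, the mean, the population standard deviation
(divide by $n$, matching the firmware arithmetic), the shrunk envelope
`stdShrink = stdDev * (1 - shrinkPercent)`, and the mean of the samples
inside `mean ± stdShrink` (boundaries inclusive; the source does not say,
and keeping boundary samples is the conservative choice). If the band is
empty the unfiltered mean is returned — fail-safe over fail-silent.
Defaults are `n = 50`, `shrink_percent = 0.5`, both configurable. One
property worth knowing: a lone spike in a *large* window barely moves the
raw mean, so there is little for the filter to correct; the
spike-robustness property tests therefore use 10-sample windows, where a
single 10-sigma spike is a 10% contamination the raw mean cannot ignore.

## Control

The motor-speed law is the firmware's proportional update,
`motorSpeed <- motorSpeed + error * Kp`, clamped to `[min_speed, 255]`;
`min_speed` defaults to 10 counts so the turbine never restarts from
standstill between phases. A general PID (`pid_update()`, trapezoidal
integral, backward-difference derivative, anti-windup clamp) is provided
and tested against a brute-force oracle; the mode loops themselves use only
proportional terms, as the device firmware does.

Feed-forward start tables (`default_ff_table()`) are packaged defaults
fitted once on the default lung and circuit by inverting the steady-state
component laws (the hardware's tables were hard-coded and never published):

* volume mode: $p_2 = V_T/C + p_{crack} + PEEP$, then speed from the fan law;
* pressure mode: $p_2 = PIP + p_{crack}$;
* PEEP: invert the pilot chain $PEEP \approx g_{pilot}(1-\alpha)(1-\sigma_v)\,p_1$.

Update cadence was an open design choice; the package adopts:

* **PRVC**: per-breath constant speed, adjusted once per cycle by
  `kp_volume` (0.05 counts/ml) times the tidal-volume error — the loop gain
  on the default lung is about 0.6, giving monotone geometric convergence;
* **PCV inspiration**: per-sample proportional action around a base speed,
  plus a once-per-breath recalibration of that base by `kp_pip` times the
  band-filtered PIP error. A purely integrating per-sample controller is
  unsuitable here: within a breath the airway pressure cannot fall (the
  one-way valve blocks deflation while the PEEP valve is pilot-sealed), so
  integrator wind-up during the pressure rise converts directly into
  irreversible overshoot;
* **expiration (both modes)**: feed-forward speed with a once-per-breath
  trim by `kp_peep` times the PEEP-estimate error. Per-sample pressure
  feedback is ill-posed early in expiration, when the airway is still high
  simply because the lung has not emptied yet.

## Mode logic, triggering, alarms

Breath timing: cycle time $= 60/\mathrm{BPM}$, split into `ti` and `te`.
The SIMV bookkeeping computes `non_sync_time = bct * (1 - w)` and
`sync_time = non_sync_time - ti` for window fraction `w` (default 0.1; the
hardware's SIMV demonstration used 0.4 so a manual pull could land inside
the window). The patient-trigger window is the final `w` fraction of the
cycle — equivalently, expiratory time beyond `sync_time` — and a trigger
requires sensed inspiratory flow at or above the setpoint (default
20 ml/s). The two source phrasings of the comparator ("greater than" vs
"more or equal") conflict; `>=` is adopted. A patient trigger delivers the
next breath early and advances the schedule by one breath.

PIP is estimated at end-inspiration by band-filtering the last 50
inspiratory pressure samples (never the raw maximum); the PEEP estimate
mirrors this over the last expiratory samples. Disconnection is flagged
when the end-inspiratory PIP estimate is strictly below 5 cmH2O — with an
open circuit pressure cannot build while flow rises. On detection the
motor drops to minimum speed for the remainder of the breath (the safety
response), but the next inspiration is attempted at the feed-forward speed:
without that, pressure could never recover and a reconnection would be
undetectable. Alarms (tidal volume, PIP, PEEP out of bounds; disconnection;
flow-sensor failure on non-finite readings) are evaluated once per breath.

## Energetics

Energy bookkeeping is deliberately simple: trapezoidal integration of
sampled power to Wh, average power as energy over duration, battery energy
as capacity times voltage (a 3S2P pack of 3400 mAh cells at 12.6 V carries
85.68 Wh), runtime as pack energy over average draw, and the
"times more efficient" comparison as `reference/new - 1` — the only
convention consistent with the published bench energies for the solenoid
and servo release mechanisms. The simulated electrical load
(`simulate_power()`) is an idle draw plus a cubic-in-speed turbine term
scaled to draw on the order of 15 W at the long-battery-life operating
point; it supports qualitative run summaries, while the headline
power/runtime chain is computed from the bench figures themselves.

## Telemetry frames

The firmware and GUI exchange settings as a single fixed-width string (27
characters, a leading type character, zero-padded decimal fields). The
field order and widths were never published; the layout documented in
`?encode_frame` is this package's frozen convention, shaped to the known
example string, and no claim is made that it reproduces the original
semantics. The codec is total on its grammar, rejects everything else with
an error naming the offending field, and never partially applies settings.

## Problem sizes, determinism, limitations

The standard study runs are: 20 PRVC breaths (100 s of simulated time at
1 kHz), a 25-breath PRVC run with compliance halved at 60 s, a 12-breath
(60 s) PCV run, an 8-breath SIMV run with one effort inside and one outside
the widened window, and a 10-breath disconnection/reconnection run. All
randomness (sensor noise, scenario jitter) flows from a single seed per
run; identical configuration and seed reproduce output files byte for byte.

What passing tests do and do not show: the synthetic lung is linear and
single-compartment, with no critical-opening-pressure nonlinearity, no
gas-exchange physiology and no multi-compartment heterogeneity, so
closed-loop convergence here demonstrates the control logic, not clinical
performance. The pneumatic free parameters that the hardware description
leaves unquantified — the PRM vent conductance, the patient:pilot split and
the pilot mechanical advantage — are fixed at plausible values consistent
with the device's qualitative behaviour (PEEP valve sealed throughout
inspiration, PEEP set by turbine speed during expiration); absolute
pressures in intermediate nodes should not be over-interpreted. Oxygen
blending, BiPAP-specific logic, acoustic noise, battery discharge curves
and the Android GUI are out of scope.

## A worked example

```{r example, eval = FALSE}
library(ventsim)

settings <- vent_settings("PRVC", tidal_volume = 350, bpm = 12, ti = 2,
                          peep = 5)
run <- run_prvc(settings, n_breaths = 20, seed = 1)
print(run)
summary(run)[c("tidal_volume_ml", "min_pressure_cmH2O",
               "max_balance_residual")]

# export waveforms for plotting or external analysis
write_waveforms(run, tempdir())
```
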