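# ventsim

Closed-loop simulation of a low-cost, turbine-based emergency ventilator in
R — for engineers and researchers who want to study, re-tune or
regression-test the firmware algorithms of blower-driven ventilators
without hardware.

Portable emergency ventilators of this class combine a centrifugal turbine,
a servo-actuated pressure release mechanism (PRM), a one-way valve and a
passive pilot-operated PEEP valve, run by microcontroller firmware that
offers the clinically common modes: PRVC (pressure-regulated volume
control), PCV (pressure control ventilation) and SIMV (synchronized
intermittent mandatory ventilation). `ventsim` reimplements that
computational core against a synthetic single-compartment test lung:

* **Patient model** — the equation of motion
  `P_aw = R·Q + V/C + P0 + Pmus(t)` with typical adult defaults
  (C = 50 ml/cmH2O, R = 5 cmH2O/(L/s)), integrated with a fixed-step 1 ms
  Euler loop that mirrors the firmware cadence; spontaneous-effort,
  disconnection and compliance-change scenarios.
* **Pneumatics** — turbine fan laws between the rated extremes (70 cmH2O,
  240 L/min), the PRM pressure balance `P1 = P2 + P3 + P4` enforced exactly
  at every step, a 5 cmH2O-cracking one-way valve, and a pilot-operated
  PEEP valve whose pilot line sets the PEEP level through turbine speed
  alone.
* **Sensing** — MPX2010DP-style calibration `pressure = (analog − offset)·C`
  with the packaged 21-point water-column table (fitted slope
  C = 0.208879 cmH2O/count), an SFM3300-style flow sensor, and the
  firmware's outlier-band filtration: population SD over a window, a shrunk
  band `mean ± stdDev·(1 − shrinkPercent)`, and the mean of the in-band
  samples.
* **Control** — `motorSpeed ← motorSpeed + error·Kp` with clamping, a
  general anti-windup PID, and feed-forward start tables inverted from the
  component laws.
* **Modes** — breath timing (`bct = 60/BPM`), the SIMV trigger window
  (`nonSyncTime = bct·(1 − w)`, `syncTime = nonSyncTime − Ti`, flow trigger
  `≥` setpoint, expiratory window only), per-breath PIP/PEEP estimation via
  the band filter, patient-circuit disconnection detection (end-inspiratory
  PIP < 5 cmH2O) with alarm and recovery, and TV/PIP/PEEP alarm bounds.
* **Energetics** — trapezoidal Wh integration, average power, battery pack
  energy (3S2P × 3400 mAh at 12.6 V = 85.68 Wh), runtime, and the
  `reference/new − 1` "times more efficient" comparison.
* **Telemetry** — the fixed-width 27-character settings frame codec used on
  the firmware↔GUI link.

## Worked example

```r
library(ventsim)

settings <- vent_settings("PRVC", tidal_volume = 350, bpm = 12, ti = 2,
                          peep = 5)
run <- run_prvc(settings, n_breaths = 20, seed = 1)
print(run)
#> <vent_run> PRVC, 20 breaths, 100.0 s simulated
#>   last breaths: VT 350 ml, PIP 12.3 cmH2O, min P 5.0 cmH2O
```

Over the last five breaths the controller delivers 350.1 ml against the
350 ml target (the volume error feedback settles within ~6 breaths from a
first-breath overshoot), holds the expiratory floor at 5.01 cmH2O against
the 5 cmH2O PEEP setting, and needs only ~12.3 cmH2O of peak pressure —
PRVC's point is exactly this: the target volume at the lowest pressure the
lung requires. `summary(run)` exposes the same figures plus the worst
PRM pressure-balance residual (`3.6e-15` cmH2O here, i.e. the
`P1 = P2 + P3 + P4` identity holds to machine precision at all 100 000
samples) and the modelled energy use; `write_waveforms(run, dir)` exports
per-sample and per-breath CSVs.

Sensor-side, the packaged calibration table reproduces the published
conversion constant:

```r
tab <- read_calibration_table(system.file("extdata",
  "mpx2010_calibration.csv", package = "ventsim"))
fit_calibration(tab)$c_constant
#> [1] 0.2088791
```

## Documentation

The methods vignette (`vignettes/ventilator-simulation.Rmd`) describes the
models, their assumptions, the tunable parameters with units and defaults,
the numerical choices, and what the synthetic lung does and does not show
about real patients.
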