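#' Single-compartment test-lung parameters
#'
#' Parameters of the linear one-compartment equation of motion used as the
#' synthetic test lung: applied airway pressure is partitioned into a resistive
#' drop, an elastic recoil and a baseline, `P_aw = R*Q + V/C + P0 + Pmus(t)`.
#' Defaults are typical adult values.
#'
#' @param compliance Respiratory-system compliance in ml per cmH2O (> 0).
#' @param resistance Airway resistance in cmH2O per (L/s) (>= 0).
#' @param baseline_pressure Baseline (atmospheric-referenced) pressure in
#'   cmH2O; the lung is at rest at this applied pressure with zero volume
#'   above FRC.
#' @param effort_profile Optional muscle-pressure waveform `Pmus(t)`: a
#'   function of time in seconds returning cmH2O. Inspiratory effort lowers
#'   alveolar pressure, so effort values must be <= 0.
#' @return An object of class `lung_params`.
#' @seealso [step_lung()], [effort_half_sine()]
#' @export
lung_params <- function(compliance = 50, resistance = 5,
                        baseline_pressure = 0, effort_profile = NULL) {
  if (!is.numeric(compliance) || length(compliance) != 1L ||
      !is.finite(compliance) || compliance <= 0)
    stop("`compliance` must be a single finite value > 0 (ml/cmH2O)")
  if (!is.numeric(resistance) || length(resistance) != 1L ||
      !is.finite(resistance) || resistance < 0)
    stop("`resistance` must be a single finite value >= 0 (cmH2O/(L/s))")
  if (!is.finite(baseline_pressure))
    stop("`baseline_pressure` must be finite")
  if (!is.null(effort_profile) && !is.function(effort_profile))
    stop("`effort_profile` must be NULL or a function of time (s)")
  structure(
    list(compliance = compliance, resistance = resistance,
         baseline_pressure = baseline_pressure,
         effort_profile = effort_profile),
    class = "lung_params"
  )
}

#' @export
print.lung_params <- function(x, ...) {
  cat(sprintf(
    "<lung_params> C = %g ml/cmH2O, R = %g cmH2O/(L/s), baseline = %g cmH2O, %s\n",
    x$compliance, x$resistance, x$baseline_pressure,
    if (is.null(x$effort_profile)) "passive" else "with effort profile"))
  invisible(x)
}

#' Test-lung state at one instant
#'
#' @param time Simulation time in s.
#' @param volume_above_frc Lung volume above functional residual capacity, ml
#'   (>= 0).
#' @param flow Flow into the lung, ml/s (positive = inflation).
#' @param alveolar_pressure Alveolar pressure, cmH2O.
#' @param airway_pressure Pressure at the airway opening, cmH2O.
#' @return An object of class `lung_state`.
#' @export
lung_state <- function(time = 0, volume_above_frc = 0, flow = 0,
                       alveolar_pressure = 0, airway_pressure = 0) {
  vals <- c(time, volume_above_frc, flow, alveolar_pressure, airway_pressure)
  if (!all(is.finite(vals))) stop("lung state fields must all be finite")
  if (volume_above_frc < 0) stop("`volume_above_frc` must be >= 0")
  structure(
    list(time = time, volume_above_frc = volume_above_frc, flow = flow,
         alveolar_pressure = alveolar_pressure,
         airway_pressure = airway_pressure),
    class = "lung_state"
  )
}

#' Advance the test lung one time step
#'
#' Explicit fixed-step Euler update of the single-compartment equation of
#' motion under a constant applied airway pressure over the step:
#' `Q = (P_applied - P0 - Pmus(t) - V/C) / R`, `V <- max(0, V + Q*dt)`.
#' With `resistance = 0` the lung equilibrates instantaneously,
#' `V = C * (P_applied - P0 - Pmus)`.
#'
#' @param state A [lung_state()].
#' @param params A [lung_params()].
#' @param applied_pressure Pressure applied at the airway opening, cmH2O.
#' @param dt Time step in s; must satisfy `dt <= 0.1 * tau` where
#'   `tau = R*C` is the mechanical time constant (stability contract of the
#'   explicit integrator) when `resistance > 0`.
#' @return The advanced [lung_state()].
#' @examples
#' st <- lung_state()
#' step_lung(st, lung_params(), applied_pressure = 10, dt = 0.001)
#' @export
step_lung <- function(state, params, applied_pressure, dt) {
  stopifnot(inherits(state, "lung_state"), inherits(params, "lung_params"))
  if (!is.finite(applied_pressure) || !is.finite(dt))
    stop("invalid lung state: non-finite input")
  if (dt <= 0) stop("`dt` must be > 0")
  # resistance is per L/s; internal flows are ml/s
  r_ml <- params$resistance / 1000
  tau <- r_ml * params$compliance
  if (params$resistance > 0 && dt > 0.1 * tau + 1e-12)
    stop(sprintf("`dt` = %g s violates the stability contract dt <= 0.1*R*C = %g s",
                 dt, 0.1 * tau))
  pmus <- if (is.null(params$effort_profile)) 0 else params$effort_profile(state$time)
  drive <- applied_pressure - params$baseline_pressure - pmus -
    state$volume_above_frc / params$compliance
  if (r_ml > 0) {
    q <- drive / r_ml
    v <- state$volume_above_frc + q * dt
  } else {
    v <- params$compliance *
      (applied_pressure - params$baseline_pressure - pmus)
    q <- (v - state$volume_above_frc) / dt
  }
  if (v < 0) {
    q <- -state$volume_above_frc / dt
    v <- 0
  }
  lung_state(
    time = state$time + dt,
    volume_above_frc = v,
    flow = q,
    alveolar_pressure = v / params$compliance + params$baseline_pressure + pmus,
    airway_pressure = applied_pressure
  )
}

#' Half-sine inspiratory-effort waveform
#'
#' Builds a muscle-pressure function `Pmus(t)` made of half-sine negative
#' pulses centred on the requested onset times, emulating a patient (or a
#' manual pull on a test lung) initiating a breath.
#'
#' @param onset_times Numeric vector of effort onset times, s.
#' @param amplitude Peak effort in cmH2O; must be <= 0 (inspiratory effort
#'   lowers alveolar pressure). Default -10, a vigorous effort comparable to a
#'   manual pull on a test lung.
#' @param duration Pulse duration in s.
#' @return A function of time returning Pmus in cmH2O (vectorised over time).
#' @export
effort_half_sine <- function(onset_times, amplitude = -10, duration = 0.6) {
  if (amplitude > 0) stop("effort `amplitude` must be <= 0 cmH2O")
  if (duration <= 0) stop("`duration` must be > 0")
  onset_times <- sort(onset_times)
  force(amplitude); force(duration)
  function(t) {
    out <- numeric(length(t))
    for (t0 in onset_times) {
      inpulse <- t >= t0 & t < t0 + duration
      if (any(inpulse))
        out[inpulse] <- out[inpulse] +
          amplitude * sin(pi * (t[inpulse] - t0) / duration)
    }
    out
  }
}

#' Build a simulation scenario
#'
#' Scenarios define the external events every mode run is exercised against:
#' `"normal"` (passive lung, no events), `"spontaneous"` (half-sine
#' inspiratory efforts at `event_times`), `"disconnect"` (a leak path opens at
#' `event_times[1]`, emulating the patient circuit coming off) and
#' `"reconnect"` (leak opens at `event_times[1]` and closes again at
#' `event_times[2]`).
#'
#' @param kind One of `"normal"`, `"spontaneous"`, `"disconnect"`,
#'   `"reconnect"`.
#' @param event_times Strictly increasing event times, s. Effort onsets for
#'   `"spontaneous"`; leak open (and close) times otherwise.
#' @param leak_conductance Leak-path conductance when open, ml/s per cmH2O
#'   (>= 0). Default 2000: a detached circuit is essentially an open port, so
#'   airway pressure collapses however hard the turbine drives.
#' @param effort_amplitude,effort_duration Passed to [effort_half_sine()] for
#'   spontaneous scenarios.
#' @param effort_jitter_sd Standard deviation (s) of seeded Gaussian jitter
#'   added to effort onset times; 0 keeps them exact.
#' @param compliance_events Optional `data.frame(time, factor)`: at each
#'   `time`, lung compliance is multiplied by `factor` (models an abrupt
#'   mechanics change, e.g. compliance halving).
#' @param seed Integer seed for scenario randomness (effort jitter).
#' @return An object of class `vent_scenario` with elements `kind`,
#'   `event_times`, `leak_conductance`, `leak_at(t)` (conductance as a
#'   function of time), `effort` (Pmus function or `NULL`) and
#'   `compliance_events`.
#' @examples
#' make_scenario("disconnect", event_times = 30)
#' @export
make_scenario <- function(kind = c("normal", "spontaneous", "disconnect",
                                   "reconnect"),
                          event_times = numeric(0),
                          leak_conductance = 2000,
                          effort_amplitude = -10, effort_duration = 0.6,
                          effort_jitter_sd = 0,
                          compliance_events = NULL,
                          seed = 42) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown scenario kind"))
  if (length(event_times) > 1 && any(diff(event_times) <= 0))
    stop("`event_times` must be strictly increasing")
  if (leak_conductance < 0) stop("`leak_conductance` must be >= 0")
  effort <- NULL
  leak_on <- Inf; leak_off <- Inf
  if (kind == "spontaneous") {
    if (length(event_times) == 0)
      stop("spontaneous scenarios need at least one effort time")
    onsets <- event_times
    if (effort_jitter_sd > 0)
      onsets <- sort(onsets + with_seed(seed, stats::rnorm(
        length(onsets), 0, effort_jitter_sd)))
    effort <- effort_half_sine(onsets, effort_amplitude, effort_duration)
  } else if (kind == "disconnect") {
    if (length(event_times) < 1)
      stop("disconnect scenarios need an event time")
    leak_on <- event_times[1]
  } else if (kind == "reconnect") {
    if (length(event_times) < 2)
      stop("reconnect scenarios need leak open and close times")
    leak_on <- event_times[1]; leak_off <- event_times[2]
  }
  if (!is.null(compliance_events)) {
    stopifnot(is.data.frame(compliance_events),
              all(c("time", "factor") %in% names(compliance_events)))
  } else {
    compliance_events <- data.frame(time = numeric(0), factor = numeric(0))
  }
  g <- leak_conductance
  structure(
    list(kind = kind, event_times = event_times,
         leak_conductance = if (kind %in% c("disconnect", "reconnect")) g else 0,
         leak_at = function(t) ifelse(t >= leak_on & t < leak_off, g, 0),
         effort = effort,
         compliance_events = compliance_events,
         seed = seed),
    class = "vent_scenario"
  )
}

#' @export
print.vent_scenario <- function(x, ...) {
  cat(sprintf("<vent_scenario> kind = %s", x$kind))
  if (length(x$event_times))
    cat(", events at", paste(x$event_times, collapse = ", "), "s")
  cat("\n")
  invisible(x)
}

# Evaluate an expression with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
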