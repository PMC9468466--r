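#' Motor-speed controller state
#'
#' Holds the 0-255 motor speed command, the PID gains and the integrator /
#' derivative memory. The minimum speed is kept above zero so the turbine
#' never has to restart from standstill between phases.
#'
#' @param kp,ki,kd Proportional, integral and derivative gains.
#' @param motor_speed Current speed command, counts.
#' @param min_speed Lower clamp of the speed command, counts (default 10).
#' @param integral_limit Anti-windup clamp on the absolute value of the
#'   integral accumulator.
#' @return An object of class `controller_state`.
#' @export
controller_state <- function(kp = 0.05, ki = 0, kd = 0, motor_speed = 0,
                             min_speed = 10, integral_limit = 1000) {
  stopifnot(is.finite(kp), is.finite(ki), is.finite(kd),
            min_speed >= 0, min_speed <= 255, integral_limit > 0)
  structure(list(kp = kp, ki = ki, kd = kd,
                 motor_speed = min(255, max(min_speed, motor_speed)),
                 min_speed = min_speed,
                 integral_limit = integral_limit,
                 integral_accum = 0, last_error = 0),
            class = "controller_state")
}

#' Proportional motor-speed update
#'
#' The firmware's speed law: `motorSpeed <- motorSpeed + error * Kp`, clamped
#' to `[min_speed, 255]`. With error = target - measured, under-delivery
#' raises the speed. Monotone in the error for fixed kp > 0.
#'
#' @param state A [controller_state()].
#' @param error Control error in target units (e.g. ml of tidal-volume
#'   shortfall).
#' @return The updated [controller_state()].
#' @examples
#' st <- controller_state(kp = 0.1, motor_speed = 100)
#' p_update(st, 50)$motor_speed # 105
#' @export
p_update <- function(state, error) {
  stopifnot(inherits(state, "controller_state"), is.finite(error))
  state$motor_speed <- min(255, max(state$min_speed,
                                    state$motor_speed + error * state$kp))
  state
}

#' Discrete PID update
#'
#' `output = kp*e + ki*integral(e) + kd*de/dt` with a trapezoidal integral,
#' backward-difference derivative, and the integral accumulator clamped at
#' `integral_limit` (anti-windup).
#'
#' @param state A [controller_state()].
#' @param error Current control error.
#' @param dt Time since the previous update, s (> 0).
#' @return A list with `state` (updated memory) and `output`.
#' @export
pid_update <- function(state, error, dt) {
  stopifnot(inherits(state, "controller_state"), is.finite(error), dt > 0)
  acc <- state$integral_accum + (error + state$last_error) / 2 * dt
  acc <- min(state$integral_limit, max(-state$integral_limit, acc))
  deriv <- (error - state$last_error) / dt
  out <- state$kp * error + state$ki * acc + state$kd * deriv
  state$integral_accum <- acc
  state$last_error <- error
  list(state = state, output = out)
}

#' Feed-forward lookup table
#'
#' Ordered (target setting -> initial motor speed) pairs. The feed-forward
#' stage starts the motor in the neighbourhood of the right speed so feedback
#' only has to trim the residual.
#'
#' @param targets Strictly increasing target values (ml, cmH2O, ...).
#' @param speeds Motor speed commands in \[0, 255\], one per target.
#' @return An object of class `feed_forward_table`.
#' @export
feed_forward_table <- function(targets, speeds) {
  if (length(targets) == 0) stop("feed-forward table must be non-empty")
  if (length(targets) != length(speeds))
    stop("`targets` and `speeds` lengths differ")
  if (length(targets) > 1 && any(diff(targets) <= 0))
    stop("`targets` must be strictly increasing")
  if (any(speeds < 0 | speeds > 255))
    stop("speeds must lie in [0, 255]")
  structure(list(targets = as.numeric(targets), speeds = as.numeric(speeds)),
            class = "feed_forward_table")
}

#' Feed-forward initial speed for a target
#'
#' Linear interpolation between the bracketing table entries; targets outside
#' the table range are clamped to the end entries.
#'
#' @param target Target value in the table's units.
#' @param table A [feed_forward_table()].
#' @return Motor speed command (counts, possibly fractional).
#' @examples
#' tab <- feed_forward_table(c(100, 200), c(80, 120))
#' feed_forward_lookup(150, tab) # 100
#' @export
feed_forward_lookup <- function(target, table) {
  if (!inherits(table, "feed_forward_table"))
    stop("`table` must be a feed_forward_table")
  if (length(table$targets) == 1) return(table$speeds)
  stats::approx(table$targets, table$speeds, xout = target, rule = 2)$y
}

# --- packaged default feed-forward tables -----------------------------------
#
# Fitted once on the default lung and default pneumatic circuit by inverting
# the steady-state maps of the component laws:
#   inhale pressure:  p2 = patient_split * p1,  p1 = stall(s) * droop
#   delivered volume: V  ~ C * (p2 - cracking - PEEP)
#   exhale pilot:     PEEP ~ pilot_gain * (1-patient_split) * (1-vent_share) * p1
# `droop_margin` absorbs the flow-dependent sag of the turbine curve at
# typical inspiratory flows.

speed_for_stall <- function(p_stall, turbine = turbine_params(),
                            droop_margin = 0.85) {
  s <- 255 * sqrt(pmin(1, pmax(0, p_stall / droop_margin / turbine$max_pressure)))
  pmin(255, pmax(0, s))
}

#' Default feed-forward tables for the ventilation modes
#'
#' Packaged starting-speed tables derived from the default lung
#' ([lung_params()]) and circuit ([circuit_params()]) component laws:
#' `"volume"` maps a tidal-volume target (ml) to an inspiratory speed,
#' `"pressure"` maps a PIP target (cmH2O) to an inspiratory speed, and
#' `"peep"` maps a PEEP setting (cmH2O) to an expiratory speed.
#'
#' @param which One of `"volume"`, `"pressure"`, `"peep"`.
#' @param circuit A [circuit_params()].
#' @param lung A [lung_params()].
#' @param peep_assumed PEEP (cmH2O) assumed when building the volume table.
#' @return A [feed_forward_table()].
#' @export
default_ff_table <- function(which = c("volume", "pressure", "peep"),
                             circuit = circuit_params(),
                             lung = lung_params(), peep_assumed = 5) {
  which <- match.arg(which)
  prm <- circuit$prm
  crack <- circuit$one_way_cracking
  if (which == "volume") {
    targets <- seq(100, 1000, by = 100)
    p2 <- targets / lung$compliance + crack + peep_assumed
    sp <- speed_for_stall(p2 / prm$patient_split, circuit$turbine)
  } else if (which == "pressure") {
    targets <- seq(5, 60, by = 5)
    p2 <- targets + crack
    sp <- speed_for_stall(p2 / prm$patient_split, circuit$turbine)
  } else {
    targets <- seq(0, 15, by = 1)
    share3 <- prm$vent_conductance_open /
      (prm$vent_conductance_open + prm$fixed_conductance)
    p1 <- targets / (prm$pilot_gain * (1 - prm$patient_split) * (1 - share3))
    sp <- speed_for_stall(p1, circuit$turbine, droop_margin = 1)
  }
  feed_forward_table(targets, sp)
}
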