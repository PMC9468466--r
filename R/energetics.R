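#' Integrate sampled electrical power to energy
#'
#' Trapezoidal integration of evenly sampled power, converted to watt-hours.
#'
#' @param power_samples Non-negative power samples, W.
#' @param dt Sample spacing, s.
#' @return Energy in Wh.
#' @examples
#' integrate_energy(rep(15.264, 601), dt = 1) # 10 min at 15.264 W -> 2.544 Wh
#' @export
integrate_energy <- function(power_samples, dt) {
  if (any(!is.finite(power_samples)) || any(power_samples < 0))
    stop("power samples must be finite and >= 0")
  if (dt <= 0) stop("`dt` must be > 0")
  n <- length(power_samples)
  if (n < 2) return(0)
  sum((power_samples[-1] + power_samples[-n]) / 2) * dt / 3600
}

#' Average power from consumed energy
#'
#' @param energy Energy consumed, Wh.
#' @param duration Duration, h (> 0).
#' @return Average power, W.
#' @examples
#' average_power(2.544, 10 / 60) # 15.264 W
#' @export
average_power <- function(energy, duration) {
  if (duration <= 0) stop("`duration` must be > 0")
  energy / duration
}

#' Battery pack description
#'
#' Series strings set the voltage, parallel strings the capacity: a 3S2P pack
#' of 3400 mAh cells at 12.6 V carries 6800 mAh and 85.68 Wh.
#'
#' @param cell_capacity_mah Per-cell capacity, mAh.
#' @param series,parallel Cell counts per string / parallel strings.
#' @param pack_voltage Pack voltage, V.
#' @return An object of class `battery_pack`.
#' @export
battery_pack <- function(cell_capacity_mah = 3400, series = 3, parallel = 2,
                         pack_voltage = 12.6) {
  stopifnot(cell_capacity_mah > 0, series >= 1, parallel >= 1,
            pack_voltage > 0)
  structure(list(cell_capacity_mah = cell_capacity_mah, series = series,
                 parallel = parallel, pack_voltage = pack_voltage),
            class = "battery_pack")
}

#' Battery pack energy
#'
#' `(cell_capacity * parallel / 1000) * pack_voltage` watt-hours.
#'
#' @param pack A [battery_pack()].
#' @return Energy in Wh.
#' @examples
#' pack_energy(battery_pack()) # 85.68 Wh
#' @export
pack_energy <- function(pack = battery_pack()) {
  stopifnot(inherits(pack, "battery_pack"))
  pack$cell_capacity_mah * pack$parallel / 1000 * pack$pack_voltage
}

#' Expected runtime on battery
#'
#' @param pack A [battery_pack()].
#' @param avg_power Average draw, W (> 0).
#' @return Runtime in hours.
#' @examples
#' runtime_hours(battery_pack(), 15.27) # ~5.6 h
#' @export
runtime_hours <- function(pack = battery_pack(), avg_power) {
  if (avg_power <= 0) stop("`avg_power` must be > 0")
  pack_energy(pack) / avg_power
}

#' Fold-improvement in energy efficiency
#'
#' The "times more efficient" convention: `reference/new - 1`, i.e. how many
#' additional multiples of the new consumption the reference system uses.
#'
#' @param reference_energy Energy of the reference system, Wh (> 0).
#' @param new_energy Energy of the improved system, Wh (> 0).
#' @return Fold improvement (0 = no improvement).
#' @examples
#' efficiency_fold(1.042, 0.050) # 19.84
#' @export
efficiency_fold <- function(reference_energy, new_energy) {
  if (reference_energy <= 0 || new_energy <= 0)
    stop("energies must be > 0")
  reference_energy / new_energy - 1
}

#' Electrical power model of the running ventilator
#'
#' Idle draw (controller, display, sensors) plus a turbine term cubic in the
#' speed fraction (fan power scales with the cube of speed), scaled so the
#' long-battery-life operating point draws on the order of 15 W.
#'
#' @param motor_speed Speed command samples, 0-255.
#' @param idle_w Idle draw, W.
#' @param turbine_w Turbine draw at full speed, W.
#' @return Power samples in W.
#' @export
simulate_power <- function(motor_speed, idle_w = 3.5, turbine_w = 35) {
  stopifnot(idle_w >= 0, turbine_w >= 0)
  idle_w + turbine_w * (pmin(255, pmax(0, motor_speed)) / 255)^3
}
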