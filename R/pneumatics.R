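#' Turbine (blower) parameters
#'
#' The centrifugal turbine is characterised by its operating extremes: stall
#' pressure at full speed and free-flow capacity at full speed (defaults
#' 70 cmH2O and 240 L/min). Fan affinity laws scale these with the 0-255
#' speed command: stall pressure with the square of speed, free flow linearly.
#'
#' @param max_pressure Stall pressure at full command, cmH2O.
#' @param max_flow Free-flow capacity at full command, ml/s.
#' @return An object of class `turbine_params`.
#' @export
turbine_params <- function(max_pressure = 70, max_flow = 240000 / 60) {
  stopifnot(max_pressure > 0, max_flow > 0)
  structure(list(max_pressure = max_pressure, max_flow = max_flow),
            class = "turbine_params")
}

#' Turbine curve at a speed command
#'
#' Returns the stall pressure and flow limit for a 0-255 speed command under
#' the fan laws: `pressure = max_pressure * (s/255)^2`,
#' `flow_limit = max_flow * (s/255)`. Out-of-range commands are clamped with a
#' warning. Both outputs are monotone non-decreasing in the command.
#'
#' @param speed_command Integer-valued command in \[0, 255\].
#' @param params A [turbine_params()].
#' @return A list with `stall_pressure` (cmH2O) and `flow_limit` (ml/s).
#' @examples
#' turbine_pressure(255) # 70 cmH2O, 4000 ml/s
#' @export
turbine_pressure <- function(speed_command, params = turbine_params()) {
  if (speed_command < 0 || speed_command > 255) {
    warning(sprintf("speed command %g outside [0, 255]; clamped", speed_command))
    speed_command <- min(255, max(0, speed_command))
  }
  s <- speed_command / 255
  list(stall_pressure = params$max_pressure * s^2,
       flow_limit = params$max_flow * s)
}

#' Pressure release mechanism (PRM) parameters
#'
#' The PRM is a servo-actuated vent valve between the turbine and the patient
#' branch. Its vent path is modelled as a conductance proportional to the
#' servo open fraction; the share of inlet pressure diverted through the vent
#' is `g_vent / (g_vent + fixed_conductance)`. The remaining pressure is split
#' between the patient branch (`patient_split`) and the PEEP-valve pilot
#' branch (`1 - patient_split`), the patient branch being much the larger.
#' The pilot line acts on the PEEP-valve diaphragm over a larger area than the
#' patient port, giving it a mechanical advantage `pilot_gain`: the effective
#' sealing pressure is `pilot_gain * p4`.
#'
#' @param vent_conductance_open Relative vent-path conductance at a fully open
#'   servo (dimensionless, relative to `fixed_conductance`).
#' @param fixed_conductance Relative conductance of the non-vented path.
#' @param patient_split Fraction of the non-vented pressure assigned to the
#'   patient branch (p2); the rest goes to the pilot branch (p4).
#' @param pilot_gain Diaphragm mechanical-advantage factor of the pilot line.
#' @return An object of class `prm_params`.
#' @export
prm_params <- function(vent_conductance_open = 4, fixed_conductance = 1,
                       patient_split = 0.85, pilot_gain = 6) {
  stopifnot(vent_conductance_open >= 0, fixed_conductance > 0,
            patient_split > 0, patient_split < 1, pilot_gain > 0)
  structure(list(vent_conductance_open = vent_conductance_open,
                 fixed_conductance = fixed_conductance,
                 patient_split = patient_split,
                 pilot_gain = pilot_gain),
            class = "prm_params")
}

#' Pneumatic node state
#'
#' Node pressures and branch flows of the circuit at one time step. The
#' pressure balance `p1 = p2 + p3 + p4` (inlet pressure divided between the
#' patient branch, the vented branch and the PEEP-pilot branch) is enforced
#' exactly at construction.
#'
#' @param p1,p2,p3,p4 Node pressures, cmH2O: turbine inlet side, patient
#'   branch, vented branch, pilot branch.
#' @param q_in Inspiratory-limb flow through the one-way valve, ml/s.
#' @param q_peep Expiratory flow through the PEEP valve, ml/s.
#' @param q_leak Flow through an open leak path, ml/s.
#' @param q_lung Net flow into the lung, ml/s.
#' @param airway_pressure Solved airway-opening pressure, cmH2O.
#' @return An object of class `pneumatic_state`.
#' @export
pneumatic_state <- function(p1, p2, p3, p4, q_in = 0, q_peep = 0,
                            q_leak = 0, q_lung = 0, airway_pressure = 0) {
  vals <- c(p1, p2, p3, p4, q_in, q_peep, q_leak, q_lung, airway_pressure)
  if (!all(is.finite(vals))) stop("pneumatic state fields must be finite")
  if (abs(p1 - (p2 + p3 + p4)) > 1e-9)
    stop("pressure balance violated: p1 != p2 + p3 + p4")
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                 q_in = q_in, q_peep = q_peep, q_leak = q_leak,
                 q_lung = q_lung, airway_pressure = airway_pressure),
            class = "pneumatic_state")
}

#' PRM pressure balance
#'
#' Splits the inlet pressure `p1` across the three branches so that
#' `p1 = p2 + p3 + p4` holds exactly. The vented share grows with the servo
#' open fraction (weakly increasing p3, weakly decreasing p2 and p4); the
#' remainder is split between patient and pilot branches by fixed fractions.
#'
#' @param p1 Inlet pressure, cmH2O (>= 0).
#' @param servo_open_fraction Servo opening in \[0, 1\]: 0 = valve closed
#'   (inhale state, p3 = 0), 1 = fully open (exhale state).
#' @param params A [prm_params()].
#' @return A [pneumatic_state()] carrying the node pressures (flows zero).
#' @examples
#' prm_balance(35, 0)  # closed: p3 = 0, p2 + p4 = 35
#' @export
prm_balance <- function(p1, servo_open_fraction, params = prm_params()) {
  if (!is.finite(p1) || !is.finite(servo_open_fraction))
    stop("invalid state: non-finite input")
  if (p1 < 0) stop("invalid state: negative inlet pressure")
  if (servo_open_fraction < 0 || servo_open_fraction > 1)
    stop("`servo_open_fraction` must be in [0, 1]")
  g3 <- servo_open_fraction * params$vent_conductance_open
  share3 <- g3 / (g3 + params$fixed_conductance)
  p3 <- p1 * share3
  rem <- p1 - p3
  p2 <- params$patient_split * rem
  p4 <- rem - p2  # exact complement: conservation holds to machine zero
  pneumatic_state(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
}

#' One-way (check) valve flow
#'
#' Orifice law with a cracking threshold: no flow at or below the cracking
#' pressure (default 5 cmH2O), linear in the excess above it, and never
#' negative (no expiratory backflow into the inspiratory limb).
#'
#' @param delta_p Pressure across the valve (upstream minus downstream), cmH2O.
#' @param cracking_pressure Threshold below which the valve stays shut, cmH2O.
#' @param conductance Flow per unit excess pressure above cracking,
#'   ml/s per cmH2O.
#' @return Flow in ml/s (>= 0).
#' @examples
#' one_way_flow(-10) # 0: no backflow
#' one_way_flow(5)   # 0: at the cracking threshold
#' @export
one_way_flow <- function(delta_p, cracking_pressure = 5, conductance = 100) {
  pmax(0, conductance * (delta_p - cracking_pressure))
}

#' Passive PEEP valve flow
#'
#' The PEEP valve is a pilot-operated diaphragm: sealed while the patient-side
#' pressure does not exceed the pilot pressure, and linearly conducting above
#' it. During inhalation the pilot holds the film shut; during exhalation the
#' patient pressure lifts it and the airway floors at the pilot pressure,
#' which sets the PEEP level.
#'
#' @param p_patient Patient-side pressure, cmH2O.
#' @param p_pilot Effective pilot (sealing) pressure, cmH2O.
#' @param conductance Flow per unit excess pressure, ml/s per cmH2O.
#' @return Flow out through the valve in ml/s (>= 0).
#' @examples
#' peep_valve_flow(10, 15) # 0: sealed during inhalation
#' peep_valve_flow(15, 10) # proportional to the 5 cmH2O excess
#' @export
peep_valve_flow <- function(p_patient, p_pilot, conductance = 100) {
  pmax(0, conductance * (p_patient - p_pilot))
}

#' Full pneumatic circuit parameters
#'
#' Bundles the component models of the circuit: turbine, PRM, one-way valve
#' and PEEP valve conductances.
#'
#' @param turbine A [turbine_params()].
#' @param prm A [prm_params()].
#' @param one_way_cracking One-way valve cracking pressure, cmH2O.
#' @param one_way_conductance One-way valve conductance, ml/s per cmH2O.
#' @param peep_conductance PEEP valve conductance when open, ml/s per cmH2O.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(turbine = turbine_params(), prm = prm_params(),
                           one_way_cracking = 5, one_way_conductance = 100,
                           peep_conductance = 100) {
  stopifnot(inherits(turbine, "turbine_params"), inherits(prm, "prm_params"),
            one_way_cracking >= 0, one_way_conductance > 0,
            peep_conductance > 0)
  structure(list(turbine = turbine, prm = prm,
                 one_way_cracking = one_way_cracking,
                 one_way_conductance = one_way_conductance,
                 peep_conductance = peep_conductance),
            class = "circuit_params")
}

# Solve the airway node pressure x from flow balance:
#   g_ow*max(0, b1 - x)  =  (x - p_alv)/r_ml + g_pv*max(0, x - pilot) + g_leak*x
# The LHS is non-increasing and the RHS strictly increasing in x, so the root
# is unique; each of the four valve on/off combinations gives a linear
# candidate checked for consistency with its breakpoints.
solve_airway_node <- function(p2, p_alv, r_ml, g_ow, crack, g_pv, pilot,
                              g_leak) {
  b1 <- p2 - crack
  inv_r <- 1 / r_ml
  for (iin in c(TRUE, FALSE)) {
    for (ipp in c(TRUE, FALSE)) {
      den <- inv_r + g_leak + (if (iin) g_ow else 0) + (if (ipp) g_pv else 0)
      num <- p_alv * inv_r + (if (iin) g_ow * b1 else 0) +
        (if (ipp) g_pv * pilot else 0)
      x <- num / den
      ok_in <- if (iin) x <= b1 + 1e-9 else x >= b1 - 1e-9
      ok_pp <- if (ipp) x >= pilot - 1e-9 else x <= pilot + 1e-9
      if (ok_in && ok_pp) return(x)
    }
  }
  # unreachable for finite inputs; fall back to the all-off candidate
  (p_alv * inv_r) / (inv_r + g_leak)
}

#' Advance the whole pneumatic circuit and lung one time step
#'
#' One synchronised update of turbine -> PRM -> one-way valve -> lung ->
#' PEEP valve, honouring the `p1 = p2 + p3 + p4` balance and an optional leak
#' path when a disconnection scenario is active. The turbine operating point
#' follows a linear droop of stall pressure with delivered flow (previous-step
#' inspiratory flow, one-step lag). The airway-opening pressure is solved from
#' the piecewise-linear flow balance at the patient wye and, if a hard cap is
#' given, relieved at `p_max`.
#'
#' @param speed_command Motor speed command, 0-255.
#' @param servo_open_fraction PRM servo opening, 0-1.
#' @param lung A [lung_state()].
#' @param lung_par A [lung_params()].
#' @param circuit A [circuit_params()].
#' @param scenario Optional [make_scenario()]; supplies the leak conductance
#'   at the current time.
#' @param dt Time step, s.
#' @param p_max Firmware/mechanical hard pressure cap, cmH2O (default `Inf`).
#' @return A list with `pneumatic` (a [pneumatic_state()]) and `lung` (the
#'   advanced [lung_state()]).
#' @export
step_circuit <- function(speed_command, servo_open_fraction, lung, lung_par,
                         circuit = circuit_params(), scenario = NULL,
                         dt = 0.001, p_max = Inf) {
  # Hot path of every simulation: the component laws of turbine_pressure(),
  # prm_balance() and step_lung() are applied inline (their agreement with
  # the standalone operations is covered by tests); objects are built without
  # re-validation since validity holds by construction.
  s <- min(255, max(0, speed_command)) / 255
  tb_p <- circuit$turbine$max_pressure * s * s
  tb_q <- circuit$turbine$max_flow * s
  q_draw <- max(0, lung$flow)
  p1 <- if (tb_q > 0) tb_p * max(0, 1 - q_draw / tb_q) else 0

  prm <- circuit$prm
  g3 <- servo_open_fraction * prm$vent_conductance_open
  p3 <- p1 * g3 / (g3 + prm$fixed_conductance)
  rem <- p1 - p3
  p2 <- prm$patient_split * rem
  p4 <- rem - p2  # exact complement: p1 = p2 + p3 + p4 to machine zero
  pilot_eff <- prm$pilot_gain * p4

  g_leak <- if (is.null(scenario)) 0 else scenario$leak_at(lung$time)
  pmus <- if (is.null(lung_par$effort_profile)) 0 else
    lung_par$effort_profile(lung$time)
  p_alv <- lung$volume_above_frc / lung_par$compliance +
    lung_par$baseline_pressure + pmus
  r_ml <- lung_par$resistance / 1000
  if (r_ml <= 0) r_ml <- 1e-6  # near-rigid coupling for the degenerate case

  x <- solve_airway_node(p2, p_alv, r_ml, circuit$one_way_conductance,
                         circuit$one_way_cracking, circuit$peep_conductance,
                         pilot_eff, g_leak)
  if (x > p_max) x <- p_max  # mechanical/firmware relief

  q_in <- max(0, circuit$one_way_conductance *
                (p2 - x - circuit$one_way_cracking))
  q_peep <- max(0, circuit$peep_conductance * (x - pilot_eff))
  q_leak <- g_leak * x

  # explicit Euler update of the lung under applied pressure x
  q_lung <- (x - p_alv) / r_ml
  v <- lung$volume_above_frc + q_lung * dt
  if (v < 0) { q_lung <- -lung$volume_above_frc / dt; v <- 0 }
  t_new <- lung$time + dt
  new_lung <- structure(
    list(time = t_new, volume_above_frc = v, flow = q_lung,
         alveolar_pressure = v / lung_par$compliance +
           lung_par$baseline_pressure + pmus,
         airway_pressure = x),
    class = "lung_state")

  pn <- structure(
    list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, q_in = q_in, q_peep = q_peep,
         q_leak = q_leak, q_lung = q_lung, airway_pressure = x),
    class = "pneumatic_state")
  list(pneumatic = pn, lung = new_lung)
}
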