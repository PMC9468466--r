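#' Ventilator settings
#'
#' User-facing mode parameters with the GUI range validation: tidal volume
#' 100-999 ml, PIP target 0-35 cmH2O, BPM 6-60, PEEP 0-12 cmH2O. The firmware
#' hard cap `p_max` sits above the GUI limits.
#'
#' @param mode `"PRVC"` (volume-targeted, pressure-regulated) or `"PCV"`
#'   (pressure-targeted).
#' @param tidal_volume Target tidal volume, ml (PRVC).
#' @param bpm Mandatory breaths per minute.
#' @param ti Inspiration time, s; must be less than the breath cycle time
#'   `60/bpm`.
#' @param peep Set PEEP, cmH2O.
#' @param pip_target Target peak inspiratory pressure, cmH2O (PCV).
#' @param p_max Firmware hard pressure cap, cmH2O (>= `pip_target`).
#' @param simv Enable SIMV patient triggering in the expiratory window.
#' @param trigger_flow SIMV flow-trigger setpoint, ml/s; a sensed inspiratory
#'   flow at or above it fires the trigger.
#' @param sync_window_fraction Fraction of the breath cycle forming the
#'   trigger window at the end of the cycle (default 0.1; the validation runs
#'   use 0.4).
#' @param alarm_bounds Named list of `c(low, high)` bounds for `tv` (ml),
#'   `pip` (cmH2O) and `min_pressure` i.e. PEEP (cmH2O). Defaults are derived
#'   from the settings.
#' @return An object of class `vent_settings`.
#' @export
vent_settings <- function(mode = c("PRVC", "PCV"), tidal_volume = 350,
                          bpm = 12, ti = 2, peep = 5, pip_target = 20,
                          p_max = 60, simv = FALSE, trigger_flow = 20,
                          sync_window_fraction = 0.1, alarm_bounds = NULL) {
  mode <- match.arg(mode)
  if (tidal_volume < 100 || tidal_volume > 999)
    stop("`tidal_volume` must lie in [100, 999] ml")
  if (bpm < 6 || bpm > 60) stop("`bpm` must lie in [6, 60]")
  if (pip_target < 0 || pip_target > 35)
    stop("`pip_target` must lie in [0, 35] cmH2O")
  if (peep < 0 || peep > 12) stop("`peep` must lie in [0, 12] cmH2O")
  if (ti <= 0 || ti >= 60 / bpm)
    stop("`ti` must be positive and less than the breath cycle time 60/bpm")
  if (p_max < pip_target) stop("`p_max` must be >= `pip_target`")
  if (trigger_flow <= 0) stop("`trigger_flow` must be > 0")
  if (sync_window_fraction <= 0 || sync_window_fraction >= 1)
    stop("`sync_window_fraction` must be in (0, 1)")
  if (is.null(alarm_bounds))
    alarm_bounds <- list(tv = c(50, 1500), pip = c(1, 45),
                         min_pressure = c(-1, 15))
  for (nm in c("tv", "pip", "min_pressure")) {
    b <- alarm_bounds[[nm]]
    if (is.null(b) || length(b) != 2 || b[1] >= b[2])
      stop(sprintf("alarm bounds for '%s' must be c(low, high) with low < high", nm))
  }
  structure(list(mode = mode, tidal_volume = tidal_volume, bpm = bpm, ti = ti,
                 peep = peep, pip_target = pip_target, p_max = p_max,
                 simv = simv, trigger_flow = trigger_flow,
                 sync_window_fraction = sync_window_fraction,
                 alarm_bounds = alarm_bounds),
            class = "vent_settings")
}

#' @export
print.vent_settings <- function(x, ...) {
  cat(sprintf("<vent_settings> %s%s: VT %g ml, BPM %g, Ti %g s, PEEP %g, PIP %g, Pmax %g cmH2O\n",
              x$mode, if (x$simv) "+SIMV" else "", x$tidal_volume, x$bpm,
              x$ti, x$peep, x$pip_target, x$p_max))
  invisible(x)
}

#' Breath-cycle timing
#'
#' Breath cycle time `bct = 60/bpm` is the sum of inspiration and expiration
#' times. The trigger bookkeeping splits the cycle into a non-synchronised
#' part `non_sync_time = bct * (1 - sync_window_fraction)` and, measured from
#' the start of expiration, `sync_time = non_sync_time - ti`; the patient
#' trigger window is the final `sync_window_fraction` of the cycle.
#'
#' @param bpm Breaths per minute.
#' @param ti Inspiration time, s (< `60/bpm`).
#' @param sync_window_fraction Trigger-window fraction of the cycle.
#' @return An object of class `breath_timing` with `bct`, `ti`, `te`,
#'   `non_sync_time` and `sync_time` (all s).
#' @examples
#' compute_timing(10, 2, 0.1) # bct 6, te 4, non_sync 5.4, sync 3.4
#' @export
compute_timing <- function(bpm, ti, sync_window_fraction = 0.1) {
  if (bpm < 6 || bpm > 60) stop("`bpm` must lie in [6, 60]")
  bct <- 60 / bpm
  if (ti <= 0 || ti >= bct)
    stop("`ti` must be positive and less than the breath cycle time")
  non_sync <- bct * (1 - sync_window_fraction)
  sync <- non_sync - ti
  if (sync <= 0)
    stop("sync_time must be positive: shorten ti or the sync window")
  structure(list(bct = bct, ti = ti, te = bct - ti,
                 non_sync_time = non_sync, sync_time = sync),
            class = "breath_timing")
}

#' SIMV patient-trigger rule
#'
#' A patient trigger fires only during expiration, only inside the trigger
#' window (the final `sync_window_fraction` of the cycle, i.e. cycle-elapsed
#' time past `non_sync_time`), and only when the sensed inspiratory flow is at
#' or above the trigger setpoint (">= setpoint" comparator).
#'
#' @param elapsed_in_cycle Time since the start of the current breath cycle, s.
#' @param timing A [compute_timing()] result.
#' @param sensed_flow Sensed inspiratory flow, ml/s.
#' @param trigger_flow Trigger setpoint, ml/s.
#' @param phase `"expiration"` or `"inspiration"`.
#' @return Logical: deliver the synchronised breath now.
#' @export
simv_should_trigger <- function(elapsed_in_cycle, timing, sensed_flow,
                                trigger_flow,
                                phase = c("expiration", "inspiration")) {
  stopifnot(inherits(timing, "breath_timing"))
  phase <- match.arg(phase)
  phase == "expiration" &&
    elapsed_in_cycle > timing$non_sync_time &&
    elapsed_in_cycle <= timing$bct &&
    is.finite(sensed_flow) && sensed_flow >= trigger_flow
}

#' Patient-circuit disconnection check
#'
#' A disconnection is flagged when the end-inspiratory PIP estimate falls
#' strictly below the threshold (default 5 cmH2O): with an open circuit,
#' pressure cannot build and flow rises. Recovery of the PIP estimate to the
#' threshold or above clears the condition.
#'
#' @param pip_estimate Band-filtered end-inspiratory PIP, cmH2O.
#' @param phase Phase at which the check runs; only `"inspiration_end"`
#'   triggers.
#' @param threshold Detection threshold, cmH2O.
#' @return Logical.
#' @examples
#' detect_disconnection(4.9, "inspiration_end") # TRUE
#' detect_disconnection(5.0, "inspiration_end") # FALSE (strict inequality)
#' @export
detect_disconnection <- function(pip_estimate,
                                 phase = c("inspiration_end", "expiration"),
                                 threshold = 5) {
  phase <- match.arg(phase)
  phase == "inspiration_end" && is.finite(pip_estimate) &&
    pip_estimate < threshold
}

#' Evaluate per-breath alarms
#'
#' One alarm per monitored quantity outside its `[low, high]` bounds (tidal
#' volume, PIP, PEEP/minimum pressure), plus the patient-circuit disconnection
#' alarm and a flow-sensor electrical-disconnection alarm when flow readings
#' were absent or non-finite for the breath.
#'
#' @param record A per-breath record: a list or one-row data frame with
#'   `delivered_volume`, `pip`, `min_pressure`, and optionally `disconnected`
#'   and `flow_ok`.
#' @param settings A [vent_settings()] (supplies the alarm bounds).
#' @return An object of class `alarm_state`: list with `active` (character
#'   vector drawn from `"TV"`, `"PIP"`, `"PEEP"`, `"disconnection"`,
#'   `"flow_sensor"`) and `audible` (logical).
#' @export
check_alarms <- function(record, settings) {
  stopifnot(inherits(settings, "vent_settings"))
  b <- settings$alarm_bounds
  active <- character(0)
  out_of <- function(x, bounds) is.finite(x) && (x < bounds[1] || x > bounds[2])
  if (out_of(record$delivered_volume, b$tv)) active <- c(active, "TV")
  if (out_of(record$pip, b$pip)) active <- c(active, "PIP")
  if (out_of(record$min_pressure, b$min_pressure)) active <- c(active, "PEEP")
  if (isTRUE(record$disconnected)) active <- c(active, "disconnection")
  if (isFALSE(record$flow_ok)) active <- c(active, "flow_sensor")
  structure(list(active = active, audible = length(active) > 0),
            class = "alarm_state")
}

#' Controller gain configuration for the mode loops
#'
#' Gains tuned on the default lung and circuit. `kp_volume` acts once per
#' breath on the tidal-volume error (counts per ml, PRVC). In PCV the speed is
#' `base + kp_pressure * (PIP target - sensed pressure)` every sample, and the
#' base (the recalibrated feed-forward value) is trimmed once per breath by
#' `kp_pip` times the band-filtered PIP error. `kp_peep` likewise trims the
#' expiratory speed once per breath from the previous breath's PEEP estimate
#' (counts per cmH2O).
#'
#' @param kp_volume,kp_pressure,kp_pip,kp_peep Proportional gains.
#' @param min_speed Speed floor, counts; kept above zero so the turbine never
#'   restarts from standstill.
#' @return A list of class `control_gains`.
#' @export
control_gains <- function(kp_volume = 0.05, kp_pressure = 2, kp_pip = 2,
                          kp_peep = 2, min_speed = 10) {
  stopifnot(kp_volume > 0, kp_pressure > 0, kp_pip > 0, kp_peep > 0,
            min_speed >= 0, min_speed <= 255)
  structure(list(kp_volume = kp_volume, kp_pressure = kp_pressure,
                 kp_pip = kp_pip, kp_peep = kp_peep, min_speed = min_speed),
            class = "control_gains")
}

#' Sensor noise and calibration configuration
#'
#' @param pressure_noise_sd Analog pressure noise, counts.
#' @param flow_noise_sd Flow noise, ml/s.
#' @param calibration A [sensor_calibration()].
#' @return A list of class `sensor_config`.
#' @export
sensor_config <- function(pressure_noise_sd = 1, flow_noise_sd = 2,
                          calibration = sensor_calibration()) {
  stopifnot(pressure_noise_sd >= 0, flow_noise_sd >= 0,
            inherits(calibration, "sensor_calibration"))
  structure(list(pressure_noise_sd = pressure_noise_sd,
                 flow_noise_sd = flow_noise_sd, calibration = calibration),
            class = "sensor_config")
}

#' Run a closed-loop ventilation simulation
#'
#' The firmware's top-level loop against the synthetic test lung. Each breath
#' is delivered as an inspiration of length `ti` (servo closed; PRVC holds a
#' per-breath constant speed, PCV adjusts the speed every sample toward the
#' PIP target) followed by an expiration (servo open; speed trimmed per breath
#' toward the set PEEP). PIP and the expiratory minimum pressure are estimated
#' from the last 50 sensed samples of the respective phase via [band_filter()].
#' The tidal volume is the integral of the sensed inspiratory-limb flow over
#' inspiration. SIMV triggering, disconnection detection and alarm evaluation
#' run as described in [simv_should_trigger()], [detect_disconnection()] and
#' [check_alarms()]. A patient-triggered breath ends the expiration early and
#' advances the cycle by one breath.
#'
#' @param settings A [vent_settings()].
#' @param lung A [lung_params()].
#' @param scenario A [make_scenario()].
#' @param n_breaths Number of breath cycles to simulate.
#' @param dt Firmware loop period, s (default 1 ms).
#' @param seed Integer seed; given the same configuration and seed the run is
#'   reproducible bit for bit.
#' @param circuit A [circuit_params()].
#' @param gains A [control_gains()].
#' @param sensors A [sensor_config()].
#' @param filter_cfg Window/shrink used for PIP and PEEP estimation;
#'   a [filter_config()].
#' @return An object of class `vent_run`: list with `samples` (per-sample
#'   data frame: time, node pressures p1-p4, airway and sensed pressure,
#'   sensed flow, branch flows, lung volume, motor speed, servo fraction,
#'   breath index), `breaths` (per-breath records), `alarms` (final
#'   [check_alarms()] state), `energy` (from [simulate_power()] and
#'   [integrate_energy()]), `settings`, `timing`, `dt`, `seed`.
#' @seealso [run_prvc()], [run_pcv()]
#' @export
run_ventilator <- function(settings, lung = lung_params(),
                           scenario = make_scenario("normal"),
                           n_breaths = 20, dt = 0.001, seed = 1,
                           circuit = circuit_params(),
                           gains = control_gains(),
                           sensors = sensor_config(),
                           filter_cfg = filter_config(50, 0.5)) {
  stopifnot(inherits(settings, "vent_settings"), inherits(lung, "lung_params"),
            inherits(scenario, "vent_scenario"), n_breaths >= 1, dt > 0)
  timing <- compute_timing(settings$bpm, settings$ti,
                           settings$sync_window_fraction)
  steps_in <- max(2L, as.integer(round(settings$ti / dt)))
  steps_bct <- as.integer(round(timing$bct / dt))
  steps_ex <- steps_bct - steps_in
  n_max <- n_breaths * steps_bct + 2L

  cal <- sensors$calibration
  cC <- cal$c_constant; cOff <- cal$analog_offset
  pip_t <- settings$pip_target
  is_pcv <- settings$mode == "PCV"
  flow_clip <- 250000 / 60

  # preallocated per-sample storage (flat vectors: hot loop)
  v_time <- numeric(n_max); v_p1 <- numeric(n_max); v_p2 <- numeric(n_max)
  v_p3 <- numeric(n_max); v_p4 <- numeric(n_max); v_aw <- numeric(n_max)
  v_pm <- numeric(n_max); v_fm <- numeric(n_max); v_qin <- numeric(n_max)
  v_qpeep <- numeric(n_max); v_qleak <- numeric(n_max)
  v_vol <- numeric(n_max); v_spd <- numeric(n_max)
  v_servo <- numeric(n_max); v_breath <- integer(n_max)

  B <- list(breath = integer(n_breaths), t_start = numeric(n_breaths),
            trigger_type = character(n_breaths),
            delivered_volume = numeric(n_breaths), pip = numeric(n_breaths),
            min_pressure = numeric(n_breaths),
            motor_speed_insp = numeric(n_breaths),
            motor_speed_exh = numeric(n_breaths),
            disconnected = logical(n_breaths),
            alarms = character(n_breaths))

  ff_vol <- default_ff_table("volume", circuit, lung, peep_assumed = settings$peep)
  ff_pip <- default_ff_table("pressure", circuit, lung)
  ff_peep <- default_ff_table("peep", circuit, lung)

  min_s <- gains$min_speed
  insp_base <- if (is_pcv) feed_forward_lookup(pip_t, ff_pip)
  else feed_forward_lookup(settings$tidal_volume, ff_vol)
  insp_base <- min(255, max(min_s, insp_base))
  exh_speed <- min(255, max(min_s, feed_forward_lookup(settings$peep, ff_peep)))

  lung_par <- lung
  lung_par$effort_profile <- scenario$effort
  comp_ev <- scenario$compliance_events
  n_ev <- nrow(comp_ev)
  ev_i <- 1L

  run <- with_seed(seed, {
    pnoise <- if (sensors$pressure_noise_sd > 0)
      stats::rnorm(n_max, 0, sensors$pressure_noise_sd) else numeric(n_max)
    fnoise <- if (sensors$flow_noise_sd > 0)
      stats::rnorm(n_max, 0, sensors$flow_noise_sd) else numeric(n_max)

    st <- lung_state(time = 0)
    k <- 0L
    next_trigger <- "machine"
    alarm_state <- NULL
    win_n <- filter_cfg$n

    for (b in seq_len(n_breaths)) {
      t_start <- st$time
      trigger_type <- next_trigger
      next_trigger <- "machine"

      ## ---- inspiration (servo closed) ----
      s <- insp_base
      last_pm <- if (k > 0) v_pm[k] else settings$peep
      vol_int <- 0
      for (i in seq_len(steps_in)) {
        while (ev_i <= n_ev && st$time >= comp_ev$time[ev_i]) {
          lung_par$compliance <- lung_par$compliance * comp_ev$factor[ev_i]
          ev_i <- ev_i + 1L
        }
        if (is_pcv)
          s <- min(255, max(min_s, insp_base +
                              gains$kp_pressure * (pip_t - last_pm)))
        res <- step_circuit(s, 0, st, lung_par, circuit, scenario, dt,
                            p_max = settings$p_max)
        st <- res$lung; pn <- res$pneumatic
        k <- k + 1L
        counts <- min(1023, max(0, round(pn$airway_pressure / cC + cOff +
                                           pnoise[k])))
        pm <- (counts - cOff) * cC
        fm <- min(flow_clip, max(-flow_clip, pn$q_in + fnoise[k]))
        last_pm <- pm
        vol_int <- vol_int + max(0, fm) * dt
        v_time[k] <- st$time; v_p1[k] <- pn$p1; v_p2[k] <- pn$p2
        v_p3[k] <- pn$p3; v_p4[k] <- pn$p4
        v_aw[k] <- pn$airway_pressure
        v_pm[k] <- pm; v_fm[k] <- fm
        v_qin[k] <- pn$q_in; v_qpeep[k] <- pn$q_peep; v_qleak[k] <- pn$q_leak
        v_vol[k] <- st$volume_above_frc
        v_spd[k] <- s; v_servo[k] <- 0; v_breath[k] <- b
      }
      speed_insp_end <- s

      nw <- min(win_n, steps_in)
      pip_est <- band_filter(v_pm[(k - nw + 1L):k],
                             filter_config(nw, filter_cfg$shrink_percent))$filtered_mean
      flow_ok <- all(is.finite(v_fm[(k - steps_in + 1L):k]))
      disc_now <- detect_disconnection(pip_est, "inspiration_end")
      if (!disc_now) {
        if (is_pcv) {
          # recalibrate the feed-forward base from the filtered PIP
          insp_base <- min(255, max(min_s, insp_base +
                                      gains$kp_pip * (pip_t - pip_est)))
        } else {
          insp_base <- min(255, max(min_s, insp_base +
                                      gains$kp_volume *
                                        (settings$tidal_volume - vol_int)))
        }
      }

      ## ---- expiration (servo open) ----
      s <- if (disc_now) min_s else exh_speed  # safety: drop to minimum speed
      j_used <- 0L
      for (j in seq_len(steps_ex)) {
        while (ev_i <= n_ev && st$time >= comp_ev$time[ev_i]) {
          lung_par$compliance <- lung_par$compliance * comp_ev$factor[ev_i]
          ev_i <- ev_i + 1L
        }
        res <- step_circuit(s, 1, st, lung_par, circuit, scenario, dt,
                            p_max = settings$p_max)
        st <- res$lung; pn <- res$pneumatic
        k <- k + 1L
        counts <- min(1023, max(0, round(pn$airway_pressure / cC + cOff +
                                           pnoise[k])))
        pm <- (counts - cOff) * cC
        fm <- min(flow_clip, max(-flow_clip, pn$q_in + fnoise[k]))
        v_time[k] <- st$time; v_p1[k] <- pn$p1; v_p2[k] <- pn$p2
        v_p3[k] <- pn$p3; v_p4[k] <- pn$p4
        v_aw[k] <- pn$airway_pressure
        v_pm[k] <- pm; v_fm[k] <- fm
        v_qin[k] <- pn$q_in; v_qpeep[k] <- pn$q_peep; v_qleak[k] <- pn$q_leak
        v_vol[k] <- st$volume_above_frc
        v_spd[k] <- s; v_servo[k] <- 1; v_breath[k] <- b
        j_used <- j
        if (settings$simv && !disc_now) {
          elapsed <- (steps_in + j) * dt
          if (simv_should_trigger(elapsed, timing, fm,
                                  settings$trigger_flow, "expiration")) {
            next_trigger <- "patient"
            break
          }
        }
      }

      nw <- min(win_n, j_used)
      peep_est <- if (nw >= 2)
        band_filter(v_pm[(k - nw + 1L):k],
                    filter_config(nw, filter_cfg$shrink_percent))$filtered_mean
      else settings$peep
      if (!disc_now)
        exh_speed <- min(255, max(min_s, exh_speed +
                                    gains$kp_peep * (settings$peep - peep_est)))

      rec <- list(delivered_volume = vol_int, pip = pip_est,
                  min_pressure = peep_est, disconnected = disc_now,
                  flow_ok = flow_ok)
      alarm_state <- check_alarms(rec, settings)
      B$breath[b] <- b; B$t_start[b] <- t_start
      B$trigger_type[b] <- trigger_type
      B$delivered_volume[b] <- vol_int; B$pip[b] <- pip_est
      B$min_pressure[b] <- peep_est
      B$motor_speed_insp[b] <- speed_insp_end
      B$motor_speed_exh[b] <- s
      B$disconnected[b] <- disc_now
      B$alarms[b] <- paste(alarm_state$active, collapse = "|")
    }
    list(k = k, alarm_state = alarm_state)
  })

  k <- run$k
  idx <- seq_len(k)
  samples <- data.frame(
    time = v_time[idx], p1 = v_p1[idx], p2 = v_p2[idx], p3 = v_p3[idx],
    p4 = v_p4[idx], airway = v_aw[idx], sensed_pressure = v_pm[idx],
    sensed_flow = v_fm[idx], q_in = v_qin[idx], q_peep = v_qpeep[idx],
    q_leak = v_qleak[idx], volume = v_vol[idx], motor_speed = v_spd[idx],
    servo = v_servo[idx], breath = v_breath[idx])
  breaths <- as.data.frame(B, stringsAsFactors = FALSE)
  power <- simulate_power(samples$motor_speed)
  energy <- list(power_w = power,
                 energy_wh = integrate_energy(power, dt),
                 avg_power_w = if (k > 1)
                   average_power(integrate_energy(power, dt),
                                 (k - 1) * dt / 3600) else 0)
  structure(list(samples = samples, breaths = breaths,
                 alarms = run$alarm_state, energy = energy,
                 settings = settings, timing = timing, dt = dt, seed = seed),
            class = "vent_run")
}

#' @export
print.vent_run <- function(x, ...) {
  nb <- nrow(x$breaths)
  last <- x$breaths[max(1, nb - 4):nb, ]
  cat(sprintf("<vent_run> %s, %d breaths, %.1f s simulated\n",
              x$settings$mode, nb, nrow(x$samples) * x$dt))
  cat(sprintf("  last breaths: VT %.0f ml, PIP %.1f cmH2O, min P %.1f cmH2O\n",
              mean(last$delivered_volume), mean(last$pip),
              mean(last$min_pressure)))
  if (length(x$alarms$active))
    cat("  active alarms:", paste(x$alarms$active, collapse = ", "), "\n")
  invisible(x)
}

#' Run the PRVC mode
#'
#' Pressure-regulated volume control: each inspiration is delivered at a
#' per-breath constant speed that starts from the feed-forward table and is
#' adjusted every cycle by the proportional law on the tidal-volume error
#' (target minus delivered), reaching the target volume with the lowest
#' pressure the lung requires.
#'
#' @inheritParams run_ventilator
#' @param ... Passed on to [run_ventilator()].
#' @return A `vent_run`; see [run_ventilator()].
#' @export
run_prvc <- function(settings = vent_settings("PRVC"), lung = lung_params(),
                     scenario = make_scenario("normal"), n_breaths = 20,
                     seed = 1, ...) {
  if (settings$mode != "PRVC") stop("`settings$mode` must be 'PRVC'")
  run_ventilator(settings, lung, scenario, n_breaths = n_breaths,
                 seed = seed, ...)
}

#' Run the PCV mode
#'
#' Pressure control ventilation: the speed is adjusted every sample during
#' inspiration to hold the sensed pressure at the PIP target, and the
#' expiration is regulated toward the set PEEP. PIP is estimated per breath
#' by [band_filter()] over the last inspiratory samples (not the raw
#' maximum); the disconnection check runs every breath.
#'
#' @inheritParams run_ventilator
#' @param ... Passed on to [run_ventilator()].
#' @return A `vent_run`; see [run_ventilator()].
#' @export
run_pcv <- function(settings = vent_settings("PCV"), lung = lung_params(),
                    scenario = make_scenario("normal"), n_breaths = 20,
                    seed = 1, ...) {
  if (settings$mode != "PCV") stop("`settings$mode` must be 'PCV'")
  run_ventilator(settings, lung, scenario, n_breaths = n_breaths,
                 seed = seed, ...)
}
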