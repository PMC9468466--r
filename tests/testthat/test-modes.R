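test_that("breath timing follows the cycle-time and window arithmetic", {
  expect_equal(compute_timing(10, 2)$bct, 6)
  t1 <- compute_timing(12, 2)
  expect_equal(t1$te, 3)
  expect_equal(t1$ti + t1$te, t1$bct)
  t2 <- compute_timing(10, 2, 0.1)
  expect_equal(t2$non_sync_time, 5.4)
  expect_equal(t2$sync_time, 3.4)
  expect_error(compute_timing(12, 5), "breath cycle")
  expect_error(compute_timing(12, 3.1, 0.4), "sync_time")
})

test_that("settings are validated against the GUI ranges", {
  expect_s3_class(vent_settings("PRVC"), "vent_settings")
  expect_error(vent_settings(tidal_volume = 50), "100, 999")
  expect_error(vent_settings(bpm = 80), "6, 60")
  expect_error(vent_settings(pip_target = 40), "0, 35")
  expect_error(vent_settings(peep = 13), "0, 12")
  expect_error(vent_settings(bpm = 30, ti = 2), "breath cycle")
  expect_error(vent_settings(pip_target = 30, p_max = 20), "p_max")
  expect_error(vent_settings(alarm_bounds = list(tv = c(5, 1),
                                                 pip = c(1, 45),
                                                 min_pressure = c(0, 15))),
               "low < high")
})

test_that("the SIMV trigger fires only in the window, only on enough flow", {
  tm <- compute_timing(12, 2, 0.4)  # bct 5, window (3, 5]
  expect_true(simv_should_trigger(3.5, tm, 25, 20, "expiration"))
  expect_true(simv_should_trigger(3.5, tm, 20, 20, "expiration"))  # >= rule
  expect_false(simv_should_trigger(3.5, tm, 19.9, 20, "expiration"))
  expect_false(simv_should_trigger(2.5, tm, 100, 20, "expiration"))
  expect_false(simv_should_trigger(5.1, tm, 100, 20, "expiration"))
  expect_false(simv_should_trigger(3.5, tm, 100, 20, "inspiration"))
})

test_that("disconnection detection uses a strict 5 cmH2O end-inspiratory rule", {
  expect_true(detect_disconnection(4.9, "inspiration_end"))
  expect_false(detect_disconnection(5.0, "inspiration_end"))
  expect_false(detect_disconnection(4.9, "expiration"))
})

test_that("alarms flag each monitored quantity independently", {
  st <- vent_settings("PRVC", tidal_volume = 350,
                      alarm_bounds = list(tv = c(280, 520), pip = c(5, 30),
                                          min_pressure = c(2, 10)))
  ok <- list(delivered_volume = 350, pip = 15, min_pressure = 5)
  expect_length(check_alarms(ok, st)$active, 0)
  expect_false(check_alarms(ok, st)$audible)

  low_tv <- modifyList(ok, list(delivered_volume = 250))
  expect_equal(check_alarms(low_tv, st)$active, "TV")

  both <- modifyList(ok, list(pip = 35, min_pressure = 1))
  expect_setequal(check_alarms(both, st)$active, c("PIP", "PEEP"))

  disc <- modifyList(ok, list(disconnected = TRUE, flow_ok = FALSE))
  expect_setequal(check_alarms(disc, st)$active,
                  c("disconnection", "flow_sensor"))
  expect_true(check_alarms(disc, st)$audible)
})

test_that("PRVC converges to the target tidal volume on the default lung", {
  r <- prvc_run()
  b <- r$breaths
  expect_equal(nrow(b), 20)
  last5 <- b$delivered_volume[16:20]
  expect_true(all(abs(last5 - 350) / 350 < 0.05))
  # airway pressure never exceeds the hard cap
  expect_lte(max(r$samples$airway), r$settings$p_max)
  # expiratory pressure regulated to the set PEEP
  expect_true(all(abs(b$min_pressure[16:20] - 5) < 1))
})

test_that("PRVC re-converges after the lung compliance is halved", {
  b <- prvc_compliance_run()$breaths
  post <- which(b$t_start >= 60)
  rel_err <- abs(b$delivered_volume[post] - 350) / 350
  expect_lte(min(which(rel_err < 0.05)), 5)
  expect_true(all(abs(tail(b$delivered_volume, 3) - 350) / 350 < 0.05))
})

test_that("PCV holds the plateau at the PIP target and floors at PEEP", {
  r <- pcv_run()
  b <- r$breaths
  expect_true(all(abs(tail(b$pip, 5) - 20) < 1))
  expect_true(all(abs(tail(b$min_pressure, 5) - 5) < 1))
  # PIP is the band-filtered estimate, not the raw within-breath maximum
  s <- r$samples
  for (bi in c(6, 12)) {
    insp <- s$sensed_pressure[s$breath == bi & s$servo == 0]
    win <- tail(insp, 50)
    expect_equal(b$pip[bi], band_filter(win, filter_config(50, 0.5))$filtered_mean)
  }
})

test_that("machine breaths keep the 60/BPM schedule and runs are reproducible", {
  r <- prvc_run()
  expect_equal(diff(r$breaths$t_start), rep(5, 19), tolerance = 1e-9)
  expect_true(all(r$breaths$trigger_type == "machine"))

  st <- vent_settings("PRVC")
  a <- run_prvc(st, n_breaths = 3, seed = 42)
  b <- run_prvc(st, n_breaths = 3, seed = 42)
  expect_identical(a$samples, b$samples)
  expect_identical(a$breaths, b$breaths)
  c2 <- run_prvc(st, n_breaths = 3, seed = 43)
  expect_false(identical(a$samples, c2$samples))
})

test_that("a circuit disconnection raises the alarm and clears on reconnect", {
  r <- disconnect_run()  # leak opens at 14 s, closes at 30 s
  b <- r$breaths
  disc_breaths <- which(b$disconnected)
  expect_true(length(disc_breaths) > 0)
  # detected within 2 breaths of the leak opening
  first_after_leak <- min(which(b$t_start >= 14))
  expect_lte(min(disc_breaths) - first_after_leak, 2)
  expect_true(all(b$pip[disc_breaths] < 5))
  expect_true(all(grepl("disconnection", b$alarms[disc_breaths])))
  # safety response: expiration at minimum motor speed while disconnected
  expect_true(all(b$motor_speed_exh[disc_breaths] == 10))
  # recovery after the circuit is reconnected
  post <- which(b$t_start >= 30)
  expect_false(any(b$disconnected[post]))
  expect_false(any(grepl("disconnection", b$alarms[post])))
  expect_true(all(b$pip[post] > 5))
})

test_that("SIMV triggers a synchronized breath only inside the window", {
  r <- simv_run()  # efforts at 8.7 s (in window) and 16.0 s (outside)
  b <- r$breaths
  expect_equal(sum(b$trigger_type == "patient"), 1)
  pat <- which(b$trigger_type == "patient")
  # the preceding cycle was cut short inside the trigger window (3, 5] s
  cyc <- b$t_start[pat] - b$t_start[pat - 1]
  expect_gt(cyc, r$timing$non_sync_time)
  expect_lte(cyc, r$timing$bct)
  # the patient breath arrives earlier than the machine schedule
  expect_lt(b$t_start[pat], (pat - 1) * r$timing$bct)
})

test_that("mode wrappers validate their mode", {
  expect_error(run_prvc(vent_settings("PCV")), "PRVC")
  expect_error(run_pcv(vent_settings("PRVC")), "PCV")
})
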