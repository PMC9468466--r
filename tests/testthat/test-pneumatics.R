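test_that("turbine fan laws hit the rated extremes and are monotone", {
  expect_equal(turbine_pressure(0), list(stall_pressure = 0, flow_limit = 0))
  full <- turbine_pressure(255)
  expect_equal(full$stall_pressure, 70)
  expect_equal(full$flow_limit, 240000 / 60)
  half <- turbine_pressure(128)
  expect_equal(half$stall_pressure, 70 * (128 / 255)^2)
  s <- 0:255
  p <- vapply(s, function(x) turbine_pressure(x)$stall_pressure, numeric(1))
  q <- vapply(s, function(x) turbine_pressure(x)$flow_limit, numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_true(all(diff(q) >= 0))
  expect_warning(turbine_pressure(300), "clamped")
})

test_that("PRM divides the inlet pressure conservatively", {
  # closed valve: nothing vented, p1 split across patient and pilot branches
  closed <- prm_balance(35, 0)
  expect_equal(closed$p3, 0)
  expect_equal(closed$p2 + closed$p4, 35)

  # fully open with a large vent conductance: most of p1 vents through p3
  open <- prm_balance(35, 1, prm_params(vent_conductance_open = 50))
  expect_gt(open$p3, 0.9 * 35)
  expect_lt(open$p2, closed$p2)
  expect_lt(open$p4, closed$p4)

  # conservation and monotonicity in the servo fraction, over a seeded grid
  set.seed(11)
  for (i in 1:50) {
    p1 <- runif(1, 0, 70)
    fr <- sort(runif(5))
    states <- lapply(fr, function(f) prm_balance(p1, f))
    resid <- vapply(states, function(s) abs(s$p1 - (s$p2 + s$p3 + s$p4)),
                    numeric(1))
    expect_lt(max(resid), 1e-9)
    p3s <- vapply(states, `[[`, numeric(1), "p3")
    p2s <- vapply(states, `[[`, numeric(1), "p2")
    p4s <- vapply(states, `[[`, numeric(1), "p4")
    expect_true(all(diff(p3s) >= 0))
    expect_true(all(diff(p2s) <= 0))
    expect_true(all(diff(p4s) <= 0))
  }
  expect_error(prm_balance(-1, 0), "negative")
})

test_that("one-way valve cracks at threshold and never flows backward", {
  expect_equal(one_way_flow(-10), 0)
  expect_equal(one_way_flow(5), 0)  # at the cracking threshold
  expect_gt(one_way_flow(7), one_way_flow(6))
  expect_gt(one_way_flow(6), 0)
  expect_true(all(one_way_flow(seq(-20, 20, by = 0.5)) >= 0))
})

test_that("PEEP valve seals under pilot pressure and opens above it", {
  expect_equal(peep_valve_flow(10, 15), 0)  # inhale state: sealed
  expect_equal(peep_valve_flow(10, 10), 0)  # boundary
  expect_equal(peep_valve_flow(15, 10), 100 * 5)
})

test_that("step_circuit at rest with everything closed moves nothing", {
  res <- step_circuit(0, 0, lung_state(), lung_params())
  pn <- res$pneumatic
  expect_equal(pn$p1, 0)
  expect_equal(pn$q_in, 0)
  expect_equal(pn$q_peep, 0)
  expect_equal(res$lung$volume_above_frc, 0)
})

test_that("step_circuit agrees with the standalone component operations", {
  circuit <- circuit_params()
  st <- lung_state(time = 0.5, volume_above_frc = 150, flow = 300,
                   alveolar_pressure = 3, airway_pressure = 8)
  res <- step_circuit(150, 0.3, st, lung_params(), circuit)
  pn <- res$pneumatic

  tb <- turbine_pressure(150, circuit$turbine)
  p1 <- tb$stall_pressure * (1 - max(0, st$flow) / tb$flow_limit)
  prm <- prm_balance(p1, 0.3, circuit$prm)
  expect_equal(pn$p1, p1)
  expect_equal(pn$p2, prm$p2)
  expect_equal(pn$p3, prm$p3)
  expect_equal(pn$p4, prm$p4)
  expect_equal(pn$q_in, one_way_flow(pn$p2 - pn$airway_pressure,
                                     circuit$one_way_cracking,
                                     circuit$one_way_conductance))
  expect_equal(pn$q_peep,
               peep_valve_flow(pn$airway_pressure,
                               circuit$prm$pilot_gain * pn$p4,
                               circuit$peep_conductance))
  expect_equal(res$lung,
               step_lung(st, lung_params(), pn$airway_pressure, 0.001))
})

test_that("constant drive inflates the lung monotonically to its equilibrium", {
  # At equilibrium the lung flow vanishes, so the turbine runs droop-free and
  # V_inf = C * (patient_split * stall(s) - cracking): a closed-form oracle.
  circuit <- circuit_params()
  par <- lung_params()
  st <- lung_state()
  vols <- numeric(8000)  # ~10 effective time constants
  for (i in seq_along(vols)) {
    st <- step_circuit(150, 0, st, par, circuit)$lung
    vols[i] <- st$volume_above_frc
  }
  stall <- turbine_pressure(150)$stall_pressure
  v_inf <- par$compliance *
    (circuit$prm$patient_split * stall - circuit$one_way_cracking)
  expect_true(all(diff(vols) >= -1e-9))
  expect_lt(abs(vols[length(vols)] - v_inf) / v_inf, 0.01)
})

test_that("pressure balance survives a randomized stress of circuit states", {
  set.seed(4)
  par <- lung_params()
  for (i in 1:200) {
    st <- lung_state(time = runif(1, 0, 10),
                     volume_above_frc = runif(1, 0, 800),
                     flow = runif(1, -500, 1500))
    res <- step_circuit(runif(1, 0, 255), runif(1), st, par)
    pn <- res$pneumatic
    expect_lt(abs(pn$p1 - (pn$p2 + pn$p3 + pn$p4)), 1e-9)
    expect_gte(pn$q_in, 0)
    expect_gte(pn$q_peep, 0)
  }
})

test_that("an open circuit collapses airway pressure within a second", {
  sc <- make_scenario("disconnect", event_times = 0)
  par <- lung_params()
  st <- lung_state(volume_above_frc = 250)
  aw <- numeric(1000)
  for (i in seq_along(aw)) {
    res <- step_circuit(170, 0, st, par, scenario = sc)
    st <- res$lung
    aw[i] <- res$pneumatic$airway_pressure
  }
  expect_lt(aw[1000], 5)
  expect_lt(max(aw[500:1000]), 5)
})
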