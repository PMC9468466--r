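# Shared closed-loop runs, computed once per test session (the mode loops are
# the expensive part of the suite; every test that needs a standard run reuses
# these).

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.run_cache[[name]])) assign(name, expr, envir = .run_cache)
  .run_cache[[name]]
}

# 20 mandatory PRVC breaths at the default settings (VT 350 ml, 12 BPM,
# Ti 2 s, PEEP 5), default lung: 100 s of simulation.
prvc_run <- function() cached("prvc", run_prvc(
  vent_settings("PRVC", tidal_volume = 350, bpm = 12, ti = 2, peep = 5),
  n_breaths = 20, seed = 1))

# PRVC with lung compliance halved at t = 60 s (breath 13).
prvc_compliance_run <- function() cached("prvc_comp", run_prvc(
  vent_settings("PRVC", tidal_volume = 350, bpm = 12, ti = 2, peep = 5),
  scenario = make_scenario("normal",
                           compliance_events = data.frame(time = 60,
                                                          factor = 0.5)),
  n_breaths = 25, seed = 1))

# 12 PCV breaths (exactly 60 s) at PIP 20 / PEEP 5.
pcv_run <- function() cached("pcv", run_pcv(
  vent_settings("PCV", pip_target = 20, bpm = 12, ti = 2, peep = 5),
  n_breaths = 12, seed = 1))

# Patient-circuit disconnection: leak opens at 14 s, reconnected at 30 s.
disconnect_run <- function() cached("disc", run_pcv(
  vent_settings("PCV", pip_target = 20, bpm = 12, ti = 2, peep = 5),
  scenario = make_scenario("reconnect", event_times = c(14, 30)),
  n_breaths = 10, seed = 3))

# SIMV with the widened 40% trigger window (the configuration used for the
# manual-pull validation): one effort inside breath 2's window, one outside.
simv_run <- function() cached("simv", run_pcv(
  vent_settings("PCV", pip_target = 20, bpm = 12, ti = 2, peep = 3,
                simv = TRUE, sync_window_fraction = 0.4),
  scenario = make_scenario("spontaneous", event_times = c(8.7, 16.0)),
  n_breaths = 8, seed = 2))
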