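# Shared fixtures for the suite.  Everything is built in code; no stored
# binary data.

default_params <- function(...) task_parameters(...)

# A scripted responder: lifts at `go_lift` seconds on go trials and at
# `stop_lift` on stop trials (NA = holds through the trial).
scripted_responder <- function(go_lift = 0.8, stop_lift = NA_real_,
                               restarts_on = integer(0)) {
  counter <- 0L
  function(trial, ssd) {
    counter <<- counter + 1L
    list(lift = if (trial$signal == 0) go_lift else stop_lift,
         restarts = if (counter %in% restarts_on) 1L else 0L)
  }
}

# Independent brute-force oracle for the integration-method SSRT: replace
# omissions by the trial duration, then walk the sorted augmented RTs until
# the cumulative fraction first reaches p, and subtract the mean SSD.
ssrt_oracle <- function(go_rts, n_om, p, mean_ssd, trial_duration) {
  v <- sort(c(go_rts, rep(trial_duration, n_om)))
  n <- length(v)
  for (k in seq_len(n)) {
    if (k / n >= p) return(v[k] - mean_ssd)
  }
  v[n] - mean_ssd
}

# Simulate a stationary participant through n staircased stop trials and
# return the session (a single stop-only mixed block: go trials never touch
# the staircase, so this is equivalent and fast).
stop_only_session <- function(participant, params, n_stop, seed) {
  blk <- block_spec("testMixed", n_go = 0, n_stop = n_stop)
  simulate_session(participant, params, list(blk), seed = seed)
}
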