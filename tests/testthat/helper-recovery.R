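# Match detected events to ground-truth events by start-time proximity and
# score class agreement; used by the synthgen/events recovery tests and the
# acceptance suite.
recovery_stats <- function(labeled, events, tol_s = 0.05) {
  tr <- labeled$truth_events
  n <- nrow(tr)
  agree <- 0L
  max_err_s <- 0
  for (j in seq_len(n)) {
    k <- which(abs(events$start_s - tr$start_s[j]) < tol_s)
    if (length(k) == 1L) {
      if (events$class[k] == tr$class[j]) agree <- agree + 1L
      max_err_s <- max(max_err_s,
                       abs(events$start_s[k] - tr$start_s[j]),
                       abs(events$end_s[k] - tr$end_s[j]))
    }
  }
  list(n_truth = n, n_detected = nrow(events), n_agree = agree,
       max_err_s = max_err_s)
}

# pooled recovery over a set of generated traces
pooled_recovery <- function(noise_sd_mv, n_traces, duration_s = 45,
                            seed0 = 100) {
  tot <- 0L; agree <- 0L; detected <- 0L; max_err <- 0
  for (i in seq_len(n_traces)) {
    lt <- make_trace(trace_spec(
      duration_s, noise_sd_mv = noise_sd_mv, event_rate_hz = 0.6,
      spike_kind = if (i %% 2) "A" else "B", burst_fraction = 0.4,
      burst_duration_ms = 200, spikelets_per_burst = 3, seed = seed0 + i))
    ev <- detect_events(lt$trace)
    st <- recovery_stats(lt, ev)
    tot <- tot + st$n_truth; agree <- agree + st$n_agree
    detected <- detected + st$n_detected
    max_err <- max(max_err, st$max_err_s)
  }
  list(n_truth = tot, n_detected = detected, agreement = agree / tot,
       max_err_s = max_err)
}
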