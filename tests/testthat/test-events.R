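flat_trace <- function(v = -51, n = 20000, fs = 10000)
  voltage_trace(rep(v, n), fs)

test_that("baseline estimator resists event contamination", {
  expect_equal(estimate_baseline(flat_trace(-51)), -51)
  # flat trace with 5% of samples pushed to -20 (spike-like contamination)
  v <- rep(-51, 10000)
  v[seq(1, 10000, by = 20)] <- -20
  expect_equal(estimate_baseline(voltage_trace(v, 10000)), -51, tolerance = 0.1)
  # pure noise around -50: median of the lower 60% sits slightly below the
  # mean; simulation-derived bound
  set.seed(42)
  v <- rnorm(60000, -50, 1)
  expect_equal(estimate_baseline(voltage_trace(v, 10000)), -50, tolerance = 0.3)
})

test_that("detector finds a single triangular excursion with the crossing geometry", {
  # triangle from -51 up to -20 over 20 ms and back over 20 ms at 10 kHz;
  # amplitude 31 mV: crosses baseline+20 at 20*(20/31) ms into the rise and
  # falls below baseline+5 at 20 + 20*(26/31) ms, giving 23.87 ms between
  # the crossings
  fs <- 10000
  up <- seq(-51, -20, length.out = 201)        # 20 ms rise
  down <- seq(-20, -51, length.out = 201)[-1]  # 20 ms fall
  v <- c(rep(-51, 5000), up, down, rep(-51, 5000))
  ev <- detect_events(voltage_trace(v, fs), baseline_mv = -51)
  expect_equal(nrow(ev), 1L)
  dur_expect <- (20 * (26 / 31) + 20 - 20 * (20 / 31))
  expect_equal(ev$duration_ms, dur_expect, tolerance = 0.3)
  expect_equal(ev$class, "spike")
  expect_equal(ev$peak_v_mv, -20)

  # sub-threshold excursion peaking at baseline + 15 -> no events
  v2 <- c(rep(-51, 5000), seq(-51, -36, length.out = 100),
          seq(-36, -51, length.out = 100), rep(-51, 5000))
  expect_equal(nrow(detect_events(voltage_trace(v2, fs), baseline_mv = -51)), 0L)
  # flat trace -> no events
  expect_equal(nrow(detect_events(flat_trace())), 0L)
})

test_that("spikelet counting honours prominence and separation rules", {
  fs <- 10000
  base <- -51
  # single smooth spike -> 1
  lt <- make_trace(trace_spec(10, noise_sd_mv = 0, event_rate_hz = 0.4, seed = 1))
  ev <- detect_events(lt$trace)
  expect_true(all(ev$n_spikelets == 1))
  # 150 ms plateau with 3 constructed peaks of prominence 10 -> 3
  t <- seq(0, 0.15, by = 1 / fs)
  plateau <- -29 + 10 * pmax(0, sin(2 * pi * t / 0.05))  # 3 bumps of 10 mV
  expect_equal(count_spikelets(plateau, baseline_mv = base, fs_hz = fs), 3L)
  # ripples of prominence 1 mV are ignored: single maximum counted
  ripple <- -29 + 1 * sin(2 * pi * t / 0.01)
  expect_equal(count_spikelets(ripple, baseline_mv = base, fs_hz = fs), 1L)
})

test_that("event classification partitions by duration and spikelets", {
  expect_equal(classify_event(50, 1), "spike")
  expect_equal(classify_event(150, 3), "burst")
  expect_equal(classify_event(150, 1), "other")
  expect_equal(classify_event(100, 5), "spike")   # boundary goes to spike
  expect_equal(classify_event(100.1, 2), "burst")
})

test_that("spike shape metrics match constructed geometry", {
  fs <- 10000
  # symmetric triangle: 20 ms base, peak +30 over baseline -> width at half
  # height = 10 ms
  up <- seq(0, 30, length.out = 101); down <- seq(30, 0, length.out = 101)[-1]
  v <- c(rep(0, 3000), up, down, rep(0, 3000)) - 51
  tr <- voltage_trace(v, fs)
  ev <- detect_events(tr, baseline_mv = -51)
  sh <- spike_shape(tr, ev[1, ], baseline_mv = -51)
  expect_equal(sh$width_ms, 10, tolerance = 0.5)
  expect_equal(sh$peak_amplitude_mv, 30)
  # no dip below baseline -> AHP floored at 0
  expect_equal(sh$ahp_amplitude_mv, 0)

  # constructed post-spike dip to baseline - 28
  dip <- c(rep(0, 3000), up, down, seq(0, -28, length.out = 200),
           seq(-28, 0, length.out = 400), rep(0, 3000)) - 51
  tr2 <- voltage_trace(dip, fs)
  ev2 <- detect_events(tr2, baseline_mv = -51)
  sh2 <- spike_shape(tr2, ev2[1, ], baseline_mv = -51)
  expect_equal(sh2$ahp_amplitude_mv, 28, tolerance = 0.5)

  # AHP window truncated by the end of the recording -> flagged missing
  short <- c(rep(0, 3000), up, down, rep(0, 100)) - 51
  tr3 <- voltage_trace(short, fs)
  ev3 <- detect_events(tr3, baseline_mv = -51)
  expect_true(is.na(spike_shape(tr3, ev3[1, ], baseline_mv = -51)$ahp_amplitude_mv))
})

test_that("A/B phenotyping averages ten consecutive spikes with an ambiguous band", {
  sh <- function(ahps) data.frame(ahp_amplitude_mv = ahps)
  expect_equal(classify_cell_ab(sh(rep(30, 10)))$label, "A")
  expect_equal(classify_cell_ab(sh(rep(15, 10)))$label, "B")
  expect_equal(classify_cell_ab(sh(rep(22, 10)))$label, "ambiguous")
  few <- classify_cell_ab(sh(rep(30, 7)))
  expect_equal(few$label, "none")
  expect_equal(few$n_spikes_used, 7L)
  # only the first 10 consecutive spikes count
  mixed <- classify_cell_ab(sh(c(rep(30, 10), rep(10, 10))))
  expect_equal(mixed$mean_ahp_mv, 30)
})

test_that("three-point membrane potential uses median windows", {
  expect_equal(membrane_potential(flat_trace(-51.4)), -51.4)
  # linear ramp -55 -> -45 over 60 s: windows at 0/50/100% average to -50
  v <- seq(-55, -45, length.out = 600000)
  expect_equal(membrane_potential(voltage_trace(v, 10000)), -50, tolerance = 0.1)
  # one mid-recording spike is rejected by the median windows
  v2 <- rep(-51, 600000)
  v2[299900:300100] <- -20
  expect_equal(membrane_potential(voltage_trace(v2, 10000)), -51, tolerance = 0.2)
})

test_that("burst factor is the burst proportion and missing when no events", {
  ev <- structure(data.frame(class = c("burst", "spike", "burst", "spike")),
                  class = c("ctph_events", "data.frame"))
  expect_equal(burst_factor(ev), 0.5)
  empty <- structure(data.frame(class = character(0)),
                     class = c("ctph_events", "data.frame"))
  expect_true(is.na(burst_factor(empty)))
})

test_that("cell summary arithmetic and the frequency partition hold", {
  # constructed event table: 30 spikes + 10 bursts in 60 s
  ev <- structure(data.frame(
    start_s = seq(0.5, 59, length.out = 40),
    end_s = seq(0.5, 59, length.out = 40) + 0.05,
    duration_ms = c(rep(30, 30), rep(200, 10)),
    peak_v_mv = rep(-25, 40), amplitude_mv = rep(26, 40),
    n_spikelets = c(rep(1, 30), rep(3, 10)),
    class = c(rep("spike", 30), rep("burst", 10))),
    class = c("ctph_events", "data.frame"),
    baseline_mv = -51, recording_duration_s = 60, fs_hz = 10000,
    n_truncated = 0L)
  s <- summarize_cell(flat_trace(n = 600000), ev,
                      metadata = list(capacitance_pf = 5, days_in_culture = 2))
  expect_equal(s$event_freq_hz, 40 / 60)
  expect_equal(s$spike_freq_hz, 0.5)
  expect_equal(s$burst_freq_hz, 10 / 60)
  expect_equal(s$burst_factor, 0.25)
  expect_equal(s$spike_freq_hz + s$burst_freq_hz, s$event_freq_hz)
  expect_equal(s$event_duration_ms, mean(c(rep(30, 30), rep(200, 10))))
  expect_equal(s$active_time_frac, sum(ev$duration_ms) / 1000 / 60)

  # empty table: zero frequencies, missing burst factor, zero active time
  empty <- detect_events(flat_trace(n = 600000))
  s0 <- summarize_cell(flat_trace(n = 600000), empty)
  expect_equal(s0$event_freq_hz, 0)
  expect_true(is.na(s0$burst_factor))
  expect_equal(s0$active_time_frac, 0)

  # analysis window cannot exceed the recording
  expect_error(summarize_cell(flat_trace(n = 600000), empty,
                              analysis_window_s = 120), "window")
})

test_that("raising the detection threshold never increases the event count", {
  lt <- make_trace(trace_spec(60, event_rate_hz = 0.8, burst_fraction = 0.3,
                              seed = 11))
  counts <- vapply(c(15, 20, 25, 28), function(th)
    nrow(detect_events(lt$trace, delta_threshold_mv = th)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is deterministic for identical traces", {
  lt <- make_trace(trace_spec(30, event_rate_hz = 0.7, seed = 9))
  e1 <- detect_events(lt$trace)
  e2 <- detect_events(lt$trace)
  expect_identical(e1, e2)
})
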