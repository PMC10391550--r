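test_that("spike templates respect the A/B shape contracts", {
  a <- spike_template("A"); b <- spike_template("B")
  expect_gt(max(a), 20); expect_gt(max(b), 20)
  expect_gte(-min(a), 25)            # A: large AHP
  expect_lte(-min(b), 20)            # B: small AHP
  expect_lt(abs(a[length(a)]), 1)    # returns to baseline
  expect_lt(abs(b[length(b)]), 1)
  # A is sharper: shorter time-to-peak and narrower at half height
  width_at_half <- function(w) {
    half <- max(w) / 2
    above <- which(w >= half)
    (max(above) - min(above)) / 10   # samples at 10 kHz -> ms
  }
  expect_lt(which.max(a), which.max(b))
  expect_lt(width_at_half(a), width_at_half(b))
  expect_error(spike_template("C"))
  expect_error(spike_template("A", amp_mv = 15), "20 mV")
})

test_that("burst template carries the requested plateau and spikelets", {
  w <- burst_template(duration_ms = 150, n_spikelets = 3)
  expect_equal(count_spikelets(w, baseline_mv = 0, fs_hz = 10000,
                               threshold_mv = 20), 3L)
  on <- attr(w, "on_idx"); off <- attr(w, "off_idx")
  expect_equal((off - on) / 10, 150, tolerance = 15)  # ms
  expect_error(burst_template(duration_ms = 80), "100 ms")
  expect_error(burst_template(n_spikelets = 1), "2 spikelets")
})

test_that("silent spec gives a flat trace and empty truth", {
  lt <- make_trace(trace_spec(10, event_rate_hz = 0, noise_sd_mv = 0))
  expect_equal(nrow(lt$truth_events), 0L)
  expect_true(all(lt$trace$v_mv == -51.4))
  expect_equal(lt$truth_cell_class, "none")
})

test_that("trace generation is bit-identical under a fixed seed", {
  sp <- trace_spec(60, event_rate_hz = 0.5, burst_fraction = 0.3, seed = 7)
  l1 <- make_trace(sp); l2 <- make_trace(sp)
  expect_identical(l1$trace$v_mv, l2$trace$v_mv)
  expect_identical(l1$truth_events, l2$truth_events)
  l3 <- make_trace(trace_spec(60, event_rate_hz = 0.5, burst_fraction = 0.3,
                              seed = 8))
  expect_false(identical(l1$trace$v_mv, l3$trace$v_mv))
})

test_that("all-burst spec yields only burst truth with requested geometry", {
  lt <- make_trace(trace_spec(60, event_rate_hz = 0.5, burst_fraction = 1,
                              burst_duration_ms = 150, spikelets_per_burst = 3,
                              seed = 5))
  expect_gt(nrow(lt$truth_events), 0)
  expect_true(all(lt$truth_events$class == "burst"))
  expect_true(all(lt$truth_events$n_spikelets == 3))
  durs <- (lt$truth_events$end_s - lt$truth_events$start_s) * 1000
  expect_true(all(abs(durs - 150) < 20))
})

test_that("truth events are ordered, non-overlapping, inside the record", {
  for (s in 1:5) {
    lt <- make_trace(trace_spec(45, event_rate_hz = 0.9, burst_fraction = 0.4,
                                seed = s))
    tr <- lt$truth_events
    expect_true(all(diff(tr$start_s) > 0))
    expect_true(all(tr$end_s > tr$start_s))
    expect_true(all(tr$start_s[-1] >= tr$end_s[-nrow(tr)]))
    expect_true(all(tr$end_s <= 45))
  }
})

test_that("excessive event rates are rejected with an explanation", {
  expect_error(make_trace(trace_spec(10, event_rate_hz = 3,
                                     burst_fraction = 1,
                                     burst_duration_ms = 500)),
               "refractory")
})

test_that("generated spikes avoid the ambiguous AHP band", {
  # generator guarantee: A spikes are >= 25 mV deep, B spikes <= 20 mV, so
  # classification at zero noise can never land in the 20-25 band
  for (kind in c("A", "B")) {
    lt <- make_trace(trace_spec(60, noise_sd_mv = 0, event_rate_hz = 0.5,
                                spike_kind = kind, seed = 3))
    s <- analyze_trace(lt)
    expect_equal(s$ab_class, kind)
    expect_true(s$mean_ahp_mv > 25 || s$mean_ahp_mv < 20)
  }
})

test_that("basal cohort rates calibrate to the sex-specific means", {
  counts <- data.frame(sex = c("male", "female"), cell_class = "B",
                       n = c(50, 50))
  cohort <- make_cohort(cohort_spec(counts, duration_s = 60, seed = 21))
  rate <- vapply(cohort, function(lt)
    nrow(lt$truth_events) / trace_duration(lt$trace), 0)
  sex <- vapply(cohort, function(lt) lt$trace$metadata$sex, "")
  expect_equal(mean(rate[sex == "male"]), 0.53, tolerance = 0.2 / 0.53)
  expect_equal(mean(rate[sex == "female"]), 0.70, tolerance = 0.2 / 0.70)
})

test_that("cohort class counts and metadata match the specification", {
  cohort <- make_cohort(published_cohort_spec(seed = 2, duration_s = 60))
  expect_equal(length(cohort), 59L)
  md <- lapply(cohort, function(lt) lt$trace$metadata)
  sex <- vapply(md, `[[`, "", "sex")
  cls <- vapply(md, `[[`, "", "truth_cell_class")
  expect_equal(sum(sex == "male"), 29L)
  expect_equal(sum(sex == "female"), 30L)
  expect_equal(sum(sex == "male" & cls == "A"), 3L)
  expect_equal(sum(sex == "male" & cls == "B"), 25L)
  expect_equal(sum(sex == "female" & cls == "A"), 12L)
  expect_equal(sum(sex == "female" & cls == "B"), 17L)
  expect_equal(sum(cls == "none"), 2L)
  bursting <- vapply(md, `[[`, TRUE, "truth_bursting")
  expect_equal(sum(bursting & sex == "male"), 13L)
  expect_equal(sum(bursting & sex == "female"), 6L)
  caps <- vapply(md, `[[`, 0, "capacitance_pf")
  expect_true(all(caps > 0))
  # empty cohort
  expect_equal(length(make_cohort(cohort_spec(
    data.frame(sex = "male", cell_class = "B", n = 0)))), 0L)
})

test_that("CRH-bursting cohorts contain bursts in every B cell", {
  counts <- data.frame(sex = "female", cell_class = "B", n = 10)
  cohort <- make_cohort(cohort_spec(counts, condition = "crh_bursting",
                                    duration_s = 60, seed = 13))
  for (lt in cohort) {
    expect_equal(lt$truth_cell_class, "B")
    expect_gt(sum(lt$truth_events$class == "burst"), 0)
  }
})
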