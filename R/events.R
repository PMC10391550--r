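#' Construct a membrane-potential trace
#'
#' A trace is a uniformly sampled current-clamp recording of membrane
#' potential, the basic input of the analysis pipeline. Time is implicit:
#' sample `i` is at `(i - 1) / fs_hz` seconds.
#'
#' @param v_mv Numeric vector of membrane potential samples (mV). All values
#'   must be finite.
#' @param fs_hz Sampling rate in samples per second (default 10000, the
#'   standard acquisition rate for these recordings).
#' @param metadata Named list of per-cell metadata. Recognised fields:
#'   `cell_id`, `sex`, `condition`, `capacitance_pf`, `days_in_culture`.
#' @return An object of class `"ctph_trace"`: a list with elements `v_mv`,
#'   `fs_hz`, `metadata`.
#' @examples
#' tr <- voltage_trace(rep(-51, 10000), fs_hz = 10000)
#' trace_duration(tr)
#' @export
voltage_trace <- function(v_mv, fs_hz = 10000, metadata = list()) {
  v_mv <- as.numeric(v_mv)
  if (length(v_mv) < 1) stop("trace must contain at least one sample")
  if (!all(is.finite(v_mv))) stop("trace contains non-finite samples")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0)
    stop("fs_hz must be a positive scalar")
  structure(list(v_mv = v_mv, fs_hz = fs_hz, metadata = metadata),
            class = "ctph_trace")
}

#' @rdname voltage_trace
#' @param x A `ctph_trace`.
#' @export
trace_duration <- function(x) {
  stopifnot(inherits(x, "ctph_trace"))
  length(x$v_mv) / x$fs_hz
}

#' @rdname voltage_trace
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "ctph_trace"))
  (seq_along(x$v_mv) - 1) / x$fs_hz
}

#' @export
print.ctph_trace <- function(x, ...) {
  cat(sprintf("<ctph_trace> %.3f s at %g Hz (%d samples)\n",
              trace_duration(x), x$fs_hz, length(x$v_mv)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Robust baseline (resting) potential of a trace
#'
#' Events (spikes and bursts) contaminate the sample distribution from
#' above, so the baseline is estimated as the median of the samples at or
#' below the trace's 60th percentile. For an event-free trace this is simply
#' a median; for a spiking trace the upper tail carrying the events is
#' excluded before the median is taken.
#'
#' @param x A `ctph_trace` or a numeric vector of samples (mV).
#' @return Baseline membrane potential in mV.
#' @export
estimate_baseline <- function(x) {
  v <- if (inherits(x, "ctph_trace")) x$v_mv else as.numeric(x)
  q <- stats::quantile(v, 0.6, names = FALSE, type = 7)
  stats::median(v[v <= q])
}

#' Detect depolarising events in a trace
#'
#' An event opens when the membrane potential first reaches
#' `baseline + delta_threshold_mv` while the detector is armed, and closes at
#' the next sample falling below `baseline + delta_rearm_mv`, at which point
#' the detector re-arms. Each detected event carries its duration, peak,
#' amplitude (peak minus baseline), spikelet count, and a class label
#' (see [classify_event()]).
#'
#' An excursion still above the re-arm level when the recording ends cannot
#' be assigned a duration and is discarded (the count of such truncated
#' openings is returned as an attribute).
#'
#' @param x A `ctph_trace`.
#' @param delta_threshold_mv Opening threshold above baseline, mV (default 20).
#' @param delta_rearm_mv Re-arm level above baseline, mV (default 5); must be
#'   smaller than `delta_threshold_mv` and positive.
#' @param baseline_mv Baseline override in mV; estimated with
#'   [estimate_baseline()] when `NULL`.
#' @param spikelet_prominence_mv,spikelet_min_sep_ms Spikelet acceptance
#'   parameters passed to [count_spikelets()].
#' @return An object of class `"ctph_events"`: a data.frame with columns
#'   `start_s`, `end_s`, `duration_ms`, `peak_v_mv`, `amplitude_mv`,
#'   `n_spikelets`, `class`, and attributes `baseline_mv`,
#'   `recording_duration_s`, `fs_hz`, `n_truncated`.
#' @export
detect_events <- function(x, delta_threshold_mv = 20, delta_rearm_mv = 5,
                          baseline_mv = NULL,
                          spikelet_prominence_mv = 5,
                          spikelet_min_sep_ms = 2) {
  stopifnot(inherits(x, "ctph_trace"))
  if (length(x$v_mv) < 2) stop("trace shorter than one sample interval")
  if (!(delta_threshold_mv > delta_rearm_mv && delta_rearm_mv > 0))
    stop("need delta_threshold_mv > delta_rearm_mv > 0")
  v <- x$v_mv
  fs <- x$fs_hz
  base <- if (is.null(baseline_mv)) estimate_baseline(x) else baseline_mv
  thr <- base + delta_threshold_mv
  rearm <- base + delta_rearm_mv

  n <- length(v)
  at_thr <- v >= thr
  below_rearm <- v < rearm
  # rising edges into >= thr; falling edges into < rearm
  ups <- which(at_thr & !c(FALSE, at_thr[-n]))
  downs <- which(below_rearm & !c(TRUE, below_rearm[-n]))
  if (below_rearm[1]) downs <- c(1L, downs)

  starts <- integer(0); ends <- integer(0)
  iu <- 1L
  n_trunc <- 0L
  while (iu <= length(ups)) {
    s <- ups[iu]
    e_candidates <- downs[downs > s]
    if (length(e_candidates) == 0L) { n_trunc <- n_trunc + 1L; break }
    e <- e_candidates[1L]
    starts <- c(starts, s); ends <- c(ends, e)
    # skip threshold crossings inside the event just closed
    while (iu <= length(ups) && ups[iu] <= e) iu <- iu + 1L
  }

  m <- length(starts)
  if (m == 0L) {
    ev <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     duration_ms = numeric(0), peak_v_mv = numeric(0),
                     amplitude_mv = numeric(0), n_spikelets = integer(0),
                     class = character(0), stringsAsFactors = FALSE)
  } else {
    peak <- vapply(seq_len(m), function(i) max(v[starts[i]:ends[i]]), 0)
    nsp <- vapply(seq_len(m), function(i) {
      count_spikelets(v[starts[i]:ends[i]], baseline_mv = base, fs_hz = fs,
                      threshold_mv = thr,
                      prominence_mv = spikelet_prominence_mv,
                      min_sep_ms = spikelet_min_sep_ms)
    }, 0L)
    dur_ms <- (ends - starts) / fs * 1000
    ev <- data.frame(
      start_s = (starts - 1) / fs,
      end_s = (ends - 1) / fs,
      duration_ms = dur_ms,
      peak_v_mv = peak,
      amplitude_mv = peak - base,
      n_spikelets = nsp,
      class = vapply(seq_len(m), function(i) classify_event(dur_ms[i], nsp[i]), ""),
      stringsAsFactors = FALSE)
  }
  structure(ev, class = c("ctph_events", "data.frame"),
            baseline_mv = base, recording_duration_s = n / fs,
            fs_hz = fs, n_truncated = n_trunc)
}

#' Count spikelets within an event
#'
#' A spikelet is a local maximum that exceeds the detection threshold and has
#' a topographic prominence of at least `prominence_mv`; accepted spikelets
#' must be separated by at least `min_sep_ms` (when two candidates are
#' closer, the higher one is kept). Small ripples riding on a plateau are
#' thereby ignored while genuine spikelets are counted.
#'
#' @param v Numeric vector of samples spanning the event (mV).
#' @param baseline_mv Baseline of the parent trace (mV).
#' @param fs_hz Sampling rate (Hz).
#' @param threshold_mv Absolute level a spikelet peak must exceed; defaults
#'   to `baseline_mv + 20`.
#' @param prominence_mv Minimum peak prominence (mV, default 5).
#' @param min_sep_ms Minimum separation between accepted spikelets (ms,
#'   default 2).
#' @return Integer spikelet count.
#' @export
count_spikelets <- function(v, baseline_mv, fs_hz,
                            threshold_mv = baseline_mv + 20,
                            prominence_mv = 5, min_sep_ms = 2) {
  n <- length(v)
  if (n < 3) return(if (n > 0 && max(v) >= threshold_mv) 1L else 0L)
  # strict rise on the left, non-strict on the right de-duplicates flat tops
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  peaks <- which(is_peak & v >= threshold_mv)
  if (length(peaks) == 0L) {
    # monotone-edged event (e.g. a clipped triangle): its maximum counts once
    return(if (max(v) >= threshold_mv) 1L else 0L)
  }
  prom <- vapply(peaks, function(p) .peak_prominence(v, p), 0)
  keep <- peaks[prom >= prominence_mv]
  if (length(keep) == 0L)   # smooth hump: ripples ignored, one maximum
    return(if (max(v) >= threshold_mv) 1L else 0L)
  if (length(keep) == 1L) return(1L)
  # enforce separation, keeping higher peaks first
  ord <- keep[order(v[keep], decreasing = TRUE)]
  min_sep <- min_sep_ms / 1000 * fs_hz
  accepted <- integer(0)
  for (p in ord) {
    if (all(abs(accepted - p) >= min_sep)) accepted <- c(accepted, p)
  }
  length(accepted)
}

# topographic prominence of the local maximum at index p
.peak_prominence <- function(v, p) {
  h <- v[p]
  left <- if (p > 1) v[seq_len(p - 1)] else numeric(0)
  right <- if (p < length(v)) v[(p + 1):length(v)] else numeric(0)
  saddle_side <- function(side) {
    higher <- which(side >= h)
    if (length(higher) == 0) return(min(c(side, h)))
    min(side[seq_len(higher[1])])  # min down to the nearest higher ground
  }
  # walk outwards: stop at first sample >= h
  left_s <- if (length(left)) saddle_side(rev(left)) else h
  right_s <- if (length(right)) saddle_side(right) else h
  h - max(left_s, right_s)
}

#' Classify a detected event as spike, burst, or other
#'
#' Events lasting up to 100 ms are spikes. Events longer than 100 ms
#' carrying at least two spikelets are pseudo-plateau bursts. Long events
#' with fewer than two spikelets fall into neither definition and are
#' labelled `"other"`; they count towards total events but never as bursts.
#'
#' @param duration_ms Event duration (ms).
#' @param n_spikelets Spikelet count from [count_spikelets()].
#' @return One of `"spike"`, `"burst"`, `"other"`.
#' @export
classify_event <- function(duration_ms, n_spikelets) {
  if (duration_ms <= 100) "spike"
  else if (n_spikelets >= 2) "burst"
  else "other"
}

#' Shape metrics of a single spike
#'
#' Computes the width at half of the spike's amplitude (peak minus
#' baseline), the time from threshold crossing (event start) to the peak,
#' the peak amplitude, and the afterhyperpolarization (AHP) amplitude: the
#' depth below baseline of the trace minimum within `ahp_window_ms` after
#' the event's closing (re-arm) crossing, floored at zero. Half-height
#' crossing times are linearly interpolated; the search for the rising
#' half-height crossing extends up to 100 ms before the event start since
#' the upstroke begins below the detection threshold.
#'
#' @param x A `ctph_trace`.
#' @param event One row of a `ctph_events` table (class `"spike"`).
#' @param baseline_mv Baseline of the trace (mV).
#' @param ahp_window_ms Post-event window over which the AHP minimum is
#'   sought (ms, default 200).
#' @return A list with `width_ms`, `time_to_peak_ms`, `ahp_amplitude_mv`,
#'   `peak_amplitude_mv`. `ahp_amplitude_mv` is `NA` when the window is
#'   truncated by the end of the recording.
#' @export
spike_shape <- function(x, event, baseline_mv, ahp_window_ms = 200) {
  stopifnot(inherits(x, "ctph_trace"))
  v <- x$v_mv; fs <- x$fs_hz
  s <- round(event$start_s * fs) + 1L
  e <- round(event$end_s * fs) + 1L
  seg <- v[s:e]
  ipk <- which.max(seg)
  peak <- seg[ipk]
  amp <- peak - baseline_mv
  half <- baseline_mv + amp / 2

  # rising half-height crossing: search backwards from the peak
  lo <- max(1L, s - round(0.1 * fs))
  pre <- v[lo:(s + ipk - 1L)]
  t_up <- .last_crossing_up(pre, half) / fs    # samples -> s, relative to lo
  # falling half-height crossing: search forwards from the peak
  hi <- min(length(v), e + round(0.1 * fs))
  post <- v[(s + ipk - 1L):hi]
  t_dn <- .first_crossing_down(post, half) / fs
  width_ms <- if (is.na(t_up) || is.na(t_dn)) NA_real_ else {
    ((s + ipk - 1L - lo) / fs - t_up + t_dn) * 1000
  }

  ttp_ms <- (ipk - 1L) / fs * 1000

  ahp_end <- e + round(ahp_window_ms / 1000 * fs)
  ahp <- if (ahp_end > length(v)) NA_real_ else {
    max(0, baseline_mv - min(v[e:ahp_end]))
  }
  list(width_ms = width_ms, time_to_peak_ms = ttp_ms,
       ahp_amplitude_mv = ahp, peak_amplitude_mv = amp)
}

# interpolated position (in samples, 0-based from vector start) of the last
# upward crossing of `level`; NA if the vector never starts below level
.last_crossing_up <- function(v, level) {
  n <- length(v)
  below <- v < level
  idx <- which(below[-n] & !below[-1])
  if (length(idx) == 0) return(NA_real_)
  i <- idx[length(idx)]
  i - 1 + (level - v[i]) / (v[i + 1] - v[i])
}

.first_crossing_down <- function(v, level) {
  n <- length(v)
  above <- v >= level
  idx <- which(above[-n] & !above[-1])
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  i - 1 + (v[i] - level) / (v[i] - v[i + 1])
}

#' Classify a cell as A- or B-type from its spike AHPs
#'
#' Cells are phenotyped by the mean afterhyperpolarization amplitude of 10
#' consecutive single spikes: a mean AHP above `ahp_a_mv` (default 25 mV)
#' marks an A-type cell, below `ahp_b_mv` (default 20 mV) a B-type cell.
#' Means falling in the intermediate band are labelled `"ambiguous"` rather
#' than force-assigned. With fewer than 10 usable spikes the label is
#' `"none"`.
#'
#' @param shapes A data.frame (or list of lists) of spike shape metrics with
#'   an `ahp_amplitude_mv` column, ordered in time; typically from
#'   [cell_spike_shapes()].
#' @param n_spikes Number of consecutive spikes averaged (default 10).
#' @param ahp_a_mv,ahp_b_mv Classification thresholds (mV).
#' @return A list with `label` (one of `"A"`, `"B"`, `"ambiguous"`,
#'   `"none"`), `mean_ahp_mv`, `n_spikes_used`.
#' @export
classify_cell_ab <- function(shapes, n_spikes = 10, ahp_a_mv = 25, ahp_b_mv = 20) {
  ahp <- if (is.data.frame(shapes)) shapes$ahp_amplitude_mv
         else vapply(shapes, function(s) s$ahp_amplitude_mv, 0)
  ahp <- ahp[!is.na(ahp)]
  if (length(ahp) < n_spikes)
    return(list(label = "none", mean_ahp_mv = NA_real_,
                n_spikes_used = length(ahp)))
  m <- mean(ahp[seq_len(n_spikes)])
  label <- if (m > ahp_a_mv) "A" else if (m < ahp_b_mv) "B" else "ambiguous"
  list(label = label, mean_ahp_mv = m, n_spikes_used = n_spikes)
}

#' Spike shapes of the first run of consecutive single spikes
#'
#' Extracts shape metrics ([spike_shape()]) for the first run of at least
#' `n_spikes` consecutive spike-class events (a burst or other-class event
#' breaks the run). Used to feed [classify_cell_ab()].
#'
#' @param x A `ctph_trace`.
#' @param events A `ctph_events` table from [detect_events()].
#' @param n_spikes Required run length (default 10).
#' @return A data.frame of shape metrics (possibly fewer than `n_spikes`
#'   rows when no qualifying run exists, in which case the longest run of
#'   leading spikes found anywhere is returned).
#' @export
cell_spike_shapes <- function(x, events, n_spikes = 10) {
  base <- attr(events, "baseline_mv")
  cls <- events$class
  runs <- rle(cls == "spike")
  pos <- cumsum(c(1, runs$lengths))
  spike_runs <- which(runs$values)
  pick <- spike_runs[runs$lengths[spike_runs] >= n_spikes]
  idx <- if (length(pick)) {
    seq(pos[pick[1]], length.out = n_spikes)
  } else if (length(spike_runs)) {
    best <- spike_runs[which.max(runs$lengths[spike_runs])]
    seq(pos[best], length.out = runs$lengths[best])
  } else integer(0)
  out <- lapply(idx, function(i) spike_shape(x, events[i, ], base))
  do.call(rbind, lapply(out, function(s) as.data.frame(s)))
}

#' Membrane potential by three-point averaging
#'
#' The resting membrane potential of a recording is estimated by averaging
#' three time points at the beginning, middle, and end of the analysis
#' period. Each "point" is the median of a short window (default 50 ms), so
#' a spike that happens to coincide with a sampling point does not bias the
#' estimate.
#'
#' @param x A `ctph_trace`.
#' @param window_ms Width of each median window (ms, default 50).
#' @return Membrane potential in mV.
#' @export
membrane_potential <- function(x, window_ms = 50) {
  stopifnot(inherits(x, "ctph_trace"))
  v <- x$v_mv
  n <- length(v)
  if (n < 3) stop("trace must have at least 3 samples")
  w <- max(1L, round(window_ms / 1000 * x$fs_hz))
  win_at <- function(center) {
    lo <- max(1L, center - w %/% 2L)
    hi <- min(n, lo + w - 1L)
    stats::median(v[lo:hi])
  }
  mean(c(win_at(1L), win_at((n + 1L) %/% 2L), win_at(n)))
}

#' Burst factor of an event table
#'
#' The proportion of all detected events that are bursts. Undefined (`NA`)
#' for an empty table: a silent cell has no burst factor, which is distinct
#' from a spiking cell that never bursts (burst factor 0).
#'
#' @param events A `ctph_events` table.
#' @return Fraction in `[0, 1]`, or `NA` when there are no events.
#' @export
burst_factor <- function(events) {
  n <- nrow(events)
  if (n == 0) return(NA_real_)
  sum(events$class == "burst") / n
}

#' Twelve-parameter excitability summary of one cell
#'
#' Computes the per-cell parameter set used for cohort comparison and PCA:
#' cell capacitance, membrane potential, event frequency, spike frequency,
#' burst frequency, event duration, spike duration, burst duration, burst
#' factor, active time, event amplitude, and days in culture. Frequencies
#' are counts over the analysis duration; durations are class-wise means;
#' active time is the summed event duration as a fraction of the analysis
#' duration; amplitude is the mean peak excursion above baseline.
#' Class-wise metrics with no qualifying events are `NA`.
#'
#' @param x A `ctph_trace`.
#' @param events A `ctph_events` table from [detect_events()] on `x`.
#' @param metadata Optional metadata override (defaults to the trace's);
#'   `capacitance_pf` and `days_in_culture` are taken from here.
#' @param analysis_window_s Analysis duration in seconds (defaults to the
#'   full recording); must not exceed the recording.
#' @return A one-row data.frame with the 12 parameters plus `cell_id`,
#'   `sex`, `condition` when present in the metadata.
#' @export
summarize_cell <- function(x, events, metadata = NULL, analysis_window_s = NULL) {
  stopifnot(inherits(x, "ctph_trace"), inherits(events, "ctph_events"))
  md <- if (is.null(metadata)) x$metadata else metadata
  dur <- attr(events, "recording_duration_s")
  if (is.null(analysis_window_s)) analysis_window_s <- dur
  if (analysis_window_s > dur + 1e-9)
    stop("analysis window longer than the recording")
  T <- analysis_window_s
  n_ev <- nrow(events)
  n_sp <- sum(events$class == "spike")
  n_bu <- sum(events$class == "burst")
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  out <- data.frame(
    capacitance_pf = if (!is.null(md$capacitance_pf)) md$capacitance_pf else NA_real_,
    membrane_potential_mv = membrane_potential(x),
    event_freq_hz = n_ev / T,
    spike_freq_hz = n_sp / T,
    burst_freq_hz = n_bu / T,
    event_duration_ms = mean_or_na(events$duration_ms),
    spike_duration_ms = mean_or_na(events$duration_ms[events$class == "spike"]),
    burst_duration_ms = mean_or_na(events$duration_ms[events$class == "burst"]),
    burst_factor = burst_factor(events),
    active_time_frac = sum(events$duration_ms) / 1000 / T,
    event_amplitude_mv = mean_or_na(events$amplitude_mv),
    days_in_culture = if (!is.null(md$days_in_culture)) md$days_in_culture else NA_real_,
    stringsAsFactors = FALSE)
  for (f in c("cell_id", "sex", "condition"))
    if (!is.null(md[[f]])) out[[f]] <- md[[f]]
  out
}
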