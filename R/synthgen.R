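#' Specification of a synthetic voltage trace
#'
#' Defines the statistical structure of a generated current-clamp
#' recording: a renewal process of events (single spikes and/or
#' pseudo-plateau bursts) riding on a flat resting potential, plus
#' Gaussian noise low-pass filtered to emulate acquisition filtering.
#' Defaults emulate the recording conditions of these cells: 10 kHz
#' sampling, 2 kHz low-pass character, resting potential near -51 mV, and
#' low-frequency firing.
#'
#' @param duration_s Recording duration (s); must be positive.
#' @param fs_hz Sampling rate (Hz, default 10000); must exceed twice
#'   `lowpass_hz`.
#' @param baseline_mv Resting potential (mV, default -51.4).
#' @param noise_sd_mv Standard deviation of the white noise before
#'   filtering (mV, default 0.8).
#' @param lowpass_hz Corner of the 4-pole low-pass noise filter (Hz,
#'   default 2000).
#' @param event_rate_hz Mean event rate (events/s); 0 gives a silent trace.
#' @param spike_kind `"A"` or `"B"` single-spike waveform.
#' @param burst_fraction Probability that an event is a burst, in `[0, 1]`.
#' @param burst_duration_ms Plateau duration of burst events (ms).
#' @param spikelets_per_burst Spikelets riding on each burst (>= 2).
#' @param seed Integer seed; identical specs and seeds give bit-identical
#'   traces.
#' @param burst_policy `"bernoulli"` draws each event's class
#'   independently; `"late"` restricts bursts to events after the first 12
#'   (so every cell exposes a run of single spikes for phenotyping).
#' @param ensure_burst Force at least one burst when `burst_fraction > 0`
#'   and events exist (used by cohort generation).
#' @return A list of class `"ctph_trace_spec"`.
#' @export
trace_spec <- function(duration_s, fs_hz = 10000, baseline_mv = -51.4,
                       noise_sd_mv = 0.8, lowpass_hz = 2000,
                       event_rate_hz = 0.5, spike_kind = c("B", "A"),
                       burst_fraction = 0, burst_duration_ms = 180,
                       spikelets_per_burst = 3, seed = 1,
                       burst_policy = c("bernoulli", "late"),
                       ensure_burst = FALSE) {
  spike_kind <- match.arg(spike_kind)
  burst_policy <- match.arg(burst_policy)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs_hz <= 2 * lowpass_hz)
    stop("fs_hz must exceed twice lowpass_hz")
  if (burst_fraction < 0 || burst_fraction > 1)
    stop("burst_fraction must be in [0, 1]")
  if (event_rate_hz < 0) stop("event_rate_hz must be non-negative")
  if (noise_sd_mv < 0) stop("noise_sd_mv must be non-negative")
  if (spikelets_per_burst < 2) stop("spikelets_per_burst must be >= 2")
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 baseline_mv = baseline_mv, noise_sd_mv = noise_sd_mv,
                 lowpass_hz = lowpass_hz, event_rate_hz = event_rate_hz,
                 spike_kind = spike_kind, burst_fraction = burst_fraction,
                 burst_duration_ms = burst_duration_ms,
                 spikelets_per_burst = spikelets_per_burst, seed = seed,
                 burst_policy = burst_policy, ensure_burst = ensure_burst),
            class = "ctph_trace_spec")
}

#' Single-spike waveform template
#'
#' Piecewise-exponential action-potential template, in mV relative to
#' baseline: an exponential-saturating rise to the peak, then a
#' double-exponential decay whose undershoot is solved (by root finding)
#' to reach exactly the requested afterhyperpolarization depth, recovering
#' to within 1 mV of baseline at the template's end.
#'
#' A-kind templates have a sharp upstroke, short width, and a large AHP
#' (depth at least 25 mV); B-kind templates rise more slowly, are wider,
#' and have a small AHP (depth at most 20 mV).
#'
#' @param kind `"A"` or `"B"`.
#' @param fs_hz Sampling rate (Hz).
#' @param amp_mv Peak excursion above baseline (mV); must exceed 20 so the
#'   detection threshold is crossed.
#' @param t_peak_ms Time from template onset to peak (ms).
#' @param decay_ms Repolarization time constant (ms).
#' @param ahp_mv AHP depth below baseline (mV).
#' @param ahp_tau_ms AHP recovery time constant (ms).
#' @return Numeric waveform (mV relative to baseline) with attributes
#'   `on_idx`/`off_idx`: the 1-based sample indices where the waveform
#'   first reaches +20 mV and first falls back below +5 mV (the detection
#'   geometry of the template).
#' @export
spike_template <- function(kind = c("A", "B"), fs_hz = 10000,
                           amp_mv = NULL, t_peak_ms = NULL, decay_ms = NULL,
                           ahp_mv = NULL, ahp_tau_ms = NULL) {
  kind <- match.arg(kind)
  d <- if (kind == "A")
    list(amp = 36, t_peak = 8, decay = 6, ahp = 28, ahp_tau = 30)
  else
    list(amp = 32, t_peak = 20, decay = 14, ahp = 12, ahp_tau = 40)
  amp <- if (is.null(amp_mv)) d$amp else amp_mv
  t_peak <- if (is.null(t_peak_ms)) d$t_peak else t_peak_ms
  decay <- if (is.null(decay_ms)) d$decay else decay_ms
  ahp <- if (is.null(ahp_mv)) d$ahp else ahp_mv
  ahp_tau <- if (is.null(ahp_tau_ms)) d$ahp_tau else ahp_tau_ms
  if (amp <= 20) stop("template peak must exceed 20 mV above baseline")

  dt <- 1000 / fs_hz  # ms per sample
  t_rise <- seq(0, t_peak, by = dt)
  rise <- amp * (1 - exp(-3 * t_rise / t_peak)) / (1 - exp(-3))

  # post-peak: v(s) = (amp + a2) exp(-s/decay) - a2 exp(-s/ahp_tau);
  # a2 is solved so the minimum equals -ahp
  s <- seq(dt, 6 * ahp_tau + 4 * decay, by = dt)
  depth <- function(a2) min((amp + a2) * exp(-s / decay) - a2 * exp(-s / ahp_tau))
  a2 <- stats::uniroot(function(a2) depth(a2) + ahp,
                       lower = 1e-6, upper = 50 * (ahp + amp))$root
  tail_v <- (amp + a2) * exp(-s / decay) - a2 * exp(-s / ahp_tau)
  # truncate once recovered to within 1 mV of baseline after the minimum
  imin <- which.min(tail_v)
  rec <- which(abs(tail_v) < 0.8)
  rec <- rec[rec > imin]
  if (length(rec)) tail_v <- tail_v[seq_len(rec[1])]
  w <- c(rise, tail_v)
  attr(w, "on_idx") <- which(w >= 20)[1]
  off <- which(seq_along(w) > which.max(w) & w < 5)[1]
  attr(w, "off_idx") <- off
  attr(w, "kind") <- kind
  w
}

#' Pseudo-plateau burst waveform template
#'
#' A depolarized plateau carrying evenly spaced raised-cosine spikelets,
#' with smooth onset/offset ramps and a small afterhyperpolarization. The
#' plateau sits above the re-arm level and below the detection threshold;
#' spikelet peaks exceed the threshold with ample prominence, so the event
#' is detected as one long burst with the requested spikelet count.
#'
#' @param fs_hz Sampling rate (Hz).
#' @param duration_ms Plateau duration (ms); must exceed 100 for the event
#'   to classify as a burst.
#' @param n_spikelets Number of spikelets (>= 2).
#' @param plateau_mv Plateau height above baseline (mV, default 22).
#' @param spikelet_amp_mv Spikelet height above the plateau (mV, default 8).
#' @param ahp_mv Post-burst AHP depth (mV, default 6).
#' @param ahp_tau_ms AHP recovery time constant (ms, default 40).
#' @return Numeric waveform with `on_idx`/`off_idx` attributes as in
#'   [spike_template()].
#' @export
burst_template <- function(fs_hz = 10000, duration_ms = 180, n_spikelets = 3,
                           plateau_mv = 22, spikelet_amp_mv = 8,
                           ahp_mv = 6, ahp_tau_ms = 40) {
  if (n_spikelets < 2) stop("a burst carries at least 2 spikelets")
  if (duration_ms <= 100)
    stop("burst plateau must exceed 100 ms to classify as a burst")
  dt <- 1000 / fs_hz
  rise_ms <- 6; fall_ms <- 8
  rise <- plateau_mv * (1 - cos(pi * seq(0, rise_ms, by = dt) / rise_ms)) / 2
  tp <- seq(dt, duration_ms, by = dt)
  plateau <- rep(plateau_mv, length(tp))
  spacing <- duration_ms / n_spikelets
  centers <- spacing * (seq_len(n_spikelets) - 0.5)
  w_sp <- min(18, spacing * 0.6)   # spikelet width (ms)
  for (ct in centers) {
    in_sp <- abs(tp - ct) <= w_sp / 2
    plateau[in_sp] <- plateau_mv +
      spikelet_amp_mv * (1 + cos(2 * pi * (tp[in_sp] - ct) / w_sp)) / 2
  }
  fall_t <- seq(dt, fall_ms, by = dt)
  fall <- -ahp_mv + (plateau_mv + ahp_mv) * (1 + cos(pi * fall_t / fall_ms)) / 2
  rec_t <- seq(dt, 6 * ahp_tau_ms, by = dt)
  rec <- -ahp_mv * exp(-rec_t / ahp_tau_ms)
  rec <- rec[seq_len(which(abs(rec) < 0.8)[1])]
  w <- c(rise, plateau, fall, rec)
  attr(w, "on_idx") <- which(w >= 20)[1]
  off <- which(seq_along(w) > attr(w, "on_idx") & w < 5)[1]
  attr(w, "off_idx") <- off
  attr(w, "n_spikelets") <- n_spikelets
  w
}

# run code with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one labelled synthetic trace
#'
#' Events are placed by a Poisson renewal process at the requested mean
#' rate with a hard refractory gap equal to the longest template, so events
#' never overlap (the exponential inter-event rate is adjusted so the
#' realized rate matches `event_rate_hz`). Each event is a burst with
#' probability `burst_fraction`, otherwise a single spike of `spike_kind`.
#' White Gaussian noise of sd `noise_sd_mv`, low-pass filtered by a 4-pole
#' Butterworth filter at `lowpass_hz`, is added after event placement.
#' Ground-truth event times (threshold-crossing geometry of the clean
#' templates), classes, and spikelet counts are recorded exactly.
#'
#' @param spec A `"ctph_trace_spec"`.
#' @param metadata Optional metadata list stored in the trace.
#' @return A `"ctph_labeled_trace"`: list with `trace` (a [trace()]),
#'   `truth_events` (data.frame `start_s`, `end_s`, `class`,
#'   `n_spikelets`), and `truth_cell_class` (`"A"`, `"B"`, or `"none"`).
#' @export
make_trace <- function(spec, metadata = list()) {
  stopifnot(inherits(spec, "ctph_trace_spec"))
  fs <- spec$fs_hz
  n <- round(spec$duration_s * fs)
  sp_t <- spike_template(spec$spike_kind, fs)
  bu_t <- if (spec$burst_fraction > 0 || spec$ensure_burst)
    burst_template(fs, spec$burst_duration_ms, spec$spikelets_per_burst)
  else NULL
  refr_samp <- max(length(sp_t), length(bu_t))
  refr_s <- refr_samp / fs
  if (spec$event_rate_hz > 0 && spec$event_rate_hz * refr_s >= 1)
    stop(sprintf(paste0("event_rate_hz = %g is too high: the refractory gap ",
                        "(%.2f s, the longest template) already fills the ",
                        "mean inter-event interval"),
                 spec$event_rate_hz, refr_s))

  .with_seed(spec$seed, {
    starts <- numeric(0)
    if (spec$event_rate_hz > 0) {
      lambda <- 1 / (1 / spec$event_rate_hz - refr_s)
      t <- stats::rexp(1, lambda)
      while (t + refr_s < spec$duration_s - 0.01) {
        starts <- c(starts, t)
        t <- t + refr_s + stats::rexp(1, lambda)
      }
    }
    m <- length(starts)
    is_burst <- if (m == 0) logical(0)
      else if (spec$burst_policy == "bernoulli")
        stats::runif(m) < spec$burst_fraction
      else {  # "late": keep the first 12 events as single spikes
        ib <- stats::runif(m) < spec$burst_fraction
        ib[seq_len(min(m, 12L))] <- FALSE
        ib
      }
    if (spec$ensure_burst && m > 0 && spec$burst_fraction > 0 && !any(is_burst))
      is_burst[m] <- TRUE

    v <- rep(0, n)
    truth <- vector("list", m)
    for (i in seq_len(m)) {
      tmpl <- if (is_burst[i]) bu_t else sp_t
      i0 <- round(starts[i] * fs) + 1L
      i1 <- min(n, i0 + length(tmpl) - 1L)
      v[i0:i1] <- v[i0:i1] + tmpl[seq_len(i1 - i0 + 1L)]
      truth[[i]] <- data.frame(
        start_s = (i0 + attr(tmpl, "on_idx") - 2L) / fs,
        end_s = (i0 + attr(tmpl, "off_idx") - 2L) / fs,
        class = if (is_burst[i]) "burst" else "spike",
        n_spikelets = if (is_burst[i]) spec$spikelets_per_burst else 1L,
        stringsAsFactors = FALSE)
    }
    if (spec$noise_sd_mv > 0) {
      noise <- stats::rnorm(n, 0, spec$noise_sd_mv)
      bf <- signal::butter(4, spec$lowpass_hz / (fs / 2), type = "low")
      noise <- as.numeric(signal::filter(bf, noise))
      v <- v + noise
    }
    v <- v + spec$baseline_mv

    truth_df <- if (m) do.call(rbind, truth) else
      data.frame(start_s = numeric(0), end_s = numeric(0),
                 class = character(0), n_spikelets = integer(0),
                 stringsAsFactors = FALSE)
    structure(list(
      trace = voltage_trace(v, fs, metadata = c(metadata, list(fs_hz = fs, seed = spec$seed))),
      truth_events = truth_df,
      truth_cell_class = if (spec$event_rate_hz == 0) "none" else spec$spike_kind),
      class = "ctph_labeled_trace")
  })
}

#' @export
print.ctph_labeled_trace <- function(x, ...) {
  cat(sprintf("<ctph_labeled_trace> class %s, %d truth events, %.1f s\n",
              x$truth_cell_class, nrow(x$truth_events),
              trace_duration(x$trace)))
  invisible(x)
}

#' Specification of a synthetic cohort
#'
#' Per-cell counts by sex and truth class, a recording condition, and the
#' number of cells per sex that show spontaneous bursting. Basal event
#' rates default to the sex-specific means observed in these cells
#' (0.53 Hz male, 0.70 Hz female); capacitance is drawn from the reported
#' sex-specific normals (4.41 +/- 1.7 pF male, 4.91 +/- 2.1 pF female).
#'
#' @param counts data.frame with columns `sex` (`"male"`/`"female"`),
#'   `cell_class` (`"A"`, `"B"`, `"none"`), `n` (non-negative integers).
#' @param condition One of `"basal"`, `"crh"` (A-type cells respond with
#'   faster spiking, B-type with pseudo-plateau bursting), `"crh_spiking"`,
#'   `"crh_bursting"`, `"crh_bk"` (bursting with added BK conductance,
#'   higher burst fraction).
#' @param duration_s Per-cell recording duration (s, default 90).
#' @param n_bursting Named vector: number of cells per sex with spontaneous
#'   basal bursting (subset of B-type cells).
#' @param rate_by_sex Named vector of basal mean event rates (Hz).
#' @param rate_cv Per-cell gamma variability of the event rate
#'   (coefficient of variation, mean-preserving; default 0.3).
#' @param seed Integer seed.
#' @return A list of class `"ctph_cohort_spec"`.
#' @export
cohort_spec <- function(counts, condition = c("basal", "crh", "crh_spiking",
                                              "crh_bursting", "crh_bk"),
                        duration_s = 90,
                        n_bursting = c(male = 0, female = 0),
                        rate_by_sex = c(male = 0.53, female = 0.70),
                        rate_cv = 0.3, seed = 1) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(counts),
            all(c("sex", "cell_class", "n") %in% names(counts)))
  if (any(counts$n < 0)) stop("all counts must be non-negative")
  if (!all(counts$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (!all(counts$cell_class %in% c("A", "B", "none")))
    stop("cell_class must be 'A', 'B', or 'none'")
  for (s in names(n_bursting)) {
    nb <- sum(counts$n[counts$sex == s & counts$cell_class == "B"])
    if (n_bursting[[s]] > nb)
      stop("n_bursting for ", s, " exceeds the number of B-type cells")
  }
  structure(list(counts = counts, condition = condition,
                 duration_s = duration_s, n_bursting = n_bursting,
                 rate_by_sex = rate_by_sex, rate_cv = rate_cv, seed = seed),
            class = "ctph_cohort_spec")
}

#' Cohort specification mirroring the studied cohort
#'
#' 29 male cells (3 A-type, 25 B-type, 1 neither) and 30 female cells
#' (12 A-type, 17 B-type, 1 neither), with spontaneous basal bursting in
#' 13 male and 6 female cells.
#'
#' @param condition,seed,duration_s Passed to [cohort_spec()].
#' @return A `"ctph_cohort_spec"`.
#' @export
published_cohort_spec <- function(condition = "basal", seed = 1, duration_s = 90) {
  counts <- data.frame(
    sex = rep(c("male", "female"), each = 3),
    cell_class = rep(c("A", "B", "none"), 2),
    n = c(3, 25, 1, 12, 17, 1),
    stringsAsFactors = FALSE)
  cohort_spec(counts, condition = condition, duration_s = duration_s,
              n_bursting = c(male = 13, female = 6), seed = seed)
}

# per-condition generation parameters for one cell
.condition_spec <- function(condition, cell_class, sex, rate_basal, bursting) {
  base <- list(rate = rate_basal, burst_fraction = 0, burst_duration = 180,
               baseline_shift = 0, policy = "bernoulli", ensure = FALSE)
  if (condition == "basal") {
    if (bursting) {
      base$burst_fraction <- 0.08
      base$policy <- "late"; base$ensure <- TRUE
    }
  } else {
    eff <- condition
    if (condition == "crh")   # mixed response: by basal spike phenotype
      eff <- if (cell_class == "A") "crh_spiking" else "crh_bursting"
    if (cell_class == "none") eff <- "silent"
    base$baseline_shift <- 4
    if (eff == "crh_spiking") {
      base$rate <- 2.5
    } else if (eff == "crh_bursting") {
      base$rate <- 0.8; base$burst_fraction <- 0.73
      base$burst_duration <- 450; base$ensure <- TRUE
    } else if (eff == "crh_bk") {
      base$rate <- 0.8; base$burst_fraction <- 0.85
      base$burst_duration <- 550; base$ensure <- TRUE
    } else base$rate <- 0
  }
  base
}

#' Generate a labelled synthetic cohort
#'
#' One labelled trace per cell, with class counts exactly matching the
#' specification. Per-cell metadata carries the cell id, sex, condition,
#' capacitance (sex-specific normal draw, truncated at 0.5 pF), and days
#' in culture (1--4). Cells of class A or B are guaranteed at least 13
#' events (low-rate draws are re-generated with a derived sub-seed), so
#' every classifiable cell exposes a run of 10 consecutive single spikes.
#'
#' @param spec A `"ctph_cohort_spec"`.
#' @return A list of `"ctph_labeled_trace"` objects; each trace's metadata
#'   includes `truth_cell_class` and `truth_bursting`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "ctph_cohort_spec"))
  cells <- list()
  counts <- spec$counts[spec$counts$n > 0, , drop = FALSE]
  plan <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
    data.frame(sex = counts$sex[i], cell_class = counts$cell_class[i],
               idx = seq_len(counts$n[i]), stringsAsFactors = FALSE)))
  if (is.null(plan) || nrow(plan) == 0) return(list())

  .with_seed(spec$seed, {
    # mark which B-type cells burst spontaneously
    plan$bursting <- FALSE
    for (s in unique(plan$sex)) {
      nb <- if (s %in% names(spec$n_bursting)) spec$n_bursting[[s]] else 0
      bi <- which(plan$sex == s & plan$cell_class == "B")
      if (nb > 0) plan$bursting[sample(bi, nb)] <- TRUE
    }
    cell_seeds <- sample.int(2^31 - 2, nrow(plan))

    for (i in seq_len(nrow(plan))) {
      sex <- plan$sex[i]; klass <- plan$cell_class[i]
      cap_mu <- if (sex == "male") 4.41 else 4.91
      cap_sd <- if (sex == "male") 1.7 else 2.1
      cap <- stats::rnorm(1, cap_mu, cap_sd)
      while (cap < 0.5) cap <- stats::rnorm(1, cap_mu, cap_sd)
      dic <- sample(1:4, 1)
      rate0 <- spec$rate_by_sex[[sex]]
      if (spec$rate_cv > 0 && klass != "none") {
        shp <- 1 / spec$rate_cv^2
        rate0 <- stats::rgamma(1, shape = shp, rate = shp / rate0)
      }
      cs <- .condition_spec(spec$condition, klass, sex, rate0, plan$bursting[i])
      md <- list(cell_id = sprintf("%s_%s_%02d", substr(sex, 1, 1), klass,
                                   plan$idx[i]),
                 sex = sex, condition = spec$condition,
                 capacitance_pf = cap, days_in_culture = dic,
                 truth_cell_class = klass, truth_bursting = plan$bursting[i])
      sub_seed <- cell_seeds[i]
      for (try in 1:25) {
        ts <- trace_spec(
          duration_s = spec$duration_s,
          baseline_mv = -51.4 + stats::rnorm(1, 0, 2),
          event_rate_hz = if (klass == "none") 0 else cs$rate,
          spike_kind = if (klass == "A") "A" else "B",
          burst_fraction = cs$burst_fraction,
          burst_duration_ms = cs$burst_duration,
          seed = sub_seed, burst_policy = cs$policy,
          ensure_burst = cs$ensure)
        ts$baseline_mv <- ts$baseline_mv + cs$baseline_shift
        lt <- make_trace(ts, metadata = md)
        enough <- klass == "none" || nrow(lt$truth_events) >= 13
        if (enough) break
        sub_seed <- (sub_seed + 7919L) %% (2^31 - 2) + 1L
      }
      lt$truth_cell_class <- klass
      cells[[length(cells) + 1L]] <- lt
    }
    cells
  })
}
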