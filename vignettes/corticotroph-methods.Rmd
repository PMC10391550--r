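---
title: "Quantifying corticotroph excitability: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying corticotroph excitability: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Anterior-pituitary corticotrophs are electrically excitable endocrine cells.
Under basal conditions they fire low-frequency (roughly 0.5 Hz) single-spike
action potentials; secretagogues such as CRH can switch them to
*pseudo-plateau bursting* — long (>100 ms) depolarized events carrying small
spikelets — a firing mode linked to more efficient hormone secretion.
Individual cells fall into two phenotypes by the depth of the
afterhyperpolarization (AHP) that follows each spike: A-type cells have a
large AHP (>25 mV below baseline) and B-type cells a small one (<20 mV), and
the two phenotypes respond differently to CRH. Male and female cohorts
differ in the proportions of A- and B-type cells, and the BK
(large-conductance Ca- and voltage-activated K) channel is implicated in the
transition to bursting: adding a BK conductance to a cell with a dynamic
clamp can restore bursting where it is absent.

This package implements the full quantification pipeline for such
recordings — event detection, spike/burst classification, A/B phenotyping,
per-cell parameter summaries, correlation-filtered PCA, and exact cohort
statistics — together with a minimal model corticotroph and a software BK
dynamic clamp, and a synthetic-trace generator that makes every stage
testable without access to raw recordings.

## Event detection and classification

A recording is a uniformly sampled membrane-potential trace (10 kHz by
default, consistent with acquisition at 10 kHz filtered at 2 kHz). The
baseline (resting) potential is never given explicitly, so
`estimate_baseline()` uses the median of the samples at or below the 60th
percentile: events occupy the upper tail of the sample distribution, and
this trims them before taking a median. On a flat or noise-only trace the
estimator reduces to (approximately) the median.

`detect_events()` implements a threshold/re-arm detector: an event opens at
the first sample reaching **baseline + 20 mV** and closes at the next sample
falling below **baseline + 5 mV**, after which the detector re-arms. Events
are classified by `classify_event()`:

* duration ≤ 100 ms → **spike** (the boundary case goes to the spike class;
  bursts must strictly exceed 100 ms),
* duration > 100 ms with ≥ 2 spikelets → **burst**,
* duration > 100 ms with < 2 spikelets → **other** — this case is not
  covered by the spike/burst definitions; such events count toward total
  events but never as bursts.

A *spikelet* is not defined operationally in the source conventions, so the
package adopts: a local maximum above the detection threshold with
topographic prominence ≥ 5 mV, at least 2 ms from the nearest accepted
spikelet. The prominence criterion ignores sub-millivolt ripples on a
plateau while counting genuine spikelet oscillations; an event whose
maximum crosses threshold but has no prominent peak counts as one smooth
hump. An excursion still above the re-arm level at the end of the recording
has no measurable duration and is dropped (counted in an attribute).

Spike shape metrics (`spike_shape()`): width at half of the peak-minus-
baseline amplitude with linearly interpolated crossings; time from the
threshold crossing to the peak; AHP amplitude as baseline minus the trace
minimum within **200 ms** after the event's closing crossing, floored at 0
and flagged missing when the window is truncated. The 200 ms window is a
package decision — long enough to capture slow AHP troughs at these firing
rates, short enough not to overlap the next event at basal rates. AHP is
measured relative to baseline (measuring relative to threshold would be the
other defensible reading; both class thresholds are arguments).

A/B phenotyping (`classify_cell_ab()`) averages the AHP of the **first run
of 10 consecutive single spikes** (a burst breaks the run): mean AHP > 25 mV
→ A; < 20 mV → B; values in [20, 25] are labelled *ambiguous* rather than
force-assigned, since the phenotype definitions are stated as typical
ranges; fewer than 10 usable spikes → *none*.

The per-cell summary (`summarize_cell()`) computes the 12 parameters used
for cohort comparison: capacitance, membrane potential, event/spike/burst
frequency, event/spike/burst duration, burst factor, active time, event
amplitude, and days in culture. Membrane potential is the mean of three
50 ms median windows at the start, middle, and end of the analysis period
(medians make the three-point estimator robust to a spike landing on a
sampling point). Burst factor is the proportion of events that are bursts
and is *missing*, not zero, for a silent cell. Active time is the summed
event duration divided by the analysis duration — one reasonable reading of
a quantity whose exact definition is not stated.

## Feature analysis

`feature_matrix()` assembles summaries into a cells × 12 matrix. Class-wise
metrics of cells lacking that class (e.g. burst duration of a never-bursting
cell) are imputed as 0; silent cells have no defined durations and are
dropped with a warning. Event frequency and event duration are
log-transformed before inference (`transform_features()`); columns
containing zeros use `log(x + eps)` with `eps` = half the smallest positive
value, recorded in the output.

`correlation_filter()` removes highly correlated features (|r| ≥ 0.8)
greedily: repeatedly drop the feature with the largest mean absolute
correlation among its offending pairs. The greedy rule is one concrete
choice for a step usually described only by its outcome; a `force_remove`
argument reproduces an explicit published removal set (active time, burst
factor, event frequency, event duration) verbatim.

`run_pca()` standardizes columns to unit variance — the features carry
incommensurate units (pF, mV, Hz, ms) — and uses `stats::prcomp`. Whether
to standardize is genuinely open; unit variance is the defensible default
when units differ. Each component is flipped so its largest-magnitude
loading is positive, a deterministic sign convention that makes loadings
and scores reproducible across platforms. Basal and stimulated states are
fitted jointly (both states are displayed on one plane) and
`trajectories()` reports each cell's displacement; `project_pca()` supports
the alternative basal-fit projection mode.

## Statistics

`fisher_exact_2x2()` implements the two-sided Fisher exact test with the
minimum-likelihood rule: sum the hypergeometric probabilities of all tables
(with the observed margins) whose likelihood does not exceed the observed
table's, computed in log space with a relative tolerance of 1e-7 for ties.
This matches the convention of the standard statistical environments, and
the test suite cross-checks it against full enumeration and against
`stats::fisher.test`. Spike-type proportions are compared on the 2×2
A-vs-B table excluding cells that are neither.

`welch_t()` is the unequal-variance t-test with Welch–Satterthwaite degrees
of freedom, accepting raw samples or summary statistics (the two paths
agree to machine precision). `cohort_compare()` ties these together:
Fisher tests on phenotype and bursting counts, Welch tests on the named
continuous metrics with declared log-transforms applied first. Linear and
mixed-effect modelling with post-hoc contrasts is out of scope: those are
off-the-shelf procedures (`lm`, `nlme`/`lme4`, `multcomp`) with nothing
bespoke to implement.

## The model corticotroph

No measured parameter set exists for a corticotroph model in this setting,
so the model is a deliberately minimal three-variable pituitary-type cell
— the smallest system that both spikes tonically and shows BK-dependent
pseudo-plateau bursting:

$$C\,\dot V = -\big[g_{Ca}m_\infty(V)(V-V_{Ca}) + g_K n (V-V_K) +
  g_A a_\infty(V)h(V-V_K) + g_L(V-V_L)\big] + I_{app} + I_{inject} + \eta$$

with logistic steady states, first-order kinetics for $n$ (delayed
rectifier) and $h$ (A-current inactivation), and Ornstein–Uhlenbeck current
noise $\eta$ (10 ms correlation time) producing irregular firing. Units are
nS·mV = pA and pA/pF = mV/ms, so no conversion constants appear. The
reference integrator is fixed-step forward Euler (Euler–Maruyama for the
noise) at ≤ 0.1 ms, mirroring the real-time method a hardware clamp uses;
the suite checks that halving the step changes a noise-free spike count by
at most one.

**Calibration targets** (all parameter values are package calibrations, not
measurements): the B-like preset rests near −53 mV, fires noise-driven
single spikes at 0.2–1 Hz, and has a shallow (≈10 mV) AHP; a CRH-like
stimulus (`crh_stimulus()`, +2.75 pA at level 1) depolarizes the three-point
membrane potential by 3–6 mV and raises the event rate several-fold; and
with the BK clamp attached under CRH the cell transitions to pseudo-plateau
bursting, with burst factor rising monotonically over $g_{BK}$ = 0–2 nS.
The parameters were chosen with a fixed-point and eigenvalue analysis of
the depolarized state: regimes exist in which strong BK stabilizes a
depolarized focus and the cell sticks on a permanent plateau, and the
shipped preset sits well away from that boundary so the burst-rescue
behaviour is reproducible across seeds. CRH is implemented as an
applied-current increase only; variants that also reduced a potassium or
leak conductance moved the cell toward the stuck-plateau boundary and were
rejected.

The A-like preset uses a stronger delayed rectifier with a deeper K
reversal (−95 mV) plus a small A-type conductance, giving a deeper AHP than
the B preset and — its defining property — resistance to BK-induced
bursting: under CRH with $g_{BK}$ = 1 nS its burst factor stays at zero
where the B preset's rises. Its absolute AHP (≈14 mV) does not reach the
25 mV A-classification threshold; recovering that threshold is the job of
the synthetic-trace generator, where AHP depth is directly controlled. This
is a known limitation of the minimal model, recorded here deliberately.

## The BK dynamic clamp

The clamp computes, at every step: steady-state activation
$f_\infty(V) = [1+\exp((v_f-V)/s_f)]^{-1}$, one forward-Euler step of
$\tau_{BK}\dot f = f_\infty(V) - f$, and the injected current
$I_{BK} = g_{BK} f (V_K - V)$. Defaults are $g_{BK}$ = 1 nS (typical range
0.5–2), $v_f$ = −10 mV, $s_f$ = 2 mV, $\tau_{BK}$ = 2 ms, step 21 µs
(maximum 100 µs enforced). Design notes:

* $V_K$ for the clamp is not specified by the hardware convention this
  mirrors; −75 mV (a standard K reversal for these solutions) is the
  default and it is an ordinary parameter.
* $\tau_{BK}$ appears ambiguously in places ("2 m"); 2 ms is adopted, the
  value consistent with fast BK activation.
* A hardware clamp uses a variable step averaging 21 µs; the software clamp
  uses a *fixed* 21 µs step because fixed steps are deterministic and
  testable. With $g_{BK}=0$ the closed-loop run is bit-identical to the
  unclamped simulation.
* $f$ is clipped to [0, 1] after each step, guarding against overshoot at
  the stability boundary; steps above $\tau_{BK}$ are rejected outright.

The Euler update is verified against the closed form
$f_\infty(1-e^{-t/\tau})$ at fixed voltage (error < 1% at 0.02 ms steps,
first-order convergence as the step is halved).

## The synthetic-trace generator

`make_trace()` builds labelled recordings from templates: events are placed
by a Poisson renewal process with a hard refractory gap equal to the longest
template (so events never overlap; the exponential rate is adjusted so the
realized rate matches the requested one), each event is a burst with a
specified probability, and white Gaussian noise filtered by a 4-pole
Butterworth low-pass at 2 kHz (emulating acquisition filtering; default sd
0.8 mV before filtering — noise amplitude is not a reported quantity, this
is a calibration knob) is added afterwards. Spike templates are
piecewise-exponential with controllable time-to-peak, width, and AHP depth;
the A template is sharp with a 28 mV AHP, the B template slower with a
12 mV AHP, so generated cells never fall in the ambiguous 20–25 mV band
and classifier tests are unambiguous (the depths are arguments when
robustness testing wants the band occupied). Burst templates are a 22 mV
plateau carrying raised-cosine spikelets that peak above the detection
threshold with ≈8 mV prominence. Ground-truth event times are the
threshold-crossing geometry of the clean templates, recorded exactly.

`make_cohort()` generates labelled cohorts with exact per-(sex, phenotype)
counts; capacitance is drawn from the sex-specific normals (4.41 ± 1.7 pF
male, 4.91 ± 2.1 pF female) and basal rates default to the sex-specific
means (0.53 / 0.70 Hz) with mean-preserving per-cell gamma variability.
Two generation guarantees keep cohorts classifiable: A/B cells are
re-generated (with a derived sub-seed) until they carry at least 13 events,
and basal bursting cells place their bursts after the first 12 events, so
every classifiable cell exposes a run of 10 consecutive single spikes.
CRH-condition cells use plain Bernoulli burst placement (phenotyping is a
basal-condition measurement, and conditioning would bias the realized burst
fraction). The default replication cohort is 29 male (3 A / 25 B / 1
neither) and 30 female (12 A / 17 B / 1 neither) cells with spontaneous
bursting in 13 male and 6 female cells.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: drifting baselines and seal instability, cell-to-cell
waveform variability beyond the A/B dichotomy, mixed or transitional spike
shapes, stimulus-locked transients after CRH application, and recording
artifacts. Recovery results on synthetic cohorts are a validation of the
pipeline's logic, not an accuracy claim for patch-clamp data.

## Problem sizes and runtime choices

The test suite and the acceptance script use 45–90 s synthetic traces,
cohorts of 14–100 cells, model-cell runs of 60 s at 21–50 µs steps, and 10
seeds per clamp conductance; these sizes give stable statistics (the
pooled event-recovery checks cover > 500 labelled events) while keeping a
full run in minutes on one core. The integrator is compiled (Rcpp); all
randomness flows from explicit seeds, with R's RNG used in compiled code so
results are platform-independent.

## Known limitations

* The minimal model is qualitative: it reproduces firing-mode transitions,
  not quantitative voltage-clamp data; calcium handling and secretion are
  not modelled.
* The A-like model preset's AHP does not reach the A-classification
  threshold (see above).
* The baseline estimator assumes events are a minority of samples; a cell
  bursting most of the time would bias it upward (the detector's relative
  thresholds then shift accordingly).
* Import of vendor binary formats (e.g. ABF) is out of scope; traces enter
  via the CSV dialect.
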