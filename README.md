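# corticotroph

Spike and burst analysis of pituitary corticotroph excitability.

Anterior-pituitary corticotrophs — the ACTH-secreting cells of the
hypothalamic–pituitary–adrenal axis — fire low-frequency single-spike
action potentials at rest and can switch to *pseudo-plateau bursting*
(events longer than 100 ms carrying small spikelets) under secretagogues
such as CRH. Cells fall into two phenotypes by the depth of the
afterhyperpolarization (AHP) after each spike: **A-type** (AHP > 25 mV) and
**B-type** (AHP < 20 mV), and the phenotype predicts the CRH response.
The fast BK potassium conductance promotes the bursting transition, which
can be probed directly by injecting a model BK current into a cell with a
dynamic clamp.

This package is for electrophysiologists quantifying such recordings. It
provides:

* **Event detection** (`detect_events`): an event opens when the membrane
  potential reaches baseline + 20 mV and closes when it falls below
  baseline + 5 mV; events ≤ 100 ms are spikes, events > 100 ms with ≥ 2
  spikelets are bursts.
* **Phenotyping** (`classify_cell_ab`): mean AHP of 10 consecutive spikes,
  with an explicit ambiguous band between the A and B thresholds.
* **Per-cell summaries** (`summarize_cell`): the 12 excitability
  parameters (capacitance, membrane potential, event/spike/burst frequency
  and duration, burst factor = bursts/total events, active time, event
  amplitude, days in culture).
* **Feature analysis** (`correlation_filter`, `run_pca`, `trajectories`):
  greedy removal of features correlated at |r| ≥ 0.8, standardized PCA
  with a deterministic sign convention, and per-cell basal→stimulated
  displacement in PC space.
* **Cohort statistics** (`fisher_exact_2x2`, `welch_t`, `cohort_compare`):
  exact two-sided Fisher tests (minimum-likelihood rule) on phenotype
  counts and Welch t-tests on log-transformed continuous metrics.
* **A model corticotroph and BK dynamic clamp** (`cell_preset`,
  `simulate_cell`, `run_closed_loop`): a minimal three-variable
  conductance-based cell integrated by forward Euler (compiled), and a
  software clamp computing `I_BK = gBK · f · (VK − V)` with
  `τBK df/dt = f∞(V) − f`, `f∞(V) = [1 + exp((vf − V)/sf)]⁻¹`, injected in
  closed loop at a fixed 21 µs step.
* **A synthetic-trace generator** (`make_trace`, `make_cohort`): labelled
  recordings with exact ground truth, used to validate every stage.

## Worked example

Generate a labelled 60 s recording of a B-type cell (0.5 events/s, 20%
bursts), detect and classify its events, and summarize it:

```r
library(corticotroph)

lt <- make_trace(trace_spec(60, event_rate_hz = 0.5, burst_fraction = 0.2,
                            burst_policy = "late", spike_kind = "B",
                            seed = 42))
ev <- detect_events(lt$trace)
head(ev, 3)
#>   start_s  end_s duration_ms peak_v_mv amplitude_mv n_spikelets class
#> 1  0.3482 0.3713        23.1    -18.83        32.89           1 spike
#> 2  1.7625 1.7861        23.6    -18.33        33.39           1 spike
#> 3  2.5269 2.5497        22.8    -18.95        32.78           1 spike

s <- analyze_trace(lt)
#> event_freq 0.50 Hz | burst_factor 0.20 | mean AHP 13.0 mV | class B
```

The detector recovered the generated rate (0.50 Hz) and burst factor
(0.20); the 13 mV mean AHP is below the 20 mV B-threshold, so the cell is
phenotyped B, matching its ground-truth label.

A full cohort replication — 29 male and 30 female basal cells with the
published phenotype counts, processed end-to-end through detection,
classification, and group statistics:

```r
rp <- replicate_published_cohort(seed = 1)
rp$ab_table
#>         A  B
#> male    3 25
#> female 12 17
rp$compare$p[rp$compare$test == "fisher_ab"]
#> [1] 0.0148
```

Every cell was re-classified from its raw trace; the recovered table and
its exact two-sided Fisher p-value (0.0148) show the sex difference in
A/B proportions the pipeline is designed to quantify. The companion
bursting table (13/29 male vs 6/30 female spontaneously bursting cells)
gives p = 0.0539.

The BK rescue experiment on the model cell:

```r
sweep <- bk_rescue_sweep(gbk_ns = c(0, 0.5, 1, 2), seeds = 1:10)
aggregate(burst_factor ~ gbk_ns, sweep, mean)
#>   gbk_ns burst_factor
#> 1    0.0         0.00
#> 2    0.5         0.20
#> 3    1.0         0.49
#> 4    2.0         0.78
```

Under CRH-like drive the unclamped B-type model cell never bursts; adding
BK conductance converts it to pseudo-plateau bursting, with the burst
factor rising monotonically across the 0.5–2 nS range.

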