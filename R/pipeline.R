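#' Analyze one trace end to end
#'
#' Runs event detection, spike/burst classification, A/B phenotyping, and
#' the 12-parameter summary on a single recording.
#'
#' @param x A `ctph_trace` or `ctph_labeled_trace`.
#' @param ... Passed to [detect_events()].
#' @return A one-row data.frame: the 12 parameters plus `ab_class`,
#'   `mean_ahp_mv`, `bursting` (any detected burst), `n_events`, and any
#'   identifying metadata.
#' @export
analyze_trace <- function(x, ...) {
  if (inherits(x, "ctph_labeled_trace")) x <- x$trace
  stopifnot(inherits(x, "ctph_trace"))
  ev <- detect_events(x, ...)
  summ <- summarize_cell(x, ev)
  shapes <- if (sum(ev$class == "spike") > 0) cell_spike_shapes(x, ev) else NULL
  ab <- if (is.null(shapes) || nrow(shapes) == 0)
    list(label = "none", mean_ahp_mv = NA_real_, n_spikes_used = 0L)
  else classify_cell_ab(shapes)
  summ$ab_class <- ab$label
  summ$mean_ahp_mv <- ab$mean_ahp_mv
  summ$bursting <- any(ev$class == "burst")
  summ$n_events <- nrow(ev)
  summ
}

#' Analyze a cohort of traces
#'
#' @param cells List of `ctph_trace` / `ctph_labeled_trace` objects.
#' @param ... Passed to [analyze_trace()].
#' @return data.frame with one row per cell.
#' @export
analyze_cohort <- function(cells, ...) {
  do.call(rbind, lapply(cells, analyze_trace, ...))
}

#' Run the built-in replication cohort end to end
#'
#' Generates the default cohort (29 male / 30 female basal recordings with
#' the published phenotype counts: 3/25/1 male and 12/17/1 female
#' A/B/neither cells, spontaneous bursting in 13 male and 6 female cells),
#' processes every trace through detection, classification, and
#' phenotyping, and compares the sexes with Fisher's exact and Welch's
#' tests.
#'
#' @param seed Integer seed for the cohort generation.
#' @param duration_s Per-cell recording duration (s, default 90).
#' @return List with `summaries` (per-cell table), `ab_table` and
#'   `bursting_table` (2x2 matrices, males then females), and `compare`
#'   (the [cohort_compare()] results).
#' @export
replicate_published_cohort <- function(seed = 1, duration_s = 90) {
  cohort <- make_cohort(published_cohort_spec(seed = seed,
                                          duration_s = duration_s))
  summaries <- analyze_cohort(cohort)
  g <- summaries$sex
  ab <- summaries$ab_class
  ab_table <- matrix(c(sum(ab == "A" & g == "male"),
                       sum(ab == "B" & g == "male"),
                       sum(ab == "A" & g == "female"),
                       sum(ab == "B" & g == "female")),
                     2, 2, byrow = TRUE,
                     dimnames = list(c("male", "female"), c("A", "B")))
  bursting_table <- matrix(c(sum(summaries$bursting & g == "male"),
                             sum(!summaries$bursting & g == "male"),
                             sum(summaries$bursting & g == "female"),
                             sum(!summaries$bursting & g == "female")),
                           2, 2, byrow = TRUE,
                           dimnames = list(c("male", "female"),
                                           c("bursting", "non-bursting")))
  list(summaries = summaries,
       ab_table = ab_table,
       bursting_table = bursting_table,
       compare = cohort_compare(summaries))
}

#' Burst-rescue experiment on the model cell
#'
#' For each seed, simulates the chosen model-cell preset under a CRH-like
#' stimulus with the BK dynamic clamp at each conductance in `gbk_ns`, and
#' measures the burst factor of the detected events.
#'
#' @param gbk_ns Vector of BK conductances to sweep (nS).
#' @param seeds Integer vector of seeds.
#' @param preset `"B"` or `"A"` model-cell preset.
#' @param duration_s Simulated duration per run (s, default 60).
#' @param crh_level CRH stimulus level (default 1).
#' @param bk Template `bk_params()`; its `gbk_ns` is overridden by the sweep.
#' @return data.frame with `gbk_ns`, `seed`, `burst_factor`, `n_events`.
#' @export
bk_rescue_sweep <- function(gbk_ns = c(0, 0.5, 1, 2), seeds = 1:10,
                            preset = "B", duration_s = 60, crh_level = 1,
                            bk = bk_params()) {
  cell <- cell_preset(preset)
  out <- list()
  for (g in gbk_ns) for (s in seeds) {
    bkg <- bk; bkg$gbk_ns <- g
    res <- run_closed_loop(cell, bkg, duration_ms = duration_s * 1000,
                           crh_level = crh_level, seed = s,
                           record_gating = FALSE)
    ev <- detect_events(res$trace)
    out[[length(out) + 1L]] <- data.frame(
      gbk_ns = g, seed = s,
      burst_factor = burst_factor(ev), n_events = nrow(ev))
  }
  do.call(rbind, out)
}
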