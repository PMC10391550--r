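# feature matrix built directly from plausible summary columns
synth_summaries <- function(n = 100, seed = 31) {
  set.seed(seed)
  df <- data.frame(
    cell_id = sprintf("c%03d", 1:n),
    sex = rep(c("male", "female"), length.out = n),
    capacitance_pf = rnorm(n, 4.6, 1.8),
    membrane_potential_mv = rnorm(n, -51, 3),
    spike_freq_hz = rgamma(n, 4, 8),
    burst_freq_hz = rgamma(n, 2, 10),
    spike_duration_ms = rnorm(n, 35, 6),
    burst_duration_ms = rnorm(n, 250, 60),
    event_amplitude_mv = rnorm(n, 30, 4),
    days_in_culture = sample(1:4, n, replace = TRUE),
    stringsAsFactors = FALSE)
  # four engineered collinear columns, each a near-duplicate of a retained
  # feature that sits later in the canonical column order
  df$event_freq_hz <- df$spike_freq_hz * 1.1 + rnorm(n, 0, 0.005)
  df$event_duration_ms <- df$spike_duration_ms * 0.9 + rnorm(n, 0, 0.05)
  df$burst_factor <- df$event_amplitude_mv / 60 + rnorm(n, 0, 0.003)
  df$active_time_frac <- df$days_in_culture / 40 + rnorm(n, 0, 0.0008)
  df
}

test_that("log transform handles units, zeros, and bad input", {
  s <- synth_summaries(50)
  m <- feature_matrix(s)
  ones <- m; ones[, "event_freq_hz"] <- 1
  expect_equal(unname(transform_features(ones)[, "event_freq_hz"]),
               rep(0, nrow(m)))
  geo <- m; geo[, "event_freq_hz"] <- rep(c(1, exp(1), exp(2)),
                                          length.out = nrow(m))
  expect_equal(unname(transform_features(geo)[, "event_freq_hz"]),
               rep(c(0, 1, 2), length.out = nrow(m)))
  # zeros become finite under the half-minimum offset policy
  z <- m; z[1, "event_freq_hz"] <- 0
  tz <- transform_features(z)
  expect_true(all(is.finite(tz[, "event_freq_hz"])))
  expect_equal(unname(attr(tz, "log_offsets")["event_freq_hz"]),
               min(z[z[, "event_freq_hz"] > 0, "event_freq_hz"]) / 2)
  neg <- m; neg[1, "event_freq_hz"] <- -1
  expect_error(transform_features(neg), "negative")
})

test_that("correlation filter removes duplicates and spares orthogonal sets", {
  set.seed(5)
  base <- matrix(rnorm(300), 100, 3,
                 dimnames = list(NULL, c("x", "y", "z")))
  dup <- cbind(base, x_copy = base[, "x"])
  fm <- structure(dup, class = c("ctph_features", "matrix", "array"),
                  labels = NULL, log_transformed = character(0))
  filtered <- correlation_filter(fm)
  expect_equal(ncol(filtered), 3)
  expect_length(intersect(c("x", "x_copy"), colnames(filtered)), 1)
  # orthogonal columns survive untouched
  fm2 <- structure(base, class = c("ctph_features", "matrix", "array"),
                   labels = NULL, log_transformed = character(0))
  expect_equal(ncol(correlation_filter(fm2)), 3)
  expect_length(attr(correlation_filter(fm2), "removed"), 0)
})

test_that("the engineered 12-parameter cohort loses exactly the four collinear features", {
  m <- feature_matrix(synth_summaries())
  filtered <- correlation_filter(m)
  expect_setequal(attr(filtered, "removed"),
                  c("event_freq_hz", "event_duration_ms", "burst_factor",
                    "active_time_frac"))
  expect_equal(ncol(filtered), 8)
  # idempotence: filtering a filtered matrix removes nothing
  again <- correlation_filter(filtered)
  expect_length(attr(again, "removed"), 0)
  # replication mode removes a named set verbatim
  forced <- correlation_filter(m, force_remove = c("event_freq_hz",
                                                   "burst_factor"))
  expect_equal(attr(forced, "removed"), c("event_freq_hz", "burst_factor"))
  expect_equal(ncol(forced), 10)
})

test_that("PCA satisfies orthonormality, ordering, and the sign convention", {
  m <- feature_matrix(synth_summaries())
  p <- run_pca(correlation_filter(m))
  gram <- t(p$loadings) %*% p$loadings
  expect_lt(max(abs(gram - diag(ncol(p$loadings)))), 1e-10)
  expect_true(all(abs(colMeans(p$scores)) < 1e-10))
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  expect_equal(sum(p$variance_explained), 1)
  # largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(p$loadings))) {
    l <- p$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("points on a line give a single component; isotropy splits evenly", {
  set.seed(8)
  t <- rnorm(200)
  line <- structure(cbind(a = 2 * t, b = -t, c = 0.5 * t + 1),
                    class = c("ctph_features", "matrix", "array"),
                    labels = NULL, log_transformed = character(0))
  p <- run_pca(line)
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-10)
  iso <- structure(matrix(rnorm(30000), 10000, 3,
                          dimnames = list(NULL, c("a", "b", "c"))),
                   class = c("ctph_features", "matrix", "array"),
                   labels = NULL, log_transformed = character(0))
  pi_ <- run_pca(iso)
  expect_true(all(abs(pi_$variance_explained - 1 / 3) < 0.02))
})

test_that("full reconstruction from all components recovers the data", {
  m <- feature_matrix(synth_summaries(60))
  p <- run_pca(m)
  std <- scale(m, center = p$center, scale = p$scale)
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - std)), 1e-8)
  # zero-variance columns are rejected by name
  zv <- m; zv[, "capacitance_pf"] <- 3
  expect_error(run_pca(zv), "capacitance_pf")
})

test_that("trajectories report per-cell displacement and reject mismatches", {
  m <- feature_matrix(synth_summaries(40))
  p <- run_pca(m)
  expect_equal(max(abs(trajectories(p$scores, p$scores)[, -1])), 0)
  shifted <- p$scores; shifted[, 1] <- shifted[, 1] - 2
  tr <- trajectories(p$scores, shifted)
  expect_true(all(abs(tr$dPC1 + 2) < 1e-12))
  bad <- p$scores; rownames(bad)[1] <- "nonexistent"
  expect_error(trajectories(p$scores, bad), "unmatched")
})

test_that("stimulated cells move coherently along the bursting component", {
  # 14 male B cells, basal vs CRH-bursting: displacement along the
  # burst-frequency-loaded component should share one sign in >= 90% of cells
  counts <- data.frame(sex = "male", cell_class = "B", n = 14)
  basal <- analyze_cohort(make_cohort(cohort_spec(counts, duration_s = 60,
                                                  seed = 41)))
  stim <- analyze_cohort(make_cohort(cohort_spec(counts,
                                                 condition = "crh_bursting",
                                                 duration_s = 60, seed = 42)))
  both <- rbind(basal, stim)
  m <- feature_matrix(both)
  p <- run_pca(m)
  nb <- nrow(basal)
  sb <- p$scores[seq_len(nb), , drop = FALSE]
  ss <- p$scores[nb + seq_len(nrow(stim)), , drop = FALSE]
  rownames(sb) <- basal$cell_id; rownames(ss) <- stim$cell_id
  # the bursting-loaded direction within the leading plane (the plotted PCs)
  jpc <- which.max(abs(p$loadings["burst_freq_hz", 1:2]))
  disp <- trajectories(sb, ss, components = ncol(p$scores))[[paste0("dPC", jpc)]]
  frac_same <- max(mean(disp > 0), mean(disp < 0))
  expect_gte(frac_same, 0.9)
})
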