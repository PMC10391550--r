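#' Assemble a per-cell feature matrix
#'
#' Binds cell summaries (rows from [summarize_cell()]) into a numeric
#' feature matrix for correlation filtering and PCA, keeping sex/condition
#' labels as attributes. Missing class-wise metrics are imputed under the
#' convention that absence of a class means zero expression of it: a cell
#' with no bursts has burst duration 0 and burst factor 0 (a silent cell's
#' burst factor stays missing and the cell is dropped with a warning).
#'
#' @param summaries data.frame of per-cell summaries (one row per cell),
#'   as returned by rbind-ing [summarize_cell()] outputs.
#' @param feature_cols Character vector of feature columns (defaults to
#'   the 12 excitability parameters).
#' @return A numeric matrix of class `"ctph_features"` with per-cell rows;
#'   attributes `labels` (data.frame with any of `cell_id`, `sex`,
#'   `condition`) and `log_transformed` (character(0) initially).
#' @export
feature_matrix <- function(summaries, feature_cols = c(
    "capacitance_pf", "membrane_potential_mv", "event_freq_hz",
    "spike_freq_hz", "burst_freq_hz", "event_duration_ms",
    "spike_duration_ms", "burst_duration_ms", "burst_factor",
    "active_time_frac", "event_amplitude_mv", "days_in_culture")) {
  stopifnot(is.data.frame(summaries))
  missing_cols <- setdiff(feature_cols, names(summaries))
  if (length(missing_cols))
    stop("summaries lack columns: ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(summaries[, feature_cols])
  # zero-imputation for class-wise metrics of active cells lacking that
  # class; silent cells keep NA and are dropped below
  silent <- summaries$event_freq_hz == 0
  for (cc in intersect(c("spike_duration_ms", "burst_duration_ms",
                         "burst_factor"), feature_cols))
    m[is.na(m[, cc]) & !silent, cc] <- 0
  keep <- stats::complete.cases(m)
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) dropped: missing features after imputation")
    m <- m[keep, , drop = FALSE]
  }
  lab_cols <- intersect(c("cell_id", "sex", "condition"), names(summaries))
  labels <- summaries[keep, lab_cols, drop = FALSE]
  if ("cell_id" %in% lab_cols) rownames(m) <- labels$cell_id
  structure(m, class = c("ctph_features", class(m)),
            labels = labels, log_transformed = character(0))
}

#' Log-transform selected feature columns
#'
#' Applies the natural logarithm to the named columns (event frequency and
#' event duration by default, to meet normality assumptions downstream).
#' Columns containing zeros use `log(x + eps)` with
#' `eps = min(positive values)/2`; the offsets used are recorded in the
#' `log_offsets` attribute. Negative values are rejected.
#'
#' @param m A `"ctph_features"` matrix.
#' @param log_columns Character vector of columns to transform.
#' @return The transformed matrix, with updated `log_transformed` and
#'   `log_offsets` attributes.
#' @export
transform_features <- function(m, log_columns = c("event_freq_hz",
                                                  "event_duration_ms")) {
  stopifnot(inherits(m, "ctph_features"))
  log_columns <- intersect(log_columns, colnames(m))
  offs <- stats::setNames(numeric(length(log_columns)), log_columns)
  for (cc in log_columns) {
    x <- m[, cc]
    if (any(x < 0)) stop("negative values in log column: ", cc)
    eps <- 0
    if (any(x == 0)) {
      pos <- x[x > 0]
      if (!length(pos)) stop("log column is all zeros: ", cc)
      eps <- min(pos) / 2
    }
    offs[cc] <- eps
    m[, cc] <- log(x + eps)
  }
  attr(m, "log_transformed") <- union(attr(m, "log_transformed"), log_columns)
  attr(m, "log_offsets") <- offs
  m
}

#' Remove highly correlated features
#'
#' Greedy filter: while any feature pair has `|r| >= cutoff`, drop the
#' feature with the largest mean absolute correlation among the offending
#' pairs; repeat until no pair exceeds the cutoff. A `force_remove`
#' argument instead removes an explicit named set (replication mode for a
#' published removal list). Constant columns have undefined correlations,
#' which are treated as 0 with a warning.
#'
#' @param m A `"ctph_features"` matrix (>= 2 columns, >= 3 rows).
#' @param cutoff Absolute-correlation threshold (default 0.8).
#' @param force_remove Optional character vector: remove exactly these
#'   columns and skip the greedy rule.
#' @return Filtered matrix with attribute `removed` (character vector, in
#'   removal order).
#' @export
correlation_filter <- function(m, cutoff = 0.8, force_remove = NULL) {
  stopifnot(inherits(m, "ctph_features"))
  if (ncol(m) < 2 || nrow(m) < 3)
    stop("need at least 2 features and 3 cells")
  if (!is.null(force_remove)) {
    bad <- setdiff(force_remove, colnames(m))
    if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
    out <- m[, setdiff(colnames(m), force_remove), drop = FALSE]
    attr(out, "removed") <- force_remove
    return(.restore_feat_attrs(out, m))
  }
  removed <- character(0)
  work <- m
  repeat {
    cm <- suppressWarnings(stats::cor(work))
    if (any(is.na(cm))) {
      warning("constant column(s): undefined correlations treated as 0")
      cm[is.na(cm)] <- 0
    }
    diag(cm) <- 0
    over <- abs(cm) >= cutoff
    if (!any(over)) break
    # mean |r| over the offending pairs only
    score <- vapply(seq_len(ncol(work)), function(j)
      if (any(over[, j])) mean(abs(cm[over[, j], j])) else 0, 0)
    drop_j <- which.max(score)
    removed <- c(removed, colnames(work)[drop_j])
    work <- work[, -drop_j, drop = FALSE]
    if (ncol(work) < 2) break
  }
  attr(work, "removed") <- removed
  .restore_feat_attrs(work, m)
}

.restore_feat_attrs <- function(out, orig) {
  attr(out, "labels") <- attr(orig, "labels")
  attr(out, "log_transformed") <- attr(orig, "log_transformed")
  if (!inherits(out, "ctph_features"))
    class(out) <- c("ctph_features", class(out))
  out
}

#' Principal component analysis of the feature matrix
#'
#' Columns are standardized to zero mean and unit variance (features carry
#' incommensurate units: pF, Hz, ms), then decomposed with [stats::prcomp].
#' A deterministic sign convention is applied: each component is flipped so
#' its largest-magnitude loading is positive, making results reproducible
#' across platforms. Zero-variance columns are rejected by name.
#'
#' @param m A `"ctph_features"` matrix.
#' @return A `"ctph_pca"`: list with `scores` (cells x components),
#'   `loadings` (features x components), `variance_explained` (fraction
#'   per component), `center`, `scale`, `labels`.
#' @export
run_pca <- function(m) {
  stopifnot(inherits(m, "ctph_features"))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  if (nrow(m) < ncol(m))
    warning("fewer cells than features; trailing components are degenerate")
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve,
                 center = pc$center, scale = pc$scale,
                 labels = attr(m, "labels")),
            class = "ctph_pca")
}

#' @export
print.ctph_pca <- function(x, ...) {
  cat(sprintf("<ctph_pca> %d cells x %d features\n",
              nrow(x$scores), nrow(x$loadings)))
  ve <- round(100 * x$variance_explained[seq_len(min(4, length(x$variance_explained)))], 1)
  cat("  variance explained (%):", paste(ve, collapse = ", "), "...\n")
  invisible(x)
}

#' Project new cells onto a fitted PCA
#'
#' @param pca A `"ctph_pca"`.
#' @param m A feature matrix with the same columns as the fit.
#' @return Score matrix for the new rows.
#' @export
project_pca <- function(pca, m) {
  stopifnot(inherits(pca, "ctph_pca"))
  m <- m[, names(pca$center), drop = FALSE]
  scale(m, center = pca$center, scale = pca$scale) %*% pca$loadings
}

#' Basal-to-stimulated trajectories in PCA space
#'
#' Computes each cell's displacement between its basal-state and
#' stimulated-state scores on the leading components. Rows are matched by
#' cell id (rownames); unmatched ids are rejected.
#'
#' @param basal_scores,stim_scores Score matrices (cells x components)
#'   with cell ids as rownames, typically both obtained from one joint
#'   PCA fit of basal plus stimulated rows, or via [project_pca()].
#' @param components Number of leading components to report (default 2).
#' @return data.frame with `cell_id` and `dPC1`, `dPC2`, ... columns.
#' @export
trajectories <- function(basal_scores, stim_scores, components = 2) {
  ids_b <- rownames(basal_scores); ids_s <- rownames(stim_scores)
  if (is.null(ids_b) || is.null(ids_s))
    stop("score matrices need cell ids as rownames")
  if (!setequal(ids_b, ids_s))
    stop("unmatched cell ids: ",
         paste(union(setdiff(ids_b, ids_s), setdiff(ids_s, ids_b)),
               collapse = ", "))
  k <- seq_len(min(components, ncol(basal_scores)))
  d <- stim_scores[ids_b, k, drop = FALSE] - basal_scores[, k, drop = FALSE]
  out <- data.frame(cell_id = ids_b, d, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[-1] <- paste0("dPC", k)
  out
}
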