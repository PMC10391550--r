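#' Write and read traces in the package CSV dialect
#'
#' A trace file is a two-column CSV with header exactly `time_s,v_mv`, one
#' row per sample, time strictly increasing on a uniform grid. Metadata
#' travels in a JSON sidecar (same path with extension `.json`) with keys
#' `cell_id`, `sex`, `condition`, `capacitance_pf`, `days_in_culture`,
#' `fs_hz`, `seed` (whichever are present).
#'
#' @param x A `ctph_trace`.
#' @param path Output CSV path.
#' @param sidecar Write the JSON metadata sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, sidecar = TRUE) {
  stopifnot(inherits(x, "ctph_trace"))
  df <- data.frame(time_s = trace_times(x), v_mv = x$v_mv)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    md <- x$metadata
    md$fs_hz <- x$fs_hz
    jsonlite::write_json(md, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_trace
#' @param tol Maximum grid jitter tolerated (s, default 1e-9).
#' @return `read_trace`: a `ctph_trace`.
#' @export
read_trace <- function(path, tol = 1e-9) {
  header <- readLines(path, n = 1)
  if (!identical(header, "time_s,v_mv"))
    stop("bad trace header: expected 'time_s,v_mv', found '", header, "'")
  df <- utils::read.csv(path)
  t <- df$time_s; v <- df$v_mv
  if (length(t) < 2) stop("trace file has fewer than 2 samples")
  dt <- diff(t)
  if (any(dt <= 0))
    stop("time not strictly increasing at row ", which(dt <= 0)[1] + 1)
  jit <- abs(dt - dt[1])
  if (any(jit > tol))
    stop("non-uniform time grid at row ", which(jit > tol)[1] + 1,
         " (jitter ", format(max(jit)), " s)")
  fs <- 1 / dt[1]
  md <- list()
  sc <- sub("\\.csv$", ".json", path)
  if (file.exists(sc)) {
    md <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(md$fs_hz)) fs <- md$fs_hz
  }
  voltage_trace(v, fs_hz = fs, metadata = md)
}

#' Write and read event tables
#'
#' Events CSV columns:
#' `start_s,end_s,duration_ms,peak_v_mv,amplitude_mv,n_spikelets,class`.
#' Ground-truth CSV columns: `start_s,end_s,class,n_spikelets`.
#'
#' @param events A `ctph_events` table (or a truth data.frame for
#'   [write_truth()]).
#' @param path Output path.
#' @return `path` (writers) / the table (readers), invisibly for writers.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "ctph_events"))
  df <- as.data.frame(events)[, c("start_s", "end_s", "duration_ms",
                                  "peak_v_mv", "amplitude_mv",
                                  "n_spikelets", "class")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(baseline_mv = attr(events, "baseline_mv"),
               recording_duration_s = attr(events, "recording_duration_s"),
               fs_hz = attr(events, "fs_hz"))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  header <- readLines(path, n = 1)
  want <- "start_s,end_s,duration_ms,peak_v_mv,amplitude_mv,n_spikelets,class"
  if (!identical(header, want))
    stop("bad events header: expected '", want, "'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- list(baseline_mv = NA_real_, recording_duration_s = NA_real_,
               fs_hz = NA_real_)
  sc <- sub("\\.csv$", ".json", path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  structure(df, class = c("ctph_events", "data.frame"),
            baseline_mv = meta$baseline_mv,
            recording_duration_s = meta$recording_duration_s,
            fs_hz = meta$fs_hz, n_truncated = 0L)
}

#' @rdname write_events
#' @param truth Truth data.frame (`start_s`, `end_s`, `class`,
#'   `n_spikelets`), e.g. from a `ctph_labeled_trace`.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth[, c("start_s", "end_s", "class", "n_spikelets")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_truth <- function(path) {
  header <- readLines(path, n = 1)
  if (!identical(header, "start_s,end_s,class,n_spikelets"))
    stop("bad truth header: expected 'start_s,end_s,class,n_spikelets'")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write per-cell summaries
#'
#' Writes the 12 excitability parameters plus identifying columns
#' (`cell_id`, `sex`, `condition` when present) as CSV.
#'
#' @param summaries data.frame of cell summaries.
#' @param path Output path.
#' @export
write_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a JSON configuration file
#'
#' @param path JSON path.
#' @return Named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a JSON provenance record for a run
#'
#' Records the package version, R version, seed, timestamp, and the
#' configuration used, so any output can be traced to its inputs.
#'
#' @param path Output JSON path.
#' @param config Named list of run configuration.
#' @param seed Seed used for the run.
#' @export
write_provenance <- function(path, config = list(), seed = NA) {
  rec <- list(package = "corticotroph",
              version = as.character(utils::packageVersion("corticotroph")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = config)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
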