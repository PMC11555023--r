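# On-disk formats: raw timestamp streams (single-column CSV, header
# "timestamp_ms"), JID matrices (plain text with a grid-metadata header
# block), and cluster test results (JSON).

#' Construct a tap stream
#'
#' @param timestamps Numeric vector of epoch-millisecond timestamps,
#'   positive and non-decreasing (sorted on construction); exact duplicates
#'   are collapsed with a message.
#' @param subject_id Optional opaque subject identifier.
#' @return An object of class `tap_stream` with fields `timestamps` and
#'   `subject_id`.
#' @export
tap_stream <- function(timestamps, subject_id = NULL) {
  timestamps <- as.numeric(timestamps)
  if (anyNA(timestamps)) stop("tap_stream: timestamps contain NA")
  if (length(timestamps) && any(timestamps <= 0))
    stop("tap_stream: timestamps must be positive epoch-ms values")
  if (is.unsorted(timestamps)) timestamps <- sort(timestamps)
  dup <- duplicated(timestamps)
  if (any(dup)) {
    message(sprintf("tap_stream: collapsed %d duplicate timestamp(s)", sum(dup)))
    timestamps <- timestamps[!dup]
  }
  structure(list(timestamps = timestamps, subject_id = subject_id),
            class = "tap_stream")
}

#' @export
print.tap_stream <- function(x, ...) {
  n <- length(x$timestamps)
  cat(sprintf("Tap stream: %d events", n))
  if (n >= 2L)
    cat(sprintf(" spanning %.2f days",
                (x$timestamps[n] - x$timestamps[1L]) / 86400e3))
  if (!is.null(x$subject_id)) cat(sprintf(" [subject %s]", x$subject_id))
  cat("\n")
  invisible(x)
}

#' Construct a behavioural day record
#'
#' Holds one day's events and the within-day inter-touch intervals (ITIs)
#' derived from them. ITIs are in seconds; a zero ITI (duplicate ms
#' timestamp) would be undefined in log10 space, so duplicates must have
#' been collapsed upstream.
#'
#' @param day_id Ordinal day tag (character).
#' @param timestamps The day's epoch-ms events, strictly increasing.
#' @param rise_time_ms Optional rise time bounding the day's start.
#' @param flagged Logical low-count flag (set by [split_days()]).
#' @return An object of class `day_record` with `day_id`, `timestamps`,
#'   `itis` (length `n_events - 1`, or 0 if the day is empty), `n_events`,
#'   `rise_time_ms`, `flagged`.
#' @export
day_record <- function(day_id, timestamps, rise_time_ms = NA_real_,
                       flagged = FALSE) {
  timestamps <- as.numeric(timestamps)
  if (is.unsorted(timestamps, strictly = TRUE) && length(timestamps) > 1L)
    stop("day_record: timestamps must be strictly increasing")
  itis <- if (length(timestamps) >= 2L) diff(timestamps) / 1000 else numeric(0)
  structure(list(day_id = as.character(day_id), timestamps = timestamps,
                 itis = itis, n_events = length(timestamps),
                 rise_time_ms = rise_time_ms, flagged = flagged),
            class = "day_record")
}

#' @export
print.day_record <- function(x, ...) {
  cat(sprintf("Day %s: %d events, %d ITIs%s\n", x$day_id, x$n_events,
              length(x$itis), if (x$flagged) " [flagged: low count]" else ""))
  invisible(x)
}

#' Read a raw tap stream from CSV
#'
#' Expects a single-column CSV with header `timestamp_ms` and one epoch-ms
#' integer per row. Out-of-order rows are sorted with a warning; exact
#' duplicates are collapsed with a message; a non-numeric row is a parse
#' error that names its line.
#'
#' @param path File path.
#' @param subject_id Optional subject tag attached to the stream.
#' @return A [tap_stream()].
#' @export
read_taps <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("read_taps: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("read_taps: empty file: ", path)
  if (trimws(lines[1L]) != "timestamp_ms")
    stop("read_taps: missing 'timestamp_ms' header in ", path)
  body <- trimws(lines[-1L])
  if (length(body) == 0L) stop("read_taps: no events in ", path)
  bad <- which(!grepl("^[0-9]+$", body))
  if (length(bad))
    stop(sprintf("read_taps: non-numeric value '%s' at line %d of %s",
                 body[bad[1L]], bad[1L] + 1L, path))
  ts <- as.numeric(body)
  if (is.unsorted(ts))
    warning(sprintf("read_taps: %s not sorted; repaired", path))
  tap_stream(ts, subject_id = subject_id)
}

#' Write a tap stream to CSV
#'
#' @param stream A [tap_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taps <- function(stream, path) {
  stopifnot(inherits(stream, "tap_stream"))
  writeLines(c("timestamp_ms", sprintf("%.0f", stream$timestamps)), path)
  invisible(path)
}

#' Write / read a JID as plain text
#'
#' The format is a `#`-prefixed metadata header (grid edges in log10
#' seconds, bin count, bandwidth, normalization mode, pair count) followed
#' by the matrix, one row of `n_bins` full-precision values per line — so
#' the grid is never implicit. `read_jid()` refuses files whose header is
#' missing or inconsistent.
#'
#' @param jid A `jid` object.
#' @param path File path.
#' @return `write_jid()` returns `path` invisibly; `read_jid()` returns a
#'   `jid` that round-trips `write_jid()` to full stored precision.
#' @export
write_jid <- function(jid, path) {
  stopifnot(inherits(jid, "jid"))
  g <- jid$grid
  hdr <- c("# jid v1",
           sprintf("# lo %.17g", g$lo),
           sprintf("# hi %.17g", g$hi),
           sprintf("# n_bins %d", g$n_bins),
           sprintf("# bandwidth %.17g", g$bandwidth),
           sprintf("# normalization %s", jid$normalization),
           sprintf("# n_pairs %d", jid$n_pairs),
           sprintf("# out_of_grid %.17g", jid$out_of_grid))
  rows <- apply(jid$matrix, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_jid
#' @export
read_jid <- function(path) {
  if (!file.exists(path)) stop("read_jid: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) == 0L || hdr[1L] != "# jid v1")
    stop("read_jid: missing grid header block in ", path)
  get <- function(key, required = TRUE) {
    m <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (length(m) != 1L) {
      if (required) stop("read_jid: header field '", key, "' missing in ", path)
      return(NA)
    }
    sub(paste0("^# ", key, " "), "", m)
  }
  grid <- jid_grid(lo = as.numeric(get("lo")), hi = as.numeric(get("hi")),
                   n_bins = as.integer(get("n_bins")),
                   bandwidth = as.numeric(get("bandwidth")))
  norm <- get("normalization")
  if (!norm %in% c("probability_mass", "density"))
    stop("read_jid: unknown normalization '", norm, "' in ", path)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != grid$n_bins)
    stop(sprintf("read_jid: expected %d matrix rows, found %d in %s",
                 grid$n_bins, length(body), path))
  m <- t(vapply(strsplit(trimws(body), "[[:space:]]+"),
                function(r) as.numeric(r), numeric(grid$n_bins)))
  if (anyNA(m)) stop("read_jid: non-numeric matrix entry in ", path)
  oog <- get("out_of_grid", required = FALSE)
  structure(list(grid = grid, matrix = m,
                 n_pairs = as.integer(get("n_pairs")),
                 normalization = norm,
                 out_of_grid = if (is.na(oog)) 0 else as.numeric(oog)),
            class = "jid")
}

#' Serialise / deserialise a cluster permutation test result
#'
#' Writes the observed cluster table (sign, size, p value, bounding box in
#' log10-seconds coordinates), the null max-cluster-size distribution and
#' its summary percentiles, and the test configuration, as JSON.
#'
#' @param result A `jid_cluster_test` from [jid_permutation_test()].
#' @param path File path.
#' @return `write_cluster_result()` returns `path` invisibly;
#'   `read_cluster_result()` returns the parsed list (not a rebuilt
#'   `jid_cluster_test`; the t-map matrix and clusters are preserved).
#' @export
write_cluster_result <- function(result, path) {
  stopifnot(inherits(result, "jid_cluster_test"))
  g <- result$tmap$grid
  cl <- result$clusters
  cluster_table <- if (length(cl)) data.frame(
    sign = vapply(cl, `[[`, numeric(1), "sign"),
    size = vapply(cl, `[[`, numeric(1), "size"),
    p_value = vapply(cl, `[[`, numeric(1), "p_value"),
    significant = vapply(cl, `[[`, logical(1), "significant"),
    row_min = vapply(cl, function(c) min(c$member_bins[, 1L]), numeric(1)),
    row_max = vapply(cl, function(c) max(c$member_bins[, 1L]), numeric(1)),
    col_min = vapply(cl, function(c) min(c$member_bins[, 2L]), numeric(1)),
    col_max = vapply(cl, function(c) max(c$member_bins[, 2L]), numeric(1))
  ) else data.frame()
  if (nrow(cluster_table)) {
    ctr <- g$centers
    cluster_table$log10_k_min <- ctr[cluster_table$row_min]
    cluster_table$log10_k_max <- ctr[cluster_table$row_max]
    cluster_table$log10_k1_min <- ctr[cluster_table$col_min]
    cluster_table$log10_k1_max <- ctr[cluster_table$col_max]
  }
  null_q <- stats::quantile(result$null_max_sizes,
                            c(0.025, 0.5, 0.95, 0.975), names = FALSE)
  obj <- list(
    format = "jid_cluster_test v1",
    grid = list(lo = g$lo, hi = g$hi, n_bins = g$n_bins,
                bandwidth = g$bandwidth),
    n_a = result$tmap$n_a, n_b = result$tmap$n_b, df = result$tmap$df,
    B = result$B, seed = result$seed,
    alpha_cluster_forming = result$alpha_cluster_forming,
    connectivity = result$connectivity,
    threshold_95 = result$threshold_95,
    null_summary = list(median = null_q[2L], q2.5 = null_q[1L],
                        q95 = null_q[3L], q97.5 = null_q[4L]),
    clusters = cluster_table,
    t_values = result$tmap$t_values,
    null_max_sizes = result$null_max_sizes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_cluster_result
#' @export
read_cluster_result <- function(path) {
  if (!file.exists(path)) stop("read_cluster_result: file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "jid_cluster_test v1"))
    stop("read_cluster_result: unrecognised format in ", path)
  obj
}
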