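# Rise-time detection and day splitting.
#
# A behavioural day runs rise-to-rise: the rise time is the end of the
# longest no-use gap found in each noon-to-noon window whose end falls in
# the search window (a gap-based heuristic; see the methods vignette for
# why this stands in for dedicated sleep/wake detection). Day boundaries
# are half-open [rise_i, rise_{i+1}), so no inter-touch interval ever spans
# a boundary.

#' Parameters for behavioural-day segmentation
#'
#' @param min_sleep_gap Minimum no-use gap, in hours, accepted as the
#'   nightly sleep gap (default 3).
#' @param search_window Clock-time window (start hour, end hour; wraps
#'   midnight) in which the sleep gap must end. Default `c(20, 12)`,
#'   i.e. 20:00 through noon.
#' @param min_day_events Days with fewer events are flagged and, by
#'   default, excluded from group statistics downstream (default 30).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(min_sleep_gap = 3, search_window = c(20, 12),
                                min_day_events = 30L) {
  if (!is.numeric(min_sleep_gap) || min_sleep_gap <= 0)
    stop("segmentation_params: min_sleep_gap must be > 0")
  if (length(search_window) != 2L || any(search_window < 0) ||
      any(search_window >= 24))
    stop("segmentation_params: search_window must be two clock hours in [0, 24)")
  min_day_events <- as.integer(min_day_events)
  if (is.na(min_day_events) || min_day_events < 2L)
    stop("segmentation_params: min_day_events must be >= 2")
  structure(list(min_sleep_gap = min_sleep_gap,
                 search_window = search_window,
                 min_day_events = min_day_events),
            class = "segmentation_params")
}

in_clock_window <- function(hour, window) {
  if (window[1L] < window[2L]) hour >= window[1L] & hour < window[2L]
  else hour >= window[1L] | hour < window[2L]
}

#' Detect rise times in a continuous tap stream
#'
#' Scans successive noon-to-noon windows; within each, the longest event gap
#' of at least `min_sleep_gap` hours whose end lies in the clock-time search
#' window is taken as the night's sleep, and its end as the rise time. The
#' stream's first event opens the first behavioural day. A window with no
#' qualifying gap merges its day into the next, with a warning.
#'
#' @param stream A [tap_stream()].
#' @param params A [segmentation_params()].
#' @return Numeric vector of strictly increasing rise times (epoch ms),
#'   one per detected behavioural day.
#' @export
detect_rise_times <- function(stream, params = segmentation_params()) {
  stopifnot(inherits(stream, "tap_stream"))
  ts <- stream$timestamps / 1000  # epoch seconds
  n <- length(ts)
  if (n == 0L) stop("detect_rise_times: empty stream")
  if (n == 1L) return(stream$timestamps)

  gap_start <- ts[-n]
  gap_end <- ts[-1L]
  gap_len <- gap_end - gap_start
  end_hour <- (gap_end %% 86400) / 3600
  eligible <- gap_len >= params$min_sleep_gap * 3600 &
    in_clock_window(end_hour, params$search_window)

  first_noon <- floor(ts[1L] / 86400) * 86400 + 43200
  if (first_noon > ts[1L]) first_noon <- first_noon - 86400
  window_starts <- seq(first_noon, ts[n], by = 86400)

  rises <- numeric(0)
  merged <- 0L
  nw <- length(window_starts)
  for (wi in seq_len(nw)) {
    a <- window_starts[wi]
    hit <- eligible & gap_end > a & gap_end <= a + 86400
    if (!any(hit)) {
      # first/last windows legitimately hold no night-gap end (stream edges)
      if (wi > 1L && wi < nw) merged <- merged + 1L
      next
    }
    best <- which(hit)[which.max(gap_len[hit])]
    rises <- c(rises, gap_end[best])
  }
  if (merged > 0L)
    warning(sprintf("detect_rise_times: %d window(s) had no sleep gap >= %.1f h; day(s) merged with the next",
                    merged, params$min_sleep_gap))
  rises <- sort(unique(rises))
  rises <- rises[rises > ts[1L]]
  round(c(ts[1L], rises) * 1000)
}

#' Split a tap stream into behavioural day records
#'
#' Assigns every event to exactly one day under the half-open convention
#' [rise_i, rise_{i+1}): an event exactly at a rise time starts that day.
#' Inter-touch intervals are computed within day only.
#'
#' @param stream A [tap_stream()].
#' @param rise_times Rise times (epoch ms) from [detect_rise_times()].
#' @param params A [segmentation_params()]; supplies the low-count flag
#'   threshold.
#' @return List of [day_record()]s; total event count over records equals
#'   the stream's event count.
#' @export
split_days <- function(stream, rise_times, params = segmentation_params()) {
  stopifnot(inherits(stream, "tap_stream"))
  rise_times <- sort(as.numeric(rise_times))
  if (length(rise_times) == 0L) stop("split_days: no rise times")
  ts <- stream$timestamps
  idx <- findInterval(ts, rise_times)
  if (any(idx == 0L)) {
    warning(sprintf("split_days: %d event(s) precede the first rise time; assigned to day 1",
                    sum(idx == 0L)))
    idx[idx == 0L] <- 1L
  }
  lapply(seq_along(rise_times), function(i) {
    di <- ts[idx == i]
    day_record(day_id = sprintf("day_%03d", i), timestamps = di,
               rise_time_ms = rise_times[i],
               flagged = length(di) < params$min_day_events)
  })
}

#' Tabulate a segmentation result
#'
#' @param days List of [day_record()]s from [split_days()].
#' @return Data frame with `day_id`, `rise_time_ms`, `n_events`, `flagged`.
#' @export
segmentation_report <- function(days) {
  data.frame(
    day_id = vapply(days, `[[`, character(1), "day_id"),
    rise_time_ms = vapply(days, `[[`, numeric(1), "rise_time_ms"),
    n_events = vapply(days, `[[`, numeric(1), "n_events"),
    flagged = vapply(days, `[[`, logical(1), "flagged"),
    stringsAsFactors = FALSE)
}
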