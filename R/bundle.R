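## EventStreamBundle: one participant-day's raw events across the nine
## sensor streams, plus per-stream presence flags.

#' Construct an event-stream bundle for one participant-day
#'
#' Timestamps are numeric seconds since the day's local midnight and must
#' fall in `[0, 30*3600)` (sleep episodes may cross midnight into the next
#' morning). An absent stream is `NULL` with its presence flag `FALSE`; a
#' present-but-empty stream is an empty data.frame (or all-NA step vector).
#'
#' @param participant_id opaque string.
#' @param date a `Date`.
#' @param location data.frame `ts`, `lat`, `lon`.
#' @param activity data.frame `ts`, `class` (still/walking/running/
#'   in_vehicle/on_bicycle).
#' @param screen data.frame `ts`, `event` (on/off/unlock).
#' @param calls data.frame `ts`, `type` (incoming/outgoing/missed),
#'   `duration` seconds.
#' @param bluetooth data.frame `ts`, `device_hash`.
#' @param wifi data.frame `ts`, `ap_hash`.
#' @param battery data.frame `ts`, `level`.
#' @param steps numeric length-1440 per-minute counts (NA = unrecorded).
#' @param sleep data.frame `onset_ts`, `offset_ts`, `minute_count`.
#' @param present named logical vector over the nine streams; defaults to
#'   non-NULL-ness of each argument.
#' @return an object of class `put_bundle`.
#' @export
event_bundle <- function(participant_id, date,
                         location = NULL, activity = NULL, screen = NULL,
                         calls = NULL, bluetooth = NULL, wifi = NULL,
                         battery = NULL, steps = NULL, sleep = NULL,
                         present = NULL) {
  streams <- list(location = location, activity = activity, screen = screen,
                  calls = calls, bluetooth = bluetooth, wifi = wifi,
                  battery = battery, steps = steps, sleep = sleep)
  if (is.null(present)) {
    present <- !vapply(streams[PUT_STREAMS], is.null, logical(1))
  }
  stopifnot(setequal(names(present), PUT_STREAMS))
  for (s in setdiff(PUT_STREAMS, "steps")) {
    df <- streams[[s]]
    if (!is.null(df) && nrow(df) > 0L) {
      ts <- if (s == "sleep") df$onset_ts else df$ts
      if (any(ts < 0 | ts >= 30 * 3600)) {
        stop(sprintf("stream '%s': timestamps outside [00:00, next-day 06:00)", s))
      }
    }
  }
  if (!is.null(steps)) {
    stopifnot(length(steps) == 1440L, all(steps >= 0, na.rm = TRUE))
  }
  structure(c(list(participant_id = participant_id, date = as.Date(date)),
              streams, list(present = present[PUT_STREAMS])),
            class = "put_bundle")
}

#' @export
print.put_bundle <- function(x, ...) {
  n_ev <- vapply(PUT_STREAMS, function(s) {
    v <- x[[s]]
    if (is.null(v)) 0L
    else if (is.data.frame(v)) nrow(v)
    else sum(!is.na(v))
  }, integer(1))
  cat(sprintf("<put_bundle> %s %s | streams present: %d/9\n",
              x$participant_id, format(x$date), sum(x$present)))
  cat("  events:", paste(sprintf("%s=%d", PUT_STREAMS, n_ev), collapse = " "),
      "\n")
  invisible(x)
}
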