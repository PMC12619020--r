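## Within-day epoch windows and event segmentation.
##
## All event timestamps are numeric seconds since local midnight of the
## bundle's calendar day; sleep episodes may run past 86400 (into the next
## morning). Epoch intervals are half-open [start, end).

#' Epoch window lookup
#'
#' @param name one of `"night"`, `"morning"`, `"afternoon"`, `"evening"`,
#'   `"all_day"`.
#' @return list with `name`, `start`, `end` (seconds since local midnight);
#'   night = \[00:00, 06:00), morning = \[06:00, 12:00), afternoon =
#'   \[12:00, 18:00), evening = \[18:00, 24:00), all day = \[00:00, 24:00).
#' @export
epoch_window <- function(name) {
  name <- match.arg(name, EPOCH_NAMES)
  b <- EPOCH_BOUNDS[[name]]
  list(name = name, start = b[1], end = b[2])
}

#' Select the point events of an epoch
#'
#' Returns the rows whose timestamp falls in `[epoch$start, epoch$end)`
#' (half-open, so an event at exactly 06:00 belongs to the morning).
#' Interval streams (screen bouts, stays, call or dwell intervals) are not
#' handled here; their durations are clipped by [clip_intervals()].
#'
#' @param events data.frame with a numeric `ts` column, time-sorted.
#' @param epoch an [epoch_window()].
#' @return the sub-data.frame of events inside the epoch.
#' @export
segment_day <- function(events, epoch) {
  if (is.null(events) || nrow(events) == 0L) return(events)
  if (is.unsorted(events$ts)) stop("events must be time-sorted")
  events[events$ts >= epoch$start & events$ts < epoch$end, , drop = FALSE]
}

#' Clip intervals to an epoch window
#'
#' Pro-rates interval durations at the epoch edges: a 17:50-18:20 screen
#' bout contributes 10 minutes to the afternoon and 20 to the evening.
#'
#' @param start,end numeric vectors of interval bounds (seconds).
#' @param epoch an [epoch_window()].
#' @return numeric vector of overlap durations in seconds (0 if disjoint).
#' @export
clip_intervals <- function(start, end, epoch) {
  pmax(0, pmin(end, epoch$end) - pmax(start, epoch$start))
}
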