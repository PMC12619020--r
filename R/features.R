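## Per-stream feature extractors. Every extractor returns a named numeric
## vector for one epoch; values are NA where the statistic is undefined
## (e.g. no data). Conventions: durations in minutes, clock times in
## seconds since local midnight, counts as nonnegative integers.

## default extraction parameters (all config-exposed through
## extract_person_day)
extraction_params <- function(gap_cap_s = 900, stay_radius_m = 100,
                              stay_min_s = 600, active_min_steps = 10,
                              activity_dwell_cap_s = 300,
                              fix_match_window_s = 600) {
  list(gap_cap_s = gap_cap_s, stay_radius_m = stay_radius_m,
       stay_min_s = stay_min_s, active_min_steps = active_min_steps,
       activity_dwell_cap_s = activity_dwell_cap_s,
       fix_match_window_s = fix_match_window_s)
}

## dwell intervals for point samples: each sample covers [ts, ts + dwell)
## where dwell = time to the next sample, capped
dwell_intervals <- function(ts, cap) {
  n <- length(ts)
  if (n == 0L) return(cbind(start = numeric(0), end = numeric(0)))
  dwell <- c(pmin(diff(ts), cap), cap)
  cbind(start = ts, end = ts + dwell)
}

## stay-point detection (greedy trajectory segmentation): a maximal run of
## fixes within `radius` of the anchor fix lasting at least `min_s`
detect_stay_points <- function(fixes, radius_m = 100, min_s = 600) {
  n <- nrow(fixes)
  s_lat <- s_lon <- s_start <- s_end <- numeric(0)
  i <- 1L
  while (i < n) {
    d <- haversine_m(fixes$lat[i], fixes$lon[i],
                     fixes$lat[(i + 1L):n], fixes$lon[(i + 1L):n])
    far <- which(d > radius_m)
    j <- if (length(far) == 0L) n else i + far[1] - 1L
    if (j > i && fixes$ts[j] - fixes$ts[i] >= min_s) {
      s_lat <- c(s_lat, mean(fixes$lat[i:j]))
      s_lon <- c(s_lon, mean(fixes$lon[i:j]))
      s_start <- c(s_start, fixes$ts[i])
      s_end <- c(s_end, fixes$ts[j])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(lat = s_lat, lon = s_lon, start = s_start, end = s_end)
}

#' Location features for one epoch
#'
#' Off-campus dwell time and share, stay-point statistics against the
#' campus zones, and the log location variance. Per-fix dwell is the time
#' to the next fix, capped at `params$gap_cap_s` (default 15 min); dwell
#' and stay intervals are clipped at the epoch edges.
#'
#' @param fixes data.frame `ts`, `lat`, `lon` (time-sorted) or NULL.
#' @param map a [campus_map()].
#' @param epoch an [epoch_window()].
#' @param params see `extraction_params()`.
#' @param stays optional precomputed [detect_stay_points()] result for
#'   these fixes (avoids recomputation across epochs).
#' @return named numeric vector of the location statistics.
#' @export
extract_location_features <- function(fixes, map, epoch,
                                      params = extraction_params(),
                                      stays = NULL) {
  out <- c(off_campus_time = NA_real_, off_campus_pct = NA_real_,
           avg_stay_off_campus = NA_real_, longest_stay_study = NA_real_,
           avg_stay_green = NA_real_, var_stay_green = NA_real_,
           location_variance = NA_real_)
  if (is.null(fixes) || nrow(fixes) == 0L) return(out)
  off <- !on_campus(map, fixes$lat, fixes$lon)
  ## region-aware dwell: the gap to the next fix counts in full while the
  ## on/off-campus classification is unchanged; at a transition (or after
  ## the last fix) the dwell is capped, since the crossing time is unknown
  n <- nrow(fixes)
  gap <- c(diff(fixes$ts), params$gap_cap_s)
  same_next <- c(off[-1] == off[-n], FALSE)
  dwell <- ifelse(same_next, gap, pmin(gap, params$gap_cap_s))
  dur <- clip_intervals(fixes$ts, fixes$ts + dwell, epoch) / 60
  total <- sum(dur)
  if (total > 0) {
    out["off_campus_time"] <- sum(dur[off])
    out["off_campus_pct"] <- sum(dur[off]) / total
  }
  in_ep <- segment_day(fixes, epoch)
  if (nrow(in_ep) >= 2L) {
    v <- stats::var(in_ep$lat) + stats::var(in_ep$lon)
    out["location_variance"] <- log(v + 1e-12)
  }
  sp <- stays %||%
    detect_stay_points(fixes, params$stay_radius_m, params$stay_min_s)
  if (nrow(sp) > 0L) {
    sdur <- clip_intervals(sp$start, sp$end, epoch) / 60
    keep <- sdur > 0
    if (any(keep)) {
      sp <- sp[keep, , drop = FALSE]; sdur <- sdur[keep]
      sp_off <- !on_campus(map, sp$lat, sp$lon)
      if (any(sp_off)) out["avg_stay_off_campus"] <- mean(sdur[sp_off])
      st <- in_zone(map$study, sp$lat, sp$lon)
      if (any(st)) out["longest_stay_study"] <- max(sdur[st])
      gr <- in_zone(map$green, sp$lat, sp$lon)
      if (any(gr)) {
        out["avg_stay_green"] <- mean(sdur[gr])
        out["var_stay_green"] <- if (sum(gr) > 1) stats::sd(sdur[gr]) else 0
      }
    }
  }
  out
}

#' Circadian movement over a trailing multi-day location buffer
#'
#' Least-squares spectral power of latitude and longitude in the
#' 23.5-24.5 h period band, summed over both coordinates and logged.
#' Requires at least 2 days of fixes; returns NA otherwise.
#'
#' @param fix_history data.frame `ts_abs` (seconds on a continuous
#'   multi-day axis), `lat`, `lon`.
#' @return scalar feature value (or NA).
#' @export
circadian_movement <- function(fix_history) {
  if (is.null(fix_history) || nrow(fix_history) < 24L ||
      diff(range(fix_history$ts_abs)) < 2 * 86400) {
    return(NA_real_)
  }
  periods <- seq(23.5, 24.5, by = 0.1) * 3600
  pow <- function(x) {
    x <- x - mean(x)
    sapply(periods, function(p) {
      w <- 2 * pi / p
      cw <- cos(w * fix_history$ts_abs); sw <- sin(w * fix_history$ts_abs)
      ## Lomb-style least-squares amplitude at this frequency
      a <- sum(x * cw) / pmax(sum(cw^2), 1e-9)
      b <- sum(x * sw) / pmax(sum(sw^2), 1e-9)
      a^2 + b^2
    })
  }
  e <- sum(pow(fix_history$lat)) + sum(pow(fix_history$lon))
  log(e + 1e-12)
}

## pair screen on/off events into bouts, dropping unmatched events;
## unlocks open interaction bouts (unlock -> next off)
screen_bouts <- function(events, kind = c("onoff", "interaction")) {
  kind <- match.arg(kind)
  if (is.null(events) || nrow(events) == 0L) {
    return(cbind(start = numeric(0), end = numeric(0)))
  }
  open_ev <- if (kind == "onoff") "on" else "unlock"
  starts <- ends <- numeric(0)
  open_ts <- NA_real_
  for (i in seq_len(nrow(events))) {
    ev <- events$event[i]
    if (ev == open_ev && is.na(open_ts)) {
      open_ts <- events$ts[i]
    } else if (ev == "off" && !is.na(open_ts)) {
      starts <- c(starts, open_ts); ends <- c(ends, events$ts[i])
      open_ts <- NA_real_
    }
  }
  cbind(start = starts, end = ends)
}

#' Screen-use features for one epoch
#'
#' @param events data.frame `ts`, `event` (`"on"`, `"off"`, `"unlock"`),
#'   time-sorted, or NULL.
#' @param epoch an [epoch_window()].
#' @param bouts optional precomputed list `onoff`, `interaction` of
#'   [screen_bouts()] matrices.
#' @return named vector: total screen minutes (on->off, clipped), unlock
#'   count, first unlock time in the epoch (s since midnight), shortest
#'   interaction bout (unlock->off) minutes.
#' @export
extract_screen_features <- function(events, epoch, bouts = NULL) {
  out <- c(screen_time = NA_real_, n_unlocks = NA_real_,
           first_unlock_time = NA_real_, shortest_bout = NA_real_)
  if (is.null(events) || nrow(events) == 0L) return(out)
  onoff <- if (!is.null(bouts)) bouts$onoff else screen_bouts(events, "onoff")
  dur <- clip_intervals(onoff[, "start"], onoff[, "end"], epoch) / 60
  out["screen_time"] <- sum(dur)
  unlocks <- events$ts[events$event == "unlock"]
  in_ep <- unlocks[unlocks >= epoch$start & unlocks < epoch$end]
  out["n_unlocks"] <- length(in_ep)
  if (length(in_ep) > 0L) out["first_unlock_time"] <- min(in_ep)
  inter <- if (!is.null(bouts)) bouts$interaction
           else screen_bouts(events, "interaction")
  idur <- clip_intervals(inter[, "start"], inter[, "end"], epoch) / 60
  idur <- idur[idur > 0]
  if (length(idur) > 0L) out["shortest_bout"] <- min(idur)
  out
}

## run-length segmentation of the per-minute step series into active
## (>= threshold steps) and sedentary runs
step_runs <- function(minutes, values, threshold) {
  active <- values >= threshold
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(active = r$values, start_min = minutes[starts],
             end_min = minutes[ends], len = r$lengths,
             steps = vapply(seq_along(starts), function(i)
               sum(values[starts[i]:ends[i]]), numeric(1)))
}

#' Step-count features for one epoch
#'
#' Active bouts are maximal runs of minutes with at least
#' `params$active_min_steps` steps (default 10); the remaining minutes are
#' sedentary. The last-active-bout end time is reported in seconds since
#' midnight.
#'
#' @param minute_steps numeric vector of length 1440 (per-minute counts,
#'   NA = minute not recorded) or NULL.
#' @param epoch an [epoch_window()].
#' @param params see `extraction_params()`.
#' @return named vector of the step statistics.
#' @export
extract_steps_features <- function(minute_steps, epoch,
                                   params = extraction_params()) {
  out <- c(total_steps = NA_real_, n_active_bouts = NA_real_,
           avg_steps_active_bout = NA_real_, last_active_bout_end = NA_real_,
           sedentary_time = NA_real_, sedentary_bout_mean = NA_real_,
           sedentary_bout_sd = NA_real_)
  if (is.null(minute_steps)) return(out)
  mins <- seq.int(epoch$start %/% 60, epoch$end %/% 60 - 1L)
  vals <- minute_steps[mins + 1L]
  obs <- !is.na(vals)
  if (!any(obs)) return(out)
  mins <- mins[obs]; vals <- vals[obs]
  out["total_steps"] <- sum(vals)
  runs <- step_runs(mins, vals, params$active_min_steps)
  act <- runs[runs$active, , drop = FALSE]
  sed <- runs[!runs$active, , drop = FALSE]
  out["n_active_bouts"] <- nrow(act)
  if (nrow(act) > 0L) {
    ## per-minute stepping intensity averaged over active bouts
    out["avg_steps_active_bout"] <- mean(act$steps / act$len)
    out["last_active_bout_end"] <- (act$end_min[nrow(act)] + 1L) * 60
  }
  out["sedentary_time"] <- sum(sed$len)
  if (nrow(sed) > 0L) {
    out["sedentary_bout_mean"] <- mean(sed$len)
    out["sedentary_bout_sd"] <- if (nrow(sed) > 1) stats::sd(sed$len) else 0
  }
  out
}

#' Call features for one epoch
#'
#' Counts are 0 (not missing) when the stream is present but empty; call
#' durations are clipped at the epoch edges.
#'
#' @param calls data.frame `ts`, `type` (`"incoming"`, `"outgoing"`,
#'   `"missed"`), `duration` (seconds), or NULL.
#' @param epoch an [epoch_window()].
#' @return named vector: missed-call count, call count, total call minutes.
#' @export
extract_call_features <- function(calls, epoch) {
  out <- c(n_missed_calls = NA_real_, n_calls = NA_real_,
           total_call_duration = NA_real_)
  if (is.null(calls)) return(out)
  in_ep <- segment_day(calls, epoch)
  out["n_missed_calls"] <- sum(in_ep$type == "missed")
  out["n_calls"] <- nrow(in_ep)
  if (nrow(calls) > 0L) {
    dur <- clip_intervals(calls$ts, calls$ts + calls$duration, epoch) / 60
    out["total_call_duration"] <- sum(dur)
  } else {
    out["total_call_duration"] <- 0
  }
  out
}

#' Wi-Fi features for one epoch
#' @param wifi data.frame `ts`, `ap_hash`, or NULL.
#' @param epoch an [epoch_window()].
#' @return named vector: number of distinct access points scanned.
#' @export
extract_wifi_features <- function(wifi, epoch) {
  if (is.null(wifi)) return(c(n_unique_aps = NA_real_))
  in_ep <- segment_day(wifi, epoch)
  c(n_unique_aps = length(unique(in_ep$ap_hash)))
}

#' Activity and fused activity-location features for one epoch
#'
#' Physical-activity duration counts minutes labelled walking, running or
#' cycling (each sample covers the time to the next sample, capped).
#' Indoor mobility fuses activity and location: walking time while the
#' nearest location fix (within `params$fix_match_window_s`) lies inside a
#' campus building zone; it is missing unless both streams are present.
#'
#' @param activity data.frame `ts`, `class`, or NULL.
#' @param fixes location data.frame `ts`, `lat`, `lon`, or NULL.
#' @param map a [campus_map()].
#' @param epoch an [epoch_window()].
#' @param params see `extraction_params()`.
#' @return named vector: `physical_activity_duration`, `indoor_mobility`
#'   (minutes).
#' @export
extract_activity_features <- function(activity, fixes, map, epoch,
                                      params = extraction_params()) {
  out <- c(physical_activity_duration = NA_real_, indoor_mobility = NA_real_)
  if (is.null(activity)) return(out)
  moving_classes <- c("walking", "running", "on_bicycle")
  iv <- dwell_intervals(activity$ts, params$activity_dwell_cap_s)
  dur <- clip_intervals(iv[, "start"], iv[, "end"], epoch) / 60
  moving <- activity$class %in% moving_classes
  out["physical_activity_duration"] <- sum(dur[moving])
  if (!is.null(fixes) && nrow(fixes) > 0L && nrow(activity) > 0L) {
    walking <- activity$class == "walking"
    indoor <- 0
    if (any(walking)) {
      idx <- findInterval(activity$ts[walking], fixes$ts)
      idx[idx == 0L] <- 1L
      near <- abs(fixes$ts[idx] - activity$ts[walking]) <=
        params$fix_match_window_s
      inb <- in_zone(map$buildings, fixes$lat[idx], fixes$lon[idx])
      indoor <- sum(dur[walking][near & inb])
    }
    out["indoor_mobility"] <- indoor
  }
  out
}

#' Daily sleep features
#'
#' Attributed to the day on which the nightly episode begins; onset is
#' encoded as seconds since midnight of the onset calendar day (23:30 ->
#' 84600, 01:10 -> 4200). The main episode is the longest of the day.
#'
#' @param sleep data.frame `onset_ts`, `offset_ts`, `minute_count` with
#'   timestamps in seconds relative to the day's midnight (values past
#'   86400 fall in the following morning), or NULL.
#' @return named vector: onset (s since midnight of the onset day), total
#'   duration (minutes), and the minute-level sample count.
#' @export
extract_sleep_features <- function(sleep) {
  out <- c(sleep_onset = NA_real_, sleep_duration = NA_real_)
  if (is.null(sleep) || nrow(sleep) == 0L) return(out)
  main <- which.max(sleep$minute_count)
  out["sleep_onset"] <- sleep$onset_ts[main] %% 86400
  out["sleep_duration"] <- sum(sleep$minute_count)
  out
}
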