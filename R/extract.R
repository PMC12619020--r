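## Person-day feature extraction: evaluate the whole catalog on one
## bundle, honoring missingness propagation and per-stream sample counts.

## per-epoch sample counts for one stream
stream_sample_count <- function(bundle, stream, epoch) {
  v <- bundle[[stream]]
  if (is.null(v)) return(NA_real_)
  if (stream == "steps") {
    mins <- seq.int(epoch$start %/% 60, epoch$end %/% 60 - 1L)
    return(sum(!is.na(v[mins + 1L])))
  }
  if (stream == "sleep") return(if (nrow(v)) sum(v$minute_count) else 0)
  nrow(segment_day(v, epoch))
}

#' Extract the full feature vector for one participant-day
#'
#' Evaluates every catalog entry over its epoch; absent streams yield
#' missing values for all features that require them (sample counts are 0
#' only when the stream is present but empty), and fused features are
#' missing unless every required stream is present.
#'
#' @param bundle a [event_bundle()].
#' @param catalog a [feature_catalog()] (default).
#' @param map a [campus_map()] (default synthetic campus).
#' @param history optional data.frame `ts_abs`, `lat`, `lon` of location
#'   fixes over a trailing multi-day buffer, for circadian movement.
#' @param params see `extraction_params()`.
#' @return a one-row data.frame: `participant_id`, `date`, one column per
#'   catalog feature, and `avail_<stream>` presence flags.
#' @export
extract_person_day <- function(bundle, catalog = feature_catalog(),
                               map = default_campus_map(), history = NULL,
                               params = extraction_params()) {
  stopifnot(inherits(bundle, "put_bundle"))
  present <- bundle$present
  get <- function(s) if (present[[s]]) bundle[[s]] else NULL

  ## shared intermediates computed once across epochs
  fixes <- get("location")
  stays <- if (!is.null(fixes) && nrow(fixes) > 0L) {
    detect_stay_points(fixes, params$stay_radius_m, params$stay_min_s)
  } else NULL
  scr <- get("screen")
  bouts <- if (!is.null(scr) && nrow(scr) > 0L) {
    list(onoff = screen_bouts(scr, "onoff"),
         interaction = screen_bouts(scr, "interaction"))
  } else NULL

  per_epoch <- list()
  for (ep_name in EPOCH_NAMES) {
    ep <- epoch_window(ep_name)
    tag <- function(v, stream) {
      stats::setNames(v, paste0(stream, ".", names(v), ".", ep_name))
    }
    act <- extract_activity_features(get("activity"), get("location"), map,
                                     ep, params)
    vals <- c(
      tag(extract_location_features(fixes, map, ep, params, stays),
          "location"),
      tag(extract_screen_features(scr, ep, bouts), "screen"),
      tag(extract_steps_features(get("steps"), ep, params), "steps"),
      tag(extract_call_features(get("calls"), ep), "calls"),
      tag(extract_wifi_features(get("wifi"), ep), "wifi"),
      tag(act["physical_activity_duration"], "activity"),
      tag(act["indoor_mobility"], "activity_location")
    )
    for (s in PUT_STREAMS) {
      if (s == "sleep" && ep_name != "all_day") next
      vals[paste0(s, ".sample_count.", ep_name)] <-
        stream_sample_count(bundle, s, ep)
    }
    per_epoch[[ep_name]] <- vals
  }
  all_vals <- do.call(c, unname(per_epoch))
  sl <- extract_sleep_features(get("sleep"))
  all_vals["sleep.sleep_onset.all_day"] <- sl[["sleep_onset"]]
  all_vals["sleep.sleep_duration.all_day"] <- sl[["sleep_duration"]]
  all_vals["location.circadian_movement.night"] <-
    if (present[["location"]]) circadian_movement(history) else NA_real_

  ## order by catalog; any catalog feature not computed stays NA
  out_vals <- stats::setNames(rep(NA_real_, nrow(catalog)), catalog$name)
  common <- intersect(catalog$name, names(all_vals))
  out_vals[common] <- all_vals[common]

  ## missingness propagation: absent required stream forces NA
  for (i in seq_len(nrow(catalog))) {
    req <- strsplit(catalog$requires[i], ",")[[1]]
    if (!all(present[req])) out_vals[catalog$name[i]] <- NA_real_
  }

  row <- data.frame(participant_id = bundle$participant_id,
                    date = bundle$date, stringsAsFactors = FALSE)
  row <- cbind(row, as.data.frame(as.list(out_vals), check.names = FALSE))
  for (s in PUT_STREAMS) row[[paste0("avail_", s)]] <- unname(present[[s]])
  row
}

#' Extract features for a list of bundles
#'
#' @param bundles list of [event_bundle()] objects (one per
#'   participant-day).
#' @param catalog,map,params as in [extract_person_day()].
#' @param use_history compute circadian movement from each participant's
#'   trailing 7 days of location fixes (slower; default FALSE).
#' @return data.frame with one row per participant-day.
#' @export
extract_features <- function(bundles, catalog = feature_catalog(),
                             map = default_campus_map(),
                             params = extraction_params(),
                             use_history = FALSE) {
  hist_for <- function(i) {
    if (!use_history) return(NULL)
    b <- bundles[[i]]
    prev <- Filter(function(x) {
      x$participant_id == b$participant_id &&
        x$date < b$date && x$date >= b$date - 7 && x$present[["location"]] &&
        !is.null(x$location) && nrow(x$location) > 0
    }, bundles)
    if (length(prev) < 2L) return(NULL)
    do.call(rbind, lapply(prev, function(x) {
      data.frame(ts_abs = as.numeric(x$date - b$date) * 86400 + x$location$ts,
                 lat = x$location$lat, lon = x$location$lon)
    }))
  }
  rows <- lapply(seq_along(bundles), function(i) {
    extract_person_day(bundles[[i]], catalog, map, hist_for(i), params)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Names of the feature columns of a feature table
#' @param table a feature table from [extract_features()] or
#'   [generate_feature_table()].
#' @return character vector of catalog feature columns present in `table`.
#' @export
feature_columns <- function(table) {
  setdiff(names(table),
          c("participant_id", "date", "label", "put_true",
            grep("^avail_", names(table), value = TRUE),
            grep("^demo_", names(table), value = TRUE)))
}
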