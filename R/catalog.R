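## The feature catalog: every behavioral statistic crossed with its
## applicable epochs, plus per-stream sample counts. Feature names are
## "<stream>.<stat>.<epoch>"; canonical ordering is alphabetical by
## (stream, stat, epoch).

## base statistics per stream; sleep is daily-only, circadian movement
## needs multi-day history and is reported under the night epoch.
CATALOG_SPEC <- list(
  location = list(
    stats = c("off_campus_time", "off_campus_pct", "avg_stay_off_campus",
              "longest_stay_study", "avg_stay_green", "var_stay_green",
              "location_variance"),
    epochs = EPOCH_NAMES),
  screen = list(
    stats = c("screen_time", "n_unlocks", "first_unlock_time",
              "shortest_bout"),
    epochs = EPOCH_NAMES),
  steps = list(
    stats = c("total_steps", "n_active_bouts", "avg_steps_active_bout",
              "last_active_bout_end", "sedentary_time",
              "sedentary_bout_mean", "sedentary_bout_sd"),
    epochs = EPOCH_NAMES),
  calls = list(
    stats = c("n_missed_calls", "n_calls", "total_call_duration"),
    epochs = EPOCH_NAMES),
  wifi = list(stats = "n_unique_aps", epochs = EPOCH_NAMES),
  activity = list(stats = "physical_activity_duration", epochs = EPOCH_NAMES),
  sleep = list(stats = c("sleep_onset", "sleep_duration"),
               epochs = "all_day")
)

## duration/count statistics for which night+morning+afternoon+evening
## must equal all_day (within clipping rounding)
ADDITIVE_STATS <- c("off_campus_time", "screen_time", "n_unlocks",
                    "total_steps", "n_missed_calls", "n_calls",
                    "total_call_duration", "physical_activity_duration",
                    "indoor_mobility", "sample_count", "sedentary_time")

#' Build the canonical feature catalog
#'
#' Enumerates every base statistic across its applicable epochs, the fused
#' activity+location indoor-mobility feature, the multi-day circadian
#' movement feature (night epoch), and one sample-count feature per stream
#' and epoch (sleep: daily only). Sleep statistics are daily-only.
#'
#' @return data.frame with columns `name`, `stream`, `stat`, `epoch`,
#'   `requires` (comma-separated streams the feature needs), `additive`
#'   (does the statistic sum across the four 6-hour epochs), `intraday`
#'   (is the statistic resolved at every 6-hour epoch).
#' @export
feature_catalog <- function() {
  if (!is.null(.catalog_cache$cat)) return(.catalog_cache$cat)
  rows <- list()
  add <- function(stream, stat, epoch, requires) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = paste(stream, stat, epoch, sep = "."),
      stream = stream, stat = stat, epoch = epoch,
      requires = paste(requires, collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (stream in names(CATALOG_SPEC)) {
    sp <- CATALOG_SPEC[[stream]]
    for (stat in sp$stats) for (ep in sp$epochs) add(stream, stat, ep, stream)
  }
  for (ep in EPOCH_NAMES) {
    add("activity_location", "indoor_mobility", ep, c("activity", "location"))
  }
  add("location", "circadian_movement", "night", "location")
  for (stream in PUT_STREAMS) {
    eps <- if (stream == "sleep") "all_day" else EPOCH_NAMES
    for (ep in eps) add(stream, "sample_count", ep, stream)
  }
  cat <- do.call(rbind, rows)
  cat <- cat[order(cat$stream, cat$stat, cat$epoch), , drop = FALSE]
  rownames(cat) <- NULL
  cat$additive <- cat$stat %in% ADDITIVE_STATS
  ## intraday-resolvable: the stat exists at all four sub-epochs
  key <- paste(cat$stream, cat$stat)
  sub_counts <- table(key[cat$epoch %in% SUB_EPOCHS])
  cat$intraday <- key %in% names(sub_counts)[sub_counts == 4L]
  .catalog_cache$cat <- cat
  cat
}

.catalog_cache <- new.env(parent = emptyenv())
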