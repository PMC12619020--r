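test_that("epoch windows are half-open and events land where defined", {
  morning <- epoch_window("morning")
  ev <- data.frame(ts = c(hms(5, 59, 59), hms(6), hms(11, 59, 59), hms(12)))
  got <- segment_day(ev, morning)
  expect_equal(got$ts, c(hms(6), hms(11, 59, 59)))  # 06:00 is morning
  expect_equal(nrow(segment_day(ev[0, , drop = FALSE], morning)), 0)
  expect_error(segment_day(data.frame(ts = c(3, 1)), morning), "sorted")
})

test_that("interval clipping pro-rates durations at epoch edges", {
  aft <- epoch_window("afternoon"); eve <- epoch_window("evening")
  ## a 17:50-18:20 bout: 10 min to afternoon, 20 to evening
  expect_equal(clip_intervals(hms(17, 50), hms(18, 20), aft) / 60, 10)
  expect_equal(clip_intervals(hms(17, 50), hms(18, 20), eve) / 60, 20)
  set.seed(6)
  for (i in 1:50) {
    s <- runif(1, 0, 82800); e <- s + runif(1, 60, 7200)
    ep <- epoch_window(sample(putsense:::EPOCH_NAMES, 1))
    expect_equal(clip_intervals(s, e, ep) / 60,
                 oracle_clip_minutes(s, e, ep$start, ep$end),
                 tolerance = 1 / 60)
  }
})

test_that("screen features follow the on/off/unlock bout definitions", {
  aft <- epoch_window("afternoon")
  ev <- data.frame(ts = c(hms(13), hms(13, 0, 1), hms(13, 45)),
                   event = c("on", "unlock", "off"))
  f <- extract_screen_features(ev, aft)
  expect_equal(unname(f["screen_time"]), 45)
  expect_equal(unname(f["n_unlocks"]), 1)
  expect_equal(unname(f["first_unlock_time"]), hms(13, 0, 1))
  ## bouts of 3, 12, 7 minutes -> shortest bout 3
  mk <- function(h, len) data.frame(
    ts = c(hms(h), hms(h) + 1, hms(h) + len * 60),
    event = c("on", "unlock", "off"))
  ev2 <- do.call(rbind, list(mk(13, 3), mk(14, 12), mk(15, 7)))
  f2 <- extract_screen_features(ev2, aft)
  expect_equal(unname(f2["shortest_bout"]), 3, tolerance = 0.02)
  ## no events -> all screen features missing
  expect_true(all(is.na(extract_screen_features(
    data.frame(ts = numeric(0), event = character(0)), aft))))
  ## unmatched events are dropped by the repair rule
  ev3 <- data.frame(ts = c(hms(13), hms(13, 10), hms(13, 20)),
                    event = c("off", "on", "off"))
  expect_equal(unname(extract_screen_features(ev3, aft)["screen_time"]), 10)
})

test_that("step features encode run-length active/sedentary structure", {
  eve <- epoch_window("evening")
  v <- rep(NA_real_, 1440)
  v[(18 * 60 + 1):1440] <- 0
  v[(18 * 60 + 1):(18 * 60 + 5)] <- c(0, 0, 20, 30, 0)
  f <- extract_steps_features(v, eve)
  expect_equal(unname(f["total_steps"]), 50)
  expect_equal(unname(f["n_active_bouts"]), 1)
  expect_equal(unname(f["avg_steps_active_bout"]), 25)
  expect_equal(unname(f["last_active_bout_end"]), (18 * 60 + 4) * 60)
  ## all-zero minutes: one sedentary bout spanning the epoch
  z <- rep(0, 1440)
  fz <- extract_steps_features(z, eve)
  expect_equal(unname(fz["total_steps"]), 0)
  expect_equal(unname(fz["n_active_bouts"]), 0)
  expect_equal(unname(fz["sedentary_time"]), 360)
  expect_equal(unname(fz["sedentary_bout_mean"]), 360)
  ## sedentary runs of 10 and 30 minutes: mean 20, sample SD
  v2 <- rep(20, 1440)
  v2[(18 * 60 + 1):(18 * 60 + 10)] <- 0
  v2[(19 * 60 + 1):(19 * 60 + 30)] <- 0
  f2 <- extract_steps_features(v2, eve)
  expect_equal(unname(f2["sedentary_bout_mean"]), 20)
  expect_equal(unname(f2["sedentary_bout_sd"]), sd(c(10, 30)))
  expect_true(all(is.na(extract_steps_features(NULL, eve))))
})

test_that("call, Wi-Fi and Bluetooth-style counts are 0 when present-empty", {
  eve <- epoch_window("evening")
  f <- extract_call_features(
    data.frame(ts = numeric(0), type = character(0), duration = numeric(0)),
    eve)
  expect_equal(unname(f["n_missed_calls"]), 0)
  expect_equal(unname(f["n_calls"]), 0)
  calls <- data.frame(ts = c(hms(19), hms(20), hms(23)),
                      type = c("missed", "missed", "outgoing"),
                      duration = c(0, 0, 300))
  f2 <- extract_call_features(calls, eve)
  expect_equal(unname(f2["n_missed_calls"]), 2)
  expect_equal(unname(f2["total_call_duration"]), 5)
  wf <- data.frame(ts = hms(c(9, 9.5, 10)), ap_hash = c("a", "a", "b"))
  expect_equal(unname(extract_wifi_features(wf, epoch_window("morning"))),
               2)
  b <- fixture_bundle()
  expect_equal(putsense:::stream_sample_count(b, "bluetooth",
                                              epoch_window("morning")), 7)
})

test_that("location features recover off-campus dwell and stay points", {
  map <- default_campus_map()
  all_day <- epoch_window("all_day")
  on <- map$center
  off <- c(on[1] + 0.03, on[2])
  ## two off-campus fixes 30 min apart then one on-campus: 30 min dwell
  ## plus the gap-capped dwell of the last off-campus fix
  fixes <- data.frame(ts = c(hms(10), hms(10, 30), hms(11)),
                      lat = c(off[1], off[1], on[1]),
                      lon = c(off[2], off[2], on[2]))
  f <- extract_location_features(fixes, map, all_day)
  expect_equal(unname(f["off_campus_time"]), 30 + 15)
  ## all fixes inside campus: zero off-campus time and share
  fixes_on <- data.frame(ts = hms(c(10, 11, 12)), lat = on[1], lon = on[2])
  f2 <- extract_location_features(fixes_on, map, all_day)
  expect_equal(unname(f2["off_campus_time"]), 0)
  expect_equal(unname(f2["off_campus_pct"]), 0)
  ## a 40-minute dwell at the library registers as a study stay
  lib <- c(map$study$lat[1], map$study$lon[1])
  fixes_s <- data.frame(ts = hms(10) + seq(0, 2400, by = 300),
                        lat = lib[1], lon = lib[2])
  f3 <- extract_location_features(fixes_s, map, all_day)
  expect_equal(unname(f3["longest_stay_study"]), 40)
  expect_true(is.na(extract_location_features(
    fixes[0, , drop = FALSE], map, all_day)["off_campus_time"]))
})

test_that("fused indoor mobility needs both streams and overlays traces", {
  map <- default_campus_map()
  all_day <- epoch_window("all_day")
  bld <- c(map$buildings$lat[1], map$buildings$lon[1])
  outd <- c(map$center[1], map$center[2])
  ## 20 one-minute walking samples; the first 12 are inside a building
  act <- data.frame(ts = hms(10) + 60 * (0:19), class = "walking")
  fixes <- data.frame(ts = hms(10) + 60 * (0:19),
                      lat = c(rep(bld[1], 12), rep(outd[1], 8)),
                      lon = c(rep(bld[2], 12), rep(outd[2], 8)))
  f <- extract_activity_features(act, fixes, map, all_day)
  expect_equal(unname(f["physical_activity_duration"]), 20, tolerance = 0.3)
  expect_equal(unname(f["indoor_mobility"]), 12, tolerance = 0.3)
  ## location absent: fused missing, activity duration still computed
  f2 <- extract_activity_features(act, NULL, map, all_day)
  expect_false(is.na(f2["physical_activity_duration"]))
  expect_true(is.na(f2["indoor_mobility"]))
  ## all-still activity: both zero
  act3 <- data.frame(ts = hms(10) + 60 * (0:9), class = "still")
  f3 <- extract_activity_features(act3, fixes, map, all_day)
  expect_equal(unname(f3["physical_activity_duration"]), 0)
})

test_that("sleep features follow the onset-day encoding convention", {
  s1 <- data.frame(onset_ts = hms(23, 30), offset_ts = hms(23, 30) + 25200,
                   minute_count = 420)
  f1 <- extract_sleep_features(s1)
  expect_equal(unname(f1["sleep_onset"]), 84600)  # 23:30 on the onset day
  ## onset 01:10 next morning (attributed to this day) encodes as 4200
  s2 <- data.frame(onset_ts = 86400 + hms(1, 10),
                   offset_ts = 86400 + hms(1, 10) + 420 * 60,
                   minute_count = 420)
  f2 <- extract_sleep_features(s2)
  expect_equal(unname(f2["sleep_onset"]), 4200)
  expect_equal(unname(f2["sleep_duration"]), 420)
  expect_true(all(is.na(extract_sleep_features(NULL))))
})

test_that("person-day extraction matches the catalog schema exactly", {
  b <- fixture_bundle()
  row <- extract_person_day(b)
  catalog <- feature_catalog()
  expect_identical(feature_columns(row), catalog$name)
  ## spot-check golden values traced by hand from the fixture
  expect_equal(row[["screen.screen_time.afternoon"]], 45)
  expect_equal(row[["wifi.n_unique_aps.morning"]], 2)
  expect_equal(row[["calls.n_missed_calls.evening"]], 1)
  expect_equal(row[["steps.total_steps.evening"]], 50)
  expect_equal(row[["sleep.sleep_onset.all_day"]], 84600)
  expect_equal(row[["bluetooth.sample_count.morning"]], 7)
  ## circadian movement needs a multi-day buffer; absent here
  expect_true(is.na(row[["location.circadian_movement.night"]]))
})

test_that("missingness propagates from streams to features and counts", {
  b <- fixture_bundle()
  b$location <- NULL; b["location"] <- list(NULL)
  b$present[["location"]] <- FALSE
  row <- extract_person_day(b)
  catalog <- feature_catalog()
  loc_feats <- catalog$name[grepl("location", catalog$requires)]
  expect_true(all(is.na(row[, loc_feats])))
  ## fused features require both streams
  expect_true(is.na(row[["activity_location.indoor_mobility.all_day"]]))
  expect_false(is.na(row[["activity.physical_activity_duration.morning"]]))
  expect_false(row$avail_location)
  ## present-but-empty stream: sample count 0, statistics missing
  b2 <- fixture_bundle()
  b2$calls <- data.frame(ts = numeric(0), type = character(0),
                         duration = numeric(0))
  row2 <- extract_person_day(b2)
  expect_equal(row2[["calls.sample_count.all_day"]], 0)
  expect_equal(row2[["calls.n_missed_calls.evening"]], 0)
})

test_that("duration and count features are additive across the four epochs", {
  set.seed(13)
  cc <- cohort_config(n_participants = 2, n_days = 2, seed = 31)
  pp <- sample_participants(cc)
  catalog <- feature_catalog()
  add_feats <- catalog[catalog$additive & catalog$epoch == "all_day" &
                         catalog$stream != "sleep", ]
  for (i in 1:2) {
    sim <- synthesize_day_events(pp[i, ], as.Date("2018-01-10") + i, i == 1,
                                 seed = 31)
    row <- extract_person_day(sim$bundle)
    for (j in seq_len(nrow(add_feats))) {
      base <- paste(add_feats$stream[j], add_feats$stat[j], sep = ".")
      parts <- vapply(putsense:::SUB_EPOCHS, function(ep)
        row[[paste0(base, ".", ep)]], numeric(1))
      total <- row[[paste0(base, ".all_day")]]
      if (anyNA(parts) || is.na(total)) next
      expect_equal(sum(parts), total, tolerance = 1.01,
                   label = sprintf("additivity of %s", base))
    }
  }
})

test_that("removing events never increases count or duration features", {
  b <- fixture_bundle()
  full <- extract_person_day(b)
  b_less <- b
  b_less$calls <- b$calls[1, , drop = FALSE]
  b_less$bluetooth <- b$bluetooth[1:3, , drop = FALSE]
  b_less$wifi <- b$wifi[1:2, , drop = FALSE]
  less <- extract_person_day(b_less)
  mono <- c("calls.n_calls.all_day", "calls.n_missed_calls.all_day",
            "bluetooth.sample_count.all_day", "wifi.n_unique_aps.all_day")
  for (f in mono) expect_lte(less[[f]], full[[f]])
})

test_that("brute-force interval sweep agrees on small mixed fixtures", {
  ## oracle: per-minute sweep of screen-on time vs the clipped-bout route
  aft <- epoch_window("afternoon")
  set.seed(17)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    on_ts <- sort(runif(k, hms(11), hms(18)))
    len <- runif(k, 120, 2400)
    len <- pmin(len, c(diff(on_ts), Inf) - 1)
    ev <- do.call(rbind, lapply(seq_len(k), function(j) {
      data.frame(ts = c(on_ts[j], on_ts[j] + len[j]),
                 event = c("on", "off"))
    }))
    got <- unname(extract_screen_features(ev, aft)["screen_time"])
    want <- sum(vapply(seq_len(k), function(j)
      oracle_clip_minutes(on_ts[j], on_ts[j] + len[j], aft$start, aft$end),
      numeric(1)))
    expect_equal(got, want, tolerance = 0.05)
  }
})
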