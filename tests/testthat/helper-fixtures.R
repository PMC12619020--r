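## Shared fixture builders (all generated in code; nothing on disk).

## a minimal hand-specified bundle whose features can be traced by hand
fixture_bundle <- function() {
  map <- default_campus_map()
  on1 <- map$center  # on campus
  off1 <- c(map$center[1] + 0.03, map$center[2])  # ~3.3 km north
  event_bundle(
    "F1", as.Date("2018-02-05"),
    location = data.frame(
      ts = c(hms(10), hms(10, 30), hms(11)),
      lat = c(off1[1], off1[1], on1[1]),
      lon = c(off1[2], off1[2], on1[2])),
    activity = data.frame(
      ts = c(hms(10), hms(10, 5), hms(10, 10)),
      class = c("still", "walking", "still")),
    screen = data.frame(
      ts = c(hms(13), hms(13, 0, 1), hms(13, 45)),
      event = c("on", "unlock", "off")),
    calls = data.frame(ts = c(hms(19), hms(20)),
                       type = c("missed", "outgoing"),
                       duration = c(0, 120)),
    bluetooth = data.frame(ts = hms(c(7, 8, 9, 9.5, 10, 10.5, 11)),
                           device_hash = paste0("d", 1:7)),
    wifi = data.frame(ts = hms(c(9, 9.5, 10)),
                      ap_hash = c("a", "a", "b")),
    battery = data.frame(ts = hms(c(0, 12)), level = c(90, 60)),
    steps = {
      v <- numeric(1440)
      v[(18 * 60 + 1):(18 * 60 + 5)] <- c(0, 0, 20, 30, 0)
      v
    },
    sleep = data.frame(onset_ts = hms(23, 30),
                       offset_ts = hms(23, 30) + 420 * 60,
                       minute_count = 420))
}

## tiny labeled feature table for assembly tests: one participant, a run
## of consecutive days with controllable labels and missingness
fixture_table <- function(labels, features = paste0("f", 1:4),
                          pid = "P1", start = as.Date("2018-01-08")) {
  n <- length(labels)
  tab <- data.frame(participant_id = pid, date = start + seq_len(n) - 1,
                    stringsAsFactors = FALSE)
  for (f in features) tab[[f]] <- stats::rnorm(n)
  for (s in putsense:::PUT_STREAMS) tab[[paste0("avail_", s)]] <- TRUE
  tab$label <- labels
  tab
}

## toy sequence set: n sequences of dim T x F with given labels; values
## N(0,1), fully observed unless a mask function is supplied
fixture_sequences <- function(labels, Tn = 4, nf = 3, mode = "multiday",
                              seed = 1) {
  set.seed(seed)
  n <- length(labels)
  vals <- array(stats::rnorm(n * Tn * nf), c(n, Tn, nf),
                dimnames = list(NULL, NULL, paste0("f", seq_len(nf))))
  mask <- array(TRUE, c(n, Tn, nf))
  meta <- data.frame(participant_id = rep("P1", n),
                     target_date = as.Date("2018-01-08") + seq_len(n) - 1,
                     label = labels, stringsAsFactors = FALSE)
  putsense:::sequence_samples(vals, mask, meta, mode,
                              if (mode == "multiday") Tn else NA)
}
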