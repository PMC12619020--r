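## Synthetic cohort generator: seeded event-level sensor streams, EMA
## responses, demographics and ground truth with the statistical structure
## the downstream analysis assumes (rare PUT days, small-to-moderate
## behavioral shifts, stream-day missingness).

#' Per-stream availability defaults
#'
#' Daily probability that a stream produces any data, per stream.
#' @return named numeric vector over the nine streams.
#' @export
default_availability_rates <- function() {
  c(activity = 0.4993, battery = 0.4361, bluetooth = 0.4865,
    calls = 0.3505, location = 0.5108, screen = 0.5185,
    wifi = 0.5244, sleep = 0.6517, steps = 0.7052)
}

#' Default PUT effect profile (standardized mean differences)
#'
#' Signed SMD targets for the behavioral shifts injected on PUT days:
#' more time off campus, higher evening/night activity, longer afternoon
#' screen time, more evening missed calls, fewer morning Bluetooth
#' detections, less indoor mobility on campus, later sleep onset and
#' shorter sleep. All |SMD| <= 0.5 (small-to-moderate effects).
#' @return named numeric vector keyed by catalog feature name.
#' @export
default_effect_profile <- function() {
  c("location.off_campus_time.all_day"            =  0.44,
    "steps.total_steps.evening"                   =  0.38,
    "activity.sample_count.night"                 =  0.33,
    "screen.screen_time.afternoon"                =  0.41,
    "bluetooth.sample_count.morning"              = -0.20,
    "calls.n_missed_calls.evening"                =  0.25,
    "activity_location.indoor_mobility.all_day"   = -0.24,
    "location.avg_stay_off_campus.all_day"        =  0.29,
    "location.off_campus_pct.all_day"             =  0.32,
    "steps.sedentary_time.evening"                = -0.42,
    "activity.physical_activity_duration.evening" =  0.37,
    "steps.avg_steps_active_bout.evening"         =  0.28,
    "location.off_campus_time.morning"            =  0.42,
    "steps.n_active_bouts.all_day"                =  0.21,
    "screen.shortest_bout.night"                  =  0.21,
    "sleep.sleep_onset.all_day"                   =  0.11,
    "sleep.sleep_duration.all_day"                = -0.25,
    "sleep.sample_count.all_day"                  = -0.11)
}

#' Cohort configuration
#'
#' @param n_participants number of participants (default 201).
#' @param n_days study days per participant (default 70, one 10-week term).
#' @param mean_put_rate mean per-user probability of a PUT day (default
#'   0.0466).
#' @param put_rate_concentration Beta concentration of per-user PUT rates
#'   (default 5; chosen so the simulated across-user 95% range of rates
#'   brackets roughly 3%-6%).
#' @param effect_profile named SMD vector, see [default_effect_profile()].
#' @param availability_rates named per-stream availability probabilities.
#' @param ema_schedule list `twice_weekly_weeks`, `daily_block_weeks`.
#' @param compliance_rate probability a participant-day is "compliant"
#'   (device recording at all): streams are dropped jointly on
#'   non-compliant days and retained with probability `rate /
#'   compliance_rate` on compliant days, preserving the per-stream
#'   marginals while inducing the strong cross-stream correlation real
#'   compliance shows. Set to 1 for fully independent stream drops.
#' @param nonresponse probability an EMA prompt goes unanswered.
#' @param label_noise probability an answered EMA contradicts the truth.
#' @param icc intraclass correlation of the fast-path feature model
#'   (between-user share of unit total variance).
#' @param start_date first study day (a Monday).
#' @param seed integer root seed.
#' @return a validated `put_cohort_config` list.
#' @export
cohort_config <- function(n_participants = 201, n_days = 70,
                          mean_put_rate = 0.0466,
                          put_rate_concentration = 5,
                          effect_profile = default_effect_profile(),
                          availability_rates = default_availability_rates(),
                          ema_schedule = list(twice_weekly_weeks = 8,
                                              daily_block_weeks = 2),
                          compliance_rate = 0.705,
                          nonresponse = 0.2, label_noise = 0,
                          icc = 0.5,
                          start_date = as.Date("2018-01-08"),
                          seed = 1L) {
  check_count(n_participants, min = 1L)
  check_count(n_days, min = 1L)
  check_prob(mean_put_rate)
  check_prob(nonresponse)
  check_prob(label_noise)
  check_prob(icc)
  stopifnot(put_rate_concentration > 0)
  if (!all(names(availability_rates) %in% PUT_STREAMS)) {
    stop("unknown stream in availability_rates: ",
         paste(setdiff(names(availability_rates), PUT_STREAMS), collapse = ", "))
  }
  for (r in availability_rates) check_prob(r, "availability rate")
  check_prob(compliance_rate)
  if (compliance_rate <= 0) stop("compliance_rate must be positive")
  structure(list(n_participants = as.integer(n_participants),
                 n_days = as.integer(n_days),
                 mean_put_rate = mean_put_rate,
                 put_rate_concentration = put_rate_concentration,
                 effect_profile = effect_profile,
                 availability_rates = availability_rates[PUT_STREAMS],
                 compliance_rate = compliance_rate,
                 ema_schedule = ema_schedule,
                 nonresponse = nonresponse, label_noise = label_noise,
                 icc = icc, start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "put_cohort_config")
}

## latent routine constants: population mean / user-level SD / day-level SD
## (plus dispersion for counts). Population SDs derived from these feed the
## SMD-scaled shifts, so injected effects land near the configured targets.
routine_constants <- function() {
  k <- list(
    off_campus = list(m_dorm = 300, m_comm = 800, p_dorm = 0.5,
                      sd_user = 120, sd_day = 200, weekend_add = 120),
    ev_steps   = list(mean = 3100, sd_user = 1500, sd_day = 1800),
    aft_screen = list(mean = 90, sd_user = 25, sd_day = 55),
    ev_missed  = list(mean = 0.8, size = 0.5),
    mo_bt      = list(mean = 45.9, size = 0.19),
    ni_act     = list(mean = 139.6, size = 2.15),
    indoor     = list(mean = 65, sd_user = 40, sd_day = 58),
    onset_s    = list(mean = 23.75 * 3600, sd_user = 2400, sd_day = 2700),
    dur_min    = list(mean = 450, sd_user = 35, sd_day = 45),
    ev_pa      = list(mean = 65, sd_user = 30, sd_day = 45)
  )
  nb_sd <- function(x) sqrt(x$mean + x$mean^2 / x$size)
  mix <- k$off_campus
  k$pop_sd <- c(
    off_campus = sqrt(mix$p_dorm * (1 - mix$p_dorm) *
                        (mix$m_comm - mix$m_dorm)^2 +
                      mix$sd_user^2 + mix$sd_day^2 +
                      (2 / 7) * (5 / 7) * mix$weekend_add^2),
    ev_steps = sqrt(k$ev_steps$sd_user^2 + k$ev_steps$sd_day^2),
    aft_screen = sqrt(k$aft_screen$sd_user^2 + k$aft_screen$sd_day^2),
    ev_missed = nb_sd(k$ev_missed),
    mo_bt = nb_sd(k$mo_bt),
    ni_act = nb_sd(k$ni_act),
    indoor = sqrt(k$indoor$sd_user^2 + k$indoor$sd_day^2),
    onset_s = sqrt(k$onset_s$sd_user^2 + k$onset_s$sd_day^2),
    dur_min = sqrt(k$dur_min$sd_user^2 + k$dur_min$sd_day^2),
    ev_pa = sqrt(k$ev_pa$sd_user^2 + k$ev_pa$sd_day^2)
  )
  k
}

## map the feature-keyed effect profile onto latent-routine shifts.
## several shifts carry pilot-derived correction factors compensating SMD
## attenuation (zero-truncation, count dispersion growth, schedule caps),
## so realized effect sizes land near the configured targets.
latent_shifts <- function(effect_profile) {
  k <- routine_constants()
  get <- function(f) unname(effect_profile[f] %|0|% 0)
  c(off_campus = get("location.off_campus_time.all_day") * k$pop_sd[["off_campus"]] * 1.15,
    ev_steps   = get("steps.total_steps.evening") * k$pop_sd[["ev_steps"]],
    aft_screen = get("screen.screen_time.afternoon") * k$pop_sd[["aft_screen"]],
    ev_missed  = get("calls.n_missed_calls.evening") * k$pop_sd[["ev_missed"]] * 1.5,
    mo_bt      = get("bluetooth.sample_count.morning") * k$pop_sd[["mo_bt"]],
    ni_act     = get("activity.sample_count.night") * k$pop_sd[["ni_act"]],
    indoor     = get("activity_location.indoor_mobility.all_day") * k$pop_sd[["indoor"]] * 0.45,
    onset_s    = get("sleep.sleep_onset.all_day") * k$pop_sd[["onset_s"]],
    dur_min    = get("sleep.sleep_duration.all_day") * k$pop_sd[["dur_min"]],
    ev_pa      = get("activity.physical_activity_duration.evening") * k$pop_sd[["ev_pa"]] * 1.13)
}

`%|0|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Sample per-user PUT rates and day-level PUT flags
#'
#' Per-user rates are Beta-distributed with the configured mean and
#' concentration; day flags are i.i.d. Bernoulli within user.
#'
#' @param n_participants,n_days cohort dimensions.
#' @param mean_rate mean PUT probability across users, in `[0, 1)`.
#' @param concentration Beta concentration (> 0).
#' @param seed integer seed.
#' @return list with `flags` (n_participants x n_days logical matrix) and
#'   `rates` (per-user probabilities).
#' @export
sample_put_labels <- function(n_participants, n_days, mean_rate,
                              concentration = 5, seed = 1L) {
  check_prob(mean_rate)
  if (mean_rate >= 1) stop("mean_rate must be < 1")
  stopifnot(concentration > 0)
  set.seed(derive_seed(seed, "put_labels"))
  if (mean_rate == 0) {
    return(list(flags = matrix(FALSE, n_participants, n_days),
                rates = rep(0, n_participants)))
  }
  rates <- stats::rbeta(n_participants, mean_rate * concentration,
                        (1 - mean_rate) * concentration)
  flags <- matrix(stats::rbinom(n_participants * n_days, 1L,
                                rep(rates, times = n_days)) == 1L,
                  nrow = n_participants, ncol = n_days)
  list(flags = flags, rates = rates)
}

#' Sample the participant roster
#'
#' Demographics emulate a first-year undergraduate cohort (age about
#' 18-19, 64.7% female) and each participant gets latent routine
#' parameters: a home anchor (on-campus dorm or off-campus commute),
#' habitual sleep onset/offset, mean daily steps, screen-use propensity
#' and user-level components of the calibrated behavioral quantities.
#'
#' @param config a [cohort_config()].
#' @param map a [campus_map()].
#' @return data.frame with one row per participant.
#' @export
sample_participants <- function(config, map = default_campus_map()) {
  set.seed(derive_seed(config$seed, "participants"))
  n <- config$n_participants
  k <- routine_constants()
  dorm <- stats::runif(n) < k$off_campus$p_dorm
  ## home anchors: dorm inside campus, commuters 1.5-4 km out
  bearing <- stats::runif(n, 0, 2 * pi)
  dist_m <- ifelse(dorm, stats::runif(n, 100, 700),
                   stats::runif(n, 1500, 4000))
  lat0 <- map$center[1]; lon0 <- map$center[2]
  home_lat <- lat0 + dist_m * cos(bearing) / 111320
  home_lon <- lon0 + dist_m * sin(bearing) /
    (111320 * cos(lat0 * pi / 180))
  onset <- k$onset_s$mean + stats::rnorm(n, 0, k$onset_s$sd_user)
  ## habitual onset constrained to 20:00-04:00 (encoded past midnight)
  onset <- pmin(pmax(onset, hms(20)), hms(28) - 1)
  gender <- sample(c("female", "male", "nonbinary"), n, replace = TRUE,
                   prob = c(0.647, 0.3, 0.053))
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = pmax(18, round(stats::rnorm(n, 18.4, 0.56))),
    gender = gender,
    first_generation = stats::runif(n) < 0.22,
    disability = stats::runif(n) < 0.12,
    home_lat = home_lat, home_lon = home_lon, dorm = dorm,
    onset_base_s = onset,
    dur_base_min = k$dur_min$mean + stats::rnorm(n, 0, k$dur_min$sd_user),
    steps_daily_mean = pmax(2000, stats::rnorm(n, 8000, 2000)),
    offc_user = ifelse(dorm, k$off_campus$m_dorm, k$off_campus$m_comm) +
      stats::rnorm(n, 0, k$off_campus$sd_user),
    ev_steps_user = k$ev_steps$mean + stats::rnorm(n, 0, k$ev_steps$sd_user),
    aft_screen_user = pmax(10, k$aft_screen$mean +
                             stats::rnorm(n, 0, k$aft_screen$sd_user)),
    indoor_user = k$indoor$mean + stats::rnorm(n, 0, k$indoor$sd_user),
    ev_pa_user = k$ev_pa$mean + stats::rnorm(n, 0, k$ev_pa$sd_user),
    stringsAsFactors = FALSE)
}

## ---- day-level latent routine --------------------------------------------

## draw the latent quantities of one participant-day; `sh` are the additive
## shifts applied when put_flag is TRUE (zero vector otherwise)
draw_day_latents <- function(p, date, put_flag, shifts) {
  k <- routine_constants()
  sh <- if (put_flag) shifts else shifts * 0
  weekend <- format(date, "%u") %in% c("6", "7")
  rnb <- function(mean, size) {
    stats::rnbinom(1, size = size, mu = max(mean, 0.05))
  }
  onset_s <- p$onset_base_s + stats::rnorm(1, 0, k$onset_s$sd_day) +
    sh[["onset_s"]]
  onset_s <- min(max(onset_s, hms(20)), hms(29.5))
  dur_min <- p$dur_base_min + stats::rnorm(1, 0, k$dur_min$sd_day) +
    sh[["dur_min"]]
  dur_min <- min(max(dur_min, 180), 720)
  off <- p$offc_user + stats::rnorm(1, 0, k$off_campus$sd_day) +
    (if (weekend) k$off_campus$weekend_add else 0) + sh[["off_campus"]]
  list(
    onset_s = onset_s, dur_min = dur_min,
    wake_min = 465 + round(stats::rnorm(1, 0, 40)),  # ~07:45
    off_campus_min = min(max(off, 0), 1380),
    ev_steps = max(0, p$ev_steps_user + stats::rnorm(1, 0, k$ev_steps$sd_day) +
                     sh[["ev_steps"]]),
    aft_screen = min(max(p$aft_screen_user +
                           stats::rnorm(1, 0, k$aft_screen$sd_day) +
                           sh[["aft_screen"]], 0), 350),
    ev_missed = rnb(k$ev_missed$mean + sh[["ev_missed"]], k$ev_missed$size),
    mo_bt = rnb(k$mo_bt$mean + sh[["mo_bt"]], k$mo_bt$size),
    ni_act = rnb(k$ni_act$mean + sh[["ni_act"]], k$ni_act$size),
    indoor_min = max(0, p$indoor_user + stats::rnorm(1, 0, k$indoor$sd_day) +
                       sh[["indoor"]]),
    ev_pa = max(0, p$ev_pa_user + stats::rnorm(1, 0, k$ev_pa$sd_day) +
                  sh[["ev_pa"]]),
    weekend = weekend)
}

## minute-state timeline for one day given the latents.
## states: sleep, home, campus_building, campus_study, campus_green,
## campus_walk_in, campus_walk_out, out
day_timeline <- function(p, lat) {
  state <- rep("home", 1440L)
  wake <- min(max(lat$wake_min, 300L), 720L)
  state[seq_len(wake)] <- "sleep"
  waking <- 1440L - wake
  off_wake <- lat$off_campus_min - (if (!p$dorm) wake else 0)
  off_wake <- min(max(round(off_wake), 0L), waking)
  campus_min <- waking - off_wake
  if (campus_min > 0L) {
    idx <- wake + seq_len(campus_min)
    ## interior structure: walking transitions spread over the block
    ## (enough of them to carry the indoor-mobility target), remaining
    ## minutes split across building / study / green blocks
    m <- length(idx)
    indoor_target <- round(lat$indoor_min)
    n_walk <- min(indoor_target + 15L, floor(0.5 * m))
    walk_pos <- if (n_walk > 0L) unique(round(seq(1L, m, length.out = n_walk)))
                else integer(0)
    n_walk <- length(walk_pos)
    indoor_target <- min(indoor_target, n_walk)
    walk_state <- rep("campus_walk_out", n_walk)
    if (indoor_target > 0L) walk_state[seq_len(indoor_target)] <- "campus_walk_in"
    block <- rep(c("campus_building", "campus_study", "campus_green"),
                 times = c(24L, 12L, 6L))
    st <- rep(block, length.out = m)
    st[walk_pos] <- walk_state
    state[idx] <- st
  }
  if (off_wake > 0L) {
    ## off-campus waking time at the end of the day: dorm residents leave
    ## campus ("out"); commuters are home (off campus) with optional outing
    idx <- (1440L - off_wake + 1L):1440L
    if (p$dorm) {
      state[idx] <- "out"
    } else {
      state[idx] <- "home"
      if (off_wake > 60L && stats::runif(1) < 0.6) {
        out_len <- min(off_wake - 30L, 60L + stats::rgeom(1, 1 / 60))
        state[idx[seq_len(out_len)]] <- "out"
      }
    }
  }
  state
}

## anchor coordinates (lat, lon) for each minute state
state_anchor <- function(state, p, map, out_anchor) {
  bz <- map$buildings; sz <- map$study; gz <- map$green
  b_pick <- sample(nrow(bz), 1); s_pick <- sample(nrow(sz), 1)
  g_pick <- sample(nrow(gz), 1)
  anchors <- rbind(
    sleep = c(p$home_lat, p$home_lon),
    home = c(p$home_lat, p$home_lon),
    campus_building = c(bz$lat[b_pick], bz$lon[b_pick]),
    campus_walk_in = c(bz$lat[b_pick], bz$lon[b_pick]),
    campus_study = c(sz$lat[s_pick], sz$lon[s_pick]),
    campus_green = c(gz$lat[g_pick], gz$lon[g_pick]),
    campus_walk_out = map$center,
    out = out_anchor)
  idx <- match(state, rownames(anchors))
  list(lat = anchors[idx, 1], lon = anchors[idx, 2])
}

## allocate a step total over the awake minutes of one epoch: active
## bursts (>= 10 steps/min) carrying most of the volume plus a low
## background on remaining minutes
allocate_steps <- function(steps, ep_minutes, awake, total) {
  cand <- ep_minutes[awake[ep_minutes + 1L]]
  if (length(cand) == 0L || total <= 0) return(steps)
  ## busier epochs carry more active bursts, so sedentary time falls as
  ## step volume rises (the emergent Box-1 direction)
  n_burst <- max(1L, stats::rpois(1, 1 + total / 900))
  burst_total <- round(0.85 * total)
  starts <- sort(sample(cand, min(n_burst, length(cand))))
  per <- stats::rmultinom(1, burst_total, rep(1, length(starts)))[, 1]
  for (b in seq_along(starts)) {
    len <- min(3L + stats::rgeom(1, 0.3), 12L)
    mins <- starts[b] + 0:(len - 1L)
    mins <- mins[mins <= max(ep_minutes)]
    if (length(mins) == 0L) next
    add <- stats::rmultinom(1, per[b], rep(1, length(mins)))[, 1]
    ## keep burst minutes at >= 10 steps so they register as active
    add <- add + 10L
    steps[mins + 1L] <- steps[mins + 1L] + add
  }
  bg <- setdiff(cand, unlist(lapply(seq_along(starts), function(b)
    starts[b] + 0:11)))
  if (length(bg) > 0L) {
    k <- min(length(bg), max(1L, round(total - burst_total) %/% 4L))
    pick <- sample(bg, k)
    steps[pick + 1L] <- steps[pick + 1L] + sample(0:9, k, replace = TRUE)
  }
  steps
}

## screen bouts totalling `total_min` inside [start_s, end_s): returns
## event rows (on, unlock, off)
emit_screen_bouts <- function(total_min, start_s, end_s) {
  if (total_min <= 0.5) return(NULL)
  k <- max(1L, round(total_min / 8))
  lens <- stats::rexp(k, 1)
  lens <- lens / sum(lens) * total_min * 60
  span <- end_s - start_s
  free <- span - sum(lens)
  if (free <= 0) {
    lens <- lens * (span * 0.9) / sum(lens)
    free <- span - sum(lens)
  }
  gaps <- stats::runif(k + 1)
  gaps <- gaps / sum(gaps) * free
  on_ts <- start_s + cumsum(gaps)[seq_len(k)] +
    c(0, cumsum(lens))[seq_len(k)]
  off_ts <- on_ts + lens
  data.frame(ts = as.vector(rbind(on_ts, on_ts + 1, off_ts)),
             event = rep(c("on", "unlock", "off"), k))
}

#' Synthesize one participant-day's raw event streams
#'
#' Generates a latent daily routine (sleep, campus blocks, off-campus
#' time) and emits events for all nine streams. When `put_flag` is TRUE,
#' the latent routine is shifted in the configured directions, with
#' magnitudes `SMD * population SD` so cohort-level effect sizes land
#' near `effect_profile`.
#'
#' @param participant one row of [sample_participants()].
#' @param date a `Date`.
#' @param put_flag logical: is this a PUT day.
#' @param effect_profile named SMD vector (see
#'   [default_effect_profile()]).
#' @param seed integer seed; identical inputs give identical bundles.
#' @param map a [campus_map()].
#' @return list with `bundle` (a [event_bundle()]) and
#'   `injected_effects` (named latent shifts; empty when `put_flag` is
#'   FALSE).
#' @export
synthesize_day_events <- function(participant, date, put_flag,
                                  effect_profile = default_effect_profile(),
                                  seed = 1L, map = default_campus_map()) {
  p <- as.list(participant)
  set.seed(derive_seed(seed, paste0("day:", p$participant_id, ":",
                                    format(as.Date(date)))))
  shifts <- latent_shifts(effect_profile)
  lat <- draw_day_latents(p, as.Date(date), put_flag, shifts)
  state <- day_timeline(p, lat)
  out_anchor <- c(map$center[1] + stats::rnorm(1, 0, 0.02),
                  map$center[2] + stats::rnorm(1, 0, 0.02))
  anch <- state_anchor(state, p, map, out_anchor)
  awake <- state != "sleep"
  wake_min <- sum(!awake)

  ## location: a fix every 5 minutes, jittered ~15 m
  fix_min <- seq(0L, 1439L, by = 5L)
  jit <- 15 / 111320
  location <- data.frame(
    ts = fix_min * 60 + stats::runif(length(fix_min), 0, 59),
    lat = anch$lat[fix_min + 1L] + stats::rnorm(length(fix_min), 0, jit),
    lon = anch$lon[fix_min + 1L] + stats::rnorm(length(fix_min), 0, jit))

  ## activity: night count is calibrated; daytime sampled every ~75 s
  ## while awake; class follows the walking states plus the evening
  ## physical-activity target
  ni_ts <- sort(stats::runif(lat$ni_act, 0, 21600))
  day_ts <- seq(21600, 86399, by = 75)
  day_ts <- day_ts[awake[pmin(day_ts %/% 60 + 1L, 1440L)]]
  day_min <- day_ts %/% 60 + 1L
  cls <- rep("still", length(day_ts))
  walk_states <- c("campus_walk_in", "campus_walk_out")
  cls[state[day_min] %in% walk_states] <- "walking"
  ## evening physical activity: mark minutes as walking/running until the
  ## target is covered (75 s cadence ~ 0.8 samples/minute)
  ev_idx <- which(day_ts >= 64800)
  need <- round(lat$ev_pa * 0.8)
  if (length(ev_idx) > 0L && need > 0L) {
    pick <- ev_idx[seq_len(min(need, length(ev_idx)))]
    cls[pick] <- sample(c("walking", "running"), length(pick),
                        replace = TRUE, prob = c(0.8, 0.2))
  }
  activity <- data.frame(ts = c(ni_ts, day_ts),
                         class = c(rep("still", length(ni_ts)), cls))
  activity <- activity[order(activity$ts), ]

  ## steps: per-minute vector from per-epoch totals
  steps <- numeric(1440L)
  day_total <- max(0, p$steps_daily_mean * exp(stats::rnorm(1, 0, 0.25)))
  targets <- c(night = 0.02 * day_total, morning = 0.33 * day_total,
               afternoon = 0.37 * day_total, evening = lat$ev_steps)
  for (ep in SUB_EPOCHS) {
    b <- EPOCH_BOUNDS[[ep]]
    steps <- allocate_steps(steps, seq.int(b[1] %/% 60, b[2] %/% 60 - 1L),
                            awake, targets[[ep]])
  }

  ## screen: calibrated afternoon total plus morning/evening/night bouts
  pre_sleep_end <- min(lat$onset_s, 107000)
  screen <- rbind(
    emit_screen_bouts(stats::rnorm(1, 35, 12), wake_min * 60 + 300, 43200),
    emit_screen_bouts(lat$aft_screen, 43200, 64800),
    emit_screen_bouts(stats::rnorm(1, 70, 25), 64800, 86400),
    if (pre_sleep_end > 86700) {
      emit_screen_bouts(min((pre_sleep_end - 86400) / 60, 25),
                        86400, pre_sleep_end)
    })
  if (!is.null(screen)) {
    screen <- screen[order(screen$ts), ]
    screen <- screen[screen$ts < 30 * 3600, , drop = FALSE]
  }

  ## calls: calibrated evening missed calls plus background traffic
  n_bg <- stats::rpois(1, 2)
  call_rows <- list()
  if (n_bg > 0L) {
    ts <- stats::runif(n_bg, wake_min * 60, 86399)
    call_rows[[1]] <- data.frame(
      ts = ts, type = sample(c("incoming", "outgoing"), n_bg, TRUE),
      duration = stats::rexp(n_bg, 1 / 180))
  }
  if (lat$ev_missed > 0L) {
    call_rows[[2]] <- data.frame(
      ts = stats::runif(lat$ev_missed, 64800, 86399),
      type = "missed", duration = 0)
  }
  calls <- if (length(call_rows)) {
    cr <- do.call(rbind, call_rows); cr[order(cr$ts), ]
  } else data.frame(ts = numeric(0), type = character(0),
                    duration = numeric(0))

  ## bluetooth: calibrated morning count; other epochs background
  bt_counts <- c(stats::rnbinom(1, mu = 18, size = 0.4), lat$mo_bt,
                 stats::rnbinom(2, mu = 30, size = 0.4))
  bt_ts <- unlist(lapply(1:4, function(i) {
    b <- EPOCH_BOUNDS[[SUB_EPOCHS[i]]]
    stats::runif(bt_counts[i], b[1], b[2] - 1)
  }))
  bluetooth <- data.frame(ts = sort(bt_ts),
                          device_hash = sprintf("bt%03d",
                            sample(600, length(bt_ts), replace = TRUE)))

  ## wifi: scans every ~10 min while awake; APs follow the minute state
  wf_min <- seq(0L, 1439L, by = 10L)
  wf_min <- wf_min[awake[wf_min + 1L] | stats::runif(length(wf_min)) < 0.15]
  campus_states <- c("campus_building", "campus_study", "campus_green",
                     "campus_walk_in", "campus_walk_out")
  ap <- ifelse(state[wf_min + 1L] %in% campus_states,
               sprintf("campus%03d", sample(60, length(wf_min), TRUE)),
               ifelse(state[wf_min + 1L] == "out",
                      sprintf("out%04d", sample(2000, length(wf_min), TRUE)),
                      paste0(p$participant_id, "_home",
                             sample(4, length(wf_min), TRUE))))
  wifi <- data.frame(ts = wf_min * 60 + stats::runif(length(wf_min), 0, 59),
                     ap_hash = ap)

  ## battery: hourly samples, discharging from a morning charge
  bat_ts <- seq(0, 86399, by = 3600) + stats::runif(24, 0, 600)
  battery <- data.frame(ts = bat_ts,
                        level = pmax(5, pmin(100, round(
                          100 - (bat_ts / 3600) * 3.2 +
                            stats::rnorm(24, 0, 4)))))

  ## sleep: the nightly episode beginning this evening (possibly after
  ## midnight, i.e. onset_ts > 86400)
  onset_ts <- lat$onset_s + 86400 - 86400  # seconds on this day's axis
  if (onset_ts < hms(20)) onset_ts <- onset_ts + 86400
  sleep <- data.frame(onset_ts = onset_ts,
                      offset_ts = onset_ts + lat$dur_min * 60,
                      minute_count = round(lat$dur_min))

  bundle <- event_bundle(p$participant_id, date,
                         location = location, activity = activity,
                         screen = if (is.null(screen))
                           data.frame(ts = numeric(0), event = character(0))
                         else screen,
                         calls = calls, bluetooth = bluetooth, wifi = wifi,
                         battery = battery, steps = steps, sleep = sleep)
  injected <- if (put_flag) shifts[shifts != 0] else
    stats::setNames(numeric(0), character(0))
  list(bundle = bundle, injected_effects = injected)
}

#' Apply stream-day missingness to a bundle
#'
#' Each stream is independently dropped for the whole day with probability
#' `1 - rate` (missing completely at random at stream-day granularity);
#' dropped streams become NULL with their presence flag cleared.
#'
#' @param bundle a [event_bundle()].
#' @param availability_rates named per-stream retention probabilities.
#' @param seed integer seed.
#' @param compliance day-level compliance probability inducing
#'   cross-stream correlation (see [cohort_config()]); 1 = fully
#'   independent stream drops (the default here).
#' @return the thinned bundle.
#' @export
apply_stream_missingness <- function(bundle,
                                     availability_rates =
                                       default_availability_rates(),
                                     seed = 1L, compliance = 1) {
  unknown <- setdiff(names(availability_rates), PUT_STREAMS)
  if (length(unknown)) {
    stop("unknown stream name(s): ", paste(unknown, collapse = ", "))
  }
  for (r in availability_rates) check_prob(r, "availability rate")
  check_prob(compliance)
  set.seed(derive_seed(seed, paste0("miss:", bundle$participant_id, ":",
                                    format(bundle$date))))
  compliant <- stats::runif(1) < compliance
  for (s in names(availability_rates)) {
    keep_p <- if (compliant) min(1, availability_rates[[s]] / compliance)
              else 0
    if (stats::runif(1) > keep_p) {
      bundle[[s]] <- NULL
      bundle[s] <- list(NULL)
      bundle$present[[s]] <- FALSE
    }
  }
  bundle
}

## study-day dates and the EMA prompt calendar implied by the config
ema_calendar <- function(config, term_start_dates = NULL) {
  tw <- config$ema_schedule$twice_weekly_weeks
  db <- config$ema_schedule$daily_block_weeks
  term_len <- 7L * (tw + db)
  n_terms <- ceiling(config$n_days / term_len)
  if (is.null(term_start_dates)) {
    term_start_dates <- config$start_date + (seq_len(n_terms) - 1L) * term_len
  }
  prompts <- list()
  for (t in seq_len(n_terms)) {
    t0 <- as.Date(term_start_dates[t])
    days <- t0 + 0:(term_len - 1L)
    days <- days[days < config$start_date + config$n_days]
    if (length(days) == 0L) next
    tw_days <- days[seq_len(min(7L * tw, length(days)))]
    wd <- as.integer(format(tw_days, "%u"))  # 1=Mon .. 7=Sun
    tw_prompts <- tw_days[wd %in% c(3L, 7L)]  # Wednesdays and Sundays
    db_days <- if (length(days) > 7L * tw) days[(7L * tw + 1L):length(days)]
               else as.Date(character(0))
    prompts[[t]] <- rbind(
      if (length(tw_prompts))
        data.frame(prompt_date = tw_prompts, referenced_date = tw_prompts - 1L),
      if (length(db_days))
        data.frame(prompt_date = db_days, referenced_date = db_days))
  }
  out <- do.call(rbind, prompts)
  if (is.null(out)) {
    out <- data.frame(prompt_date = as.Date(character(0)),
                      referenced_date = as.Date(character(0)))
  }
  out
}

#' Generate the EMA response table
#'
#' Twice-weekly prompts (Sundays and Wednesdays) reference the previous
#' day; daily-block prompts reference the same day. A prompt is unanswered
#' with probability `config$nonresponse`; answered prompts report the
#' ground-truth PUT flag of the referenced day, flipped with probability
#' `config$label_noise` (default 0).
#'
#' @param config a [cohort_config()].
#' @param ground_truth data.frame `participant_id`, `date`, `put_true`.
#' @param term_start_dates optional explicit term starts.
#' @param seed integer seed.
#' @return data.frame: `participant_id`, `response_ts` (ISO-8601 evening
#'   timestamp), `referenced_date`, `answer` ("yes"/"no"/NA), `responded`.
#' @export
generate_ema_schedule <- function(config, ground_truth,
                                  term_start_dates = NULL, seed = 1L) {
  cal <- ema_calendar(config, term_start_dates)
  set.seed(derive_seed(seed, "ema"))
  pids <- unique(ground_truth$participant_id)
  if (nrow(cal) == 0L) {
    return(data.frame(participant_id = character(0),
                      response_ts = character(0),
                      referenced_date = as.Date(character(0)),
                      answer = character(0), responded = logical(0),
                      stringsAsFactors = FALSE))
  }
  truth_key <- stats::setNames(ground_truth$put_true,
                               paste(ground_truth$participant_id,
                                     ground_truth$date))
  rows <- lapply(pids, function(pid) {
    responded <- stats::runif(nrow(cal)) >= config$nonresponse
    truth <- truth_key[paste(pid, cal$referenced_date)]
    ans <- ifelse(is.na(truth), NA, ifelse(truth, "yes", "no"))
    if (config$label_noise > 0) {
      flip <- stats::runif(nrow(cal)) < config$label_noise & !is.na(ans)
      ans[flip] <- ifelse(ans[flip] == "yes", "no", "yes")
    }
    ans[!responded] <- NA
    data.frame(participant_id = pid,
               response_ts = paste0(format(cal$prompt_date), "T20:30:00"),
               referenced_date = cal$referenced_date,
               answer = ans, responded = responded,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic cohort (event-level path)
#'
#' Deterministic given the config seed. Emits the participant roster, one
#' event bundle per participant-day (with stream-day missingness applied),
#' the EMA response table, the ground truth and a manifest echoing the
#' generation parameters.
#'
#' @param config a [cohort_config()].
#' @param map a [campus_map()].
#' @return list `participants`, `bundles`, `ema`, `ground_truth`,
#'   `manifest`.
#' @export
generate_cohort <- function(config, map = default_campus_map()) {
  stopifnot(inherits(config, "put_cohort_config"))
  participants <- sample_participants(config, map)
  lab <- sample_put_labels(config$n_participants, config$n_days,
                           config$mean_put_rate,
                           config$put_rate_concentration, config$seed)
  dates <- config$start_date + 0:(config$n_days - 1L)
  bundles <- vector("list", config$n_participants * config$n_days)
  gt <- vector("list", length(bundles))
  k <- 0L
  for (i in seq_len(config$n_participants)) {
    for (d in seq_len(config$n_days)) {
      k <- k + 1L
      sim <- synthesize_day_events(participants[i, ], dates[d],
                                   lab$flags[i, d], config$effect_profile,
                                   seed = config$seed, map = map)
      bundles[[k]] <- apply_stream_missingness(sim$bundle,
                                               config$availability_rates,
                                               seed = config$seed,
                                               config$compliance_rate)
      gt[[k]] <- data.frame(
        participant_id = participants$participant_id[i], date = dates[d],
        put_true = lab$flags[i, d],
        injected_effects = if (length(sim$injected_effects))
          paste(names(sim$injected_effects),
                round(sim$injected_effects, 3), sep = "=", collapse = ";")
        else "",
        stringsAsFactors = FALSE)
    }
  }
  ground_truth <- do.call(rbind, gt)
  ema <- generate_ema_schedule(config, ground_truth, seed = config$seed)
  list(participants = participants, bundles = bundles, ema = ema,
       ground_truth = ground_truth,
       manifest = cohort_manifest(config, "events"))
}

cohort_manifest <- function(config, path) {
  m <- unclass(config)
  m$effect_profile <- as.list(m$effect_profile)
  m$availability_rates <- as.list(m$availability_rates)
  m$start_date <- format(m$start_date)
  m$generation_path <- path
  m$put_rate_concentration_note <-
    "concentration is a calibration choice; only the mean rate and its CI are externally constrained"
  m
}
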