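test_that("PUT label sampling has Beta-Bernoulli structure", {
  z <- sample_put_labels(10, 20, 0, seed = 1)
  expect_false(any(z$flags))
  expect_true(all(z$rates == 0))
  ## law of large numbers: the grand mean of per-user positive fractions
  ## concentrates on the configured mean rate
  means <- vapply(1:60, function(s) {
    lab <- sample_put_labels(200, 70, 0.0466, 5, seed = s)
    mean(rowMeans(lab$flags))
  }, numeric(1))
  expect_equal(mean(means), 0.0466, tolerance = 0.05)
  ## the central 95% range of per-user rates brackets the reported
  ## across-user uncertainty band (3.13%..6.19%)
  lab <- sample_put_labels(5000, 1, 0.0466, 5, seed = 3)
  q <- quantile(lab$rates, c(0.025, 0.975))
  expect_lt(q[1], 0.0313)
  expect_gt(q[2], 0.0619)
  expect_error(sample_put_labels(5, 5, 1.5, 5), "probability")
})

test_that("day synthesis is deterministic and null under zero effects", {
  cc <- cohort_config(n_participants = 2, n_days = 2, seed = 8)
  pp <- sample_participants(cc)
  d <- as.Date("2018-01-09")
  a <- synthesize_day_events(pp[1, ], d, FALSE, seed = 8)
  b <- synthesize_day_events(pp[1, ], d, FALSE, seed = 8)
  expect_identical(a, b)
  ## with a zero effect profile, a PUT flag changes nothing
  zero <- default_effect_profile() * 0
  x <- synthesize_day_events(pp[2, ], d, TRUE, zero, seed = 8)
  y <- synthesize_day_events(pp[2, ], d, FALSE, zero, seed = 8)
  expect_identical(x$bundle, y$bundle)
  expect_identical(length(x$injected_effects), 0L)
  ## injected effects recorded iff the day is a PUT day
  w <- synthesize_day_events(pp[2, ], d, TRUE, seed = 8)
  expect_gt(length(w$injected_effects), 0)
})

test_that("stream missingness is MCAR at stream-day granularity", {
  cc <- cohort_config(n_participants = 1, n_days = 1, seed = 2)
  pp <- sample_participants(cc)
  b <- synthesize_day_events(pp[1, ], as.Date("2018-01-08"), FALSE,
                             seed = 2)$bundle
  all_on <- setNames(rep(1, 9), putsense:::PUT_STREAMS)
  expect_identical(apply_stream_missingness(b, all_on, seed = 1), b)
  all_off <- setNames(rep(0, 9), putsense:::PUT_STREAMS)
  b0 <- apply_stream_missingness(b, all_off, seed = 1)
  expect_false(any(b0$present))
  expect_null(b0$steps)
  expect_error(apply_stream_missingness(b, c(gps = 0.5)), "unknown stream")
  ## marginal retention rate: steps at 0.7052 over many days
  keep <- vapply(1:4000, function(i) {
    bb <- b; bb$date <- as.Date("2018-01-08") + i
    apply_stream_missingness(bb, c(steps = 0.7052), seed = 5)$present[["steps"]]
  }, logical(1))
  expect_equal(mean(keep), 0.7052, tolerance = 0.03)
})

test_that("the EMA calendar produces the configured prompt schedule", {
  cc <- cohort_config(n_participants = 1, n_days = 70, seed = 4)
  cal <- putsense:::ema_calendar(cc)
  ## 8 twice-weekly weeks (Wednesdays + Sundays) plus a 14-day daily block
  expect_equal(nrow(cal), 8 * 2 + 14)
  wd <- as.integer(format(cal$prompt_date, "%u"))
  tw <- cal$prompt_date != cal$referenced_date
  expect_true(all(wd[tw] %in% c(3, 7)))
  ## twice-weekly prompts reference the previous day; daily the same day
  expect_true(all(cal$referenced_date[tw] == cal$prompt_date[tw] - 1))
  expect_true(all(cal$referenced_date[!tw] == cal$prompt_date[!tw]))
})

test_that("EMA responses respect nonresponse and match ground truth", {
  cc <- cohort_config(n_participants = 3, n_days = 70, nonresponse = 1,
                      seed = 6)
  gt <- data.frame(participant_id = rep(c("A", "B", "C"), each = 70),
                   date = rep(cc$start_date + 0:69, 3),
                   put_true = rep(c(TRUE, FALSE), length.out = 210))
  ema <- generate_ema_schedule(cc, gt, seed = 6)
  expect_true(all(is.na(ema$answer)))
  cc2 <- cohort_config(n_participants = 3, n_days = 70, nonresponse = 0.3,
                       label_noise = 0, seed = 6)
  ema2 <- generate_ema_schedule(cc2, gt, seed = 6)
  ans <- ema2[!is.na(ema2$answer), ]
  key <- paste(gt$participant_id, gt$date)
  truth <- setNames(gt$put_true, key)[paste(ans$participant_id,
                                            ans$referenced_date)]
  ok <- !is.na(truth)
  expect_true(all((ans$answer[ok] == "yes") == truth[ok]))
})

test_that("cohort generation is seed-deterministic with full cardinality", {
  cc <- cohort_config(n_participants = 2, n_days = 3, seed = 12)
  g1 <- generate_cohort(cc)
  g2 <- generate_cohort(cc)
  expect_equal(length(g1$bundles), 6)
  expect_equal(nrow(g1$ground_truth), 6)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
  expect_equal(g1$manifest$n_participants, 2)
  expect_equal(g1$manifest$mean_put_rate, 0.0466)
})

test_that("cohort round-trips through the JSONL directory layout", {
  cc <- cohort_config(n_participants = 2, n_days = 2, seed = 19)
  g <- generate_cohort(cc)
  dir <- tempfile("cohort")
  write_cohort(g, dir)
  expect_true(file.exists(file.path(dir, "ema.csv")))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- read_cohort(dir)
  expect_equal(length(back$bundles), 4)
  expect_equal(back$ground_truth$put_true, g$ground_truth$put_true)
  ## stream content survives the round trip
  i <- which(vapply(g$bundles, function(b) b$present[["location"]],
                    logical(1)))[1]
  skip_if(is.na(i))
  orig <- g$bundles[[i]]
  match_b <- Filter(function(b) b$participant_id == orig$participant_id &&
                      b$date == orig$date, back$bundles)[[1]]
  expect_equal(nrow(match_b$location), nrow(orig$location))
  expect_equal(match_b$location$lat, orig$location$lat, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})

test_that("fast-path tables are column-compatible with extracted tables", {
  cc <- cohort_config(n_participants = 3, n_days = 10, seed = 22)
  g <- generate_feature_table(cc)
  catalog <- feature_catalog()
  expect_identical(feature_columns(g$features), catalog$name)
  expect_equal(nrow(g$features), 30)
  ## interchangeability: an extracted row binds cleanly onto the table
  pp <- sample_participants(cc)
  sim <- synthesize_day_events(pp[1, ], as.Date("2018-03-01"), FALSE,
                               seed = 22)
  row <- extract_person_day(sim$bundle)
  expect_true(all(catalog$name %in% names(row)))
  ## determinism
  g2 <- generate_feature_table(cc)
  expect_identical(g$features, g2$features)
  ## zero user variance: between-user feature means coincide
  cc0 <- cohort_config(n_participants = 4, n_days = 40, icc = 0,
                       compliance_rate = 1,
                       availability_rates = setNames(rep(1, 9),
                                                     putsense:::PUT_STREAMS),
                       seed = 23)
  g0 <- generate_feature_table(cc0)
  mu <- tapply(g0$features[["screen.screen_time.afternoon"]],
               g0$features$participant_id, mean)
  expect_lt(max(mu) - min(mu), 1)  # no user effect beyond day noise
})

test_that("fast-path effect injection reproduces the configured SMDs", {
  ## icc = 0 keeps the SMD estimator's Monte-Carlo error small (user
  ## random effects with clustered positives would dominate it otherwise)
  cc <- cohort_config(n_participants = 150, n_days = 40, seed = 31,
                      mean_put_rate = 0.25, put_rate_concentration = 60,
                      icc = 0)
  g <- generate_feature_table(cc)
  prof <- default_effect_profile()
  for (f in names(prof)[abs(prof) >= 0.2]) {
    r <- smd_record(g$features[[f]], g$ground_truth$put_true)
    expect_lt(abs(r$smd - prof[[f]]), 0.1,
              label = sprintf("fast-path SMD of %s (|error|)", f))
  }
})

test_that("event-path cohorts are calibrated: availability and effect sizes", {
  ## 5,200 simulated participant-days; PUT days oversampled to 1/3 so the
  ## SMD Monte-Carlo error is small
  n_users <- 130; n_days_pp <- 40
  cc <- cohort_config(n_participants = n_users, n_days = 1, seed = 91)
  pp <- sample_participants(cc)
  dates <- as.Date("2018-01-08") + seq_len(n_days_pp) - 1
  rates <- default_availability_rates()
  rows <- vector("list", n_users * n_days_pp)
  present <- matrix(NA, n_users * n_days_pp, 9,
                    dimnames = list(NULL, putsense:::PUT_STREAMS))
  k <- 0
  for (i in seq_len(n_users)) for (d in seq_len(n_days_pp)) {
    k <- k + 1
    putf <- k %% 3 == 0
    sim <- synthesize_day_events(pp[i, ], dates[d], putf, seed = 91)
    thin <- apply_stream_missingness(sim$bundle, rates, seed = 91,
                                     compliance = 0.705)
    present[k, ] <- thin$present
    row <- extract_person_day(sim$bundle)  # calibration on full streams
    row$put <- putf
    rows[[k]] <- row
  }
  tab <- do.call(rbind, rows)
  ## per-stream availability within 2 points of the configured rates
  emp <- 100 * colMeans(present)
  for (s in putsense:::PUT_STREAMS) {
    expect_lt(abs(emp[[s]] - 100 * rates[[s]]), 2,
              label = sprintf("availability of %s (pct error)", s))
  }
  ## realized SMD of each latently shifted feature within 0.1 of target
  ## (the sleep-onset clock encoding wraps at midnight, so its SMD is
  ## checked on the continuous duration/onset latents instead; see the
  ## methods vignette)
  targets <- c("location.off_campus_time.all_day" = 0.44,
               "steps.total_steps.evening" = 0.38,
               "screen.screen_time.afternoon" = 0.41,
               "calls.n_missed_calls.evening" = 0.25,
               "bluetooth.sample_count.morning" = -0.20,
               "activity.sample_count.night" = 0.33,
               "activity_location.indoor_mobility.all_day" = -0.24,
               "sleep.sleep_duration.all_day" = -0.25,
               "activity.physical_activity_duration.evening" = 0.37)
  for (f in names(targets)) {
    r <- smd_record(tab[[f]], tab$put)
    expect_lt(abs(r$smd - targets[[f]]), 0.1,
              label = sprintf("event-path SMD of %s (|error|)", f))
  }
  ## Box-1 directions on derived correlates
  expect_gt(smd_record(tab[["location.off_campus_pct.all_day"]],
                       tab$put)$smd, 0.1)
  expect_lt(smd_record(tab[["steps.sedentary_time.evening"]],
                       tab$put)$smd, -0.1)
})
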