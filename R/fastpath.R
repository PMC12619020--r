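## Fast cohort path: draw person-day features directly from a per-user
## random-effects Gaussian model with the same PUT shifts and stream-level
## missingness, skipping event synthesis. The table is column-compatible
## with extract_features(), so downstream stages are interchangeable.

#' Generate a person-day feature table directly (fast path)
#'
#' Each feature is standardized: `value = u_if + e`, with user effect
#' `u_if ~ N(0, icc)` and day noise `e ~ N(0, 1 - icc)` (unit total
#' variance), so a configured effect of `s` SMD units is injected as an
#' additive shift of `s` on PUT days. Stream-day missingness at the
#' configured availability rates masks the features of dropped streams.
#' EMA responses are simulated on the configured schedule and resolved
#' into labels.
#'
#' @param config a [cohort_config()].
#' @param seed optional override of `config$seed`.
#' @return list with `features` (one row per participant-day: id, date,
#'   catalog features, `avail_*` flags, demographics as `demo_*`, `label`),
#'   `ground_truth`, `participants`, `ema`, `manifest`.
#' @export
generate_feature_table <- function(config, seed = NULL) {
  stopifnot(inherits(config, "put_cohort_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  catalog <- feature_catalog()
  n_p <- config$n_participants
  n_d <- config$n_days
  n <- n_p * n_d
  nf <- nrow(catalog)

  participants <- sample_participants(config)
  lab <- sample_put_labels(n_p, n_d, config$mean_put_rate,
                           config$put_rate_concentration, config$seed)
  set.seed(derive_seed(config$seed, "fast_features"))

  pid <- rep(participants$participant_id, each = n_d)
  dates <- rep(config$start_date + 0:(n_d - 1L), times = n_p)
  put <- as.vector(t(lab$flags))

  u <- matrix(stats::rnorm(n_p * nf, 0, sqrt(config$icc)), n_p, nf)
  vals <- u[rep(seq_len(n_p), each = n_d), , drop = FALSE] +
    matrix(stats::rnorm(n * nf, 0, sqrt(1 - config$icc)), n, nf)
  eff <- config$effect_profile[catalog$name]
  eff[is.na(eff)] <- 0
  if (any(put)) {
    vals[put, ] <- vals[put, , drop = FALSE] +
      matrix(eff, sum(put), nf, byrow = TRUE)
  }
  colnames(vals) <- catalog$name

  ## stream-day missingness: day-level compliance mixture preserving the
  ## per-stream marginal availability rates
  q <- config$compliance_rate
  compliant <- stats::runif(n) < q
  avail <- sapply(PUT_STREAMS, function(s) {
    compliant & stats::runif(n) < min(1, config$availability_rates[[s]] / q)
  })
  req <- strsplit(catalog$requires, ",")
  for (j in seq_len(nf)) {
    ok <- rowSums(!avail[, req[[j]], drop = FALSE]) == 0L
    vals[!ok, j] <- NA_real_
  }

  ground_truth <- data.frame(participant_id = pid, date = dates,
                             put_true = put,
                             injected_effects = ifelse(put,
                               "fast_path_profile", ""),
                             stringsAsFactors = FALSE)
  ema <- generate_ema_schedule(config, ground_truth, seed = config$seed)

  features <- data.frame(participant_id = pid, date = dates,
                         stringsAsFactors = FALSE)
  features <- cbind(features, as.data.frame(vals, check.names = FALSE))
  colnames(avail) <- paste0("avail_", PUT_STREAMS)
  features <- cbind(features, as.data.frame(avail))
  demo <- participants[match(pid, participants$participant_id),
                       c("age", "gender", "first_generation", "disability")]
  names(demo) <- paste0("demo_", names(demo))
  features <- cbind(features, demo)
  rownames(features) <- NULL

  features <- join_ema_labels(features, ema)
  list(features = features, ground_truth = ground_truth,
       participants = participants, ema = ema,
       manifest = cohort_manifest(config, "fast_features"))
}
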