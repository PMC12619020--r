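## Dataset assembly: resolve EMA answers into person-day labels, apply
## availability filters, compute stream-availability reports, and build
## model-ready intraday/multiday sequence tensors with observation masks
## and leakage-safe chronological splits.

#' Resolve EMA answers into person-day labels
#'
#' A day is `positive` if any answered EMA referencing it says yes
#' (yes-dominant on conflicts), `negative` if all answered references say
#' no, and `unlabeled` otherwise. Unlabeled rows are kept (they can serve
#' as sequence context) but must not be used as supervised targets.
#'
#' @param features person-day feature table.
#' @param ema EMA table from [generate_ema_schedule()] (or the same
#'   schema).
#' @return `features` with a `label` column
#'   (`"positive"`/`"negative"`/`"unlabeled"`).
#' @export
join_ema_labels <- function(features, ema) {
  answered <- ema[!is.na(ema$answer), , drop = FALSE]
  key <- paste(answered$participant_id, answered$referenced_date)
  yes_days <- unique(key[answered$answer == "yes"])
  no_days <- unique(key[answered$answer == "no"])
  fkey <- paste(features$participant_id, features$date)
  features$label <- ifelse(fkey %in% yes_days, "positive",
                           ifelse(fkey %in% no_days, "negative",
                                  "unlabeled"))
  features
}

#' Keep rows with at least `min_streams` available data streams
#'
#' @param table feature table with `avail_*` flags.
#' @param min_streams minimum stream count (default 7).
#' @return the filtered table.
#' @export
filter_min_streams <- function(table, min_streams = 7L) {
  flags <- table[, paste0("avail_", PUT_STREAMS), drop = FALSE]
  table[rowSums(flags) >= min_streams, , drop = FALSE]
}

#' Per-stream availability percentages
#'
#' `availability(s) = 100 * #participant-days with stream s present /
#' (n_participants * n_days)`.
#'
#' @param avail_flags data.frame/matrix of `avail_*` logical columns (one
#'   row per participant-day actually generated).
#' @param n_participants,n_days the denominator dimensions.
#' @return data.frame `stream`, `availability_pct`.
#' @export
compute_stream_availability <- function(avail_flags, n_participants, n_days) {
  denom <- n_participants * n_days
  if (denom <= 0) stop("n_participants * n_days must be positive")
  cols <- paste0("avail_", PUT_STREAMS)
  stopifnot(all(cols %in% colnames(avail_flags)))
  data.frame(stream = PUT_STREAMS,
             availability_pct = 100 *
               colSums(as.matrix(avail_flags[, cols])) / denom,
             row.names = NULL)
}

## internal constructor for a sequence dataset
sequence_samples <- function(values, mask, meta, mode, window_days = NA) {
  structure(list(values = values, mask = mask, meta = meta, mode = mode,
                 window_days = window_days,
                 features = dimnames(values)[[3]]),
            class = "put_sequences")
}

#' @export
print.put_sequences <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<put_sequences> mode=%s n=%d T=%d F=%d (pos=%d neg=%d)\n",
              x$mode, d[1], d[2], d[3],
              sum(x$meta$label == "positive"),
              sum(x$meta$label == "negative")))
  invisible(x)
}

## resolve a daily feature list into intraday (epoch-resolved) base stats
intraday_feature_map <- function(feature_list, catalog = feature_catalog()) {
  sel <- catalog[catalog$name %in% feature_list, , drop = FALSE]
  base <- unique(paste(sel$stream, sel$stat, sep = "."))
  resolvable <- unique(paste(catalog$stream, catalog$stat,
                             sep = ".")[catalog$intraday])
  dropped <- setdiff(base, resolvable)
  if (length(dropped) > 0L) {
    warning("excluding features without 6-hour epoch resolution: ",
            paste(dropped, collapse = ", "))
  }
  keep <- intersect(base, resolvable)
  ## columns per epoch, rows in epoch order
  lapply(stats::setNames(SUB_EPOCHS, SUB_EPOCHS), function(ep) {
    paste0(keep, ".", ep)
  })
}

#' Build intraday sequences (4 epoch steps per labeled day)
#'
#' One 4 x F tensor per labeled day, rows = night, morning, afternoon,
#' evening values of each epoch-resolved base statistic; the mask marks
#' observed entries. Sequences with more than `max_missing` masked entries
#' are dropped. Daily-only features (sleep, circadian movement) are
#' excluded with a warning.
#'
#' @param table labeled feature table.
#' @param feature_list daily feature names whose base statistics form the
#'   columns.
#' @param max_missing maximum tolerated missing fraction (default 0.8).
#' @return a `put_sequences` object, mode `"intraday"`.
#' @export
build_intraday_sequences <- function(table, feature_list, max_missing = 0.8) {
  fmap <- intraday_feature_map(feature_list)
  keep_rows <- table$label %in% c("positive", "negative")
  tab <- table[keep_rows, , drop = FALSE]
  n <- nrow(tab)
  nf <- length(fmap[[1]])
  if (nf == 0L) stop("no epoch-resolvable features in feature_list")
  vals <- array(NA_real_, c(n, 4L, nf),
                dimnames = list(NULL, SUB_EPOCHS,
                                sub("\\.night$", "", fmap$night)))
  for (t in 1:4) {
    cols <- fmap[[SUB_EPOCHS[t]]]
    vals[, t, ] <- as.matrix(tab[, cols, drop = FALSE])
  }
  mask <- !is.na(vals)
  frac_missing <- 1 - apply(mask, 1, mean)
  keep <- frac_missing <= max_missing
  meta <- data.frame(participant_id = tab$participant_id,
                     target_date = tab$date, label = tab$label,
                     stringsAsFactors = FALSE)
  sequence_samples(vals[keep, , , drop = FALSE],
                   mask[keep, , , drop = FALSE],
                   meta[keep, , drop = FALSE], "intraday")
}

#' Build multiday sequences (N daily steps ending at the target day)
#'
#' One N x F tensor per labeled target day; earlier rows are that
#' participant's daily features on the preceding calendar days (calendar
#' gaps become fully masked rows). Sequences with more than `max_missing`
#' total missingness or more than `max_target_missing` missingness on the
#' target (last) row are dropped.
#'
#' @param table labeled feature table (unlabeled rows supply context).
#' @param feature_list daily feature names forming the columns.
#' @param window lookback length N >= 2 (e.g. 3, 5, 7, 9).
#' @param max_missing total missing-fraction cap (default 0.8).
#' @param max_target_missing target-day missing-fraction cap (default 0.5).
#' @return a `put_sequences` object, mode `"multiday"`.
#' @export
build_multiday_sequences <- function(table, feature_list, window = 7L,
                                     max_missing = 0.8,
                                     max_target_missing = 0.5) {
  if (window < 2L) stop("window must be >= 2")
  stopifnot(all(feature_list %in% names(table)))
  targets <- which(table$label %in% c("positive", "negative"))
  nf <- length(feature_list)
  key <- paste(table$participant_id, table$date)
  row_of <- stats::setNames(seq_len(nrow(table)), key)
  fmat <- as.matrix(table[, feature_list, drop = FALSE])
  n <- length(targets)
  vals <- array(NA_real_, c(n, window, nf),
                dimnames = list(NULL, NULL, feature_list))
  for (i in seq_len(n)) {
    r <- targets[i]
    want <- paste(table$participant_id[r],
                  table$date[r] - (window - 1L):0)
    hit <- row_of[want]
    ok <- !is.na(hit)
    if (any(ok)) vals[i, which(ok), ] <- fmat[hit[ok], , drop = FALSE]
  }
  mask <- !is.na(vals)
  total_missing <- 1 - apply(mask, 1, mean)
  target_missing <- 1 - apply(mask[, window, , drop = FALSE], 1, mean)
  keep <- total_missing <= max_missing & target_missing <= max_target_missing
  meta <- data.frame(participant_id = table$participant_id[targets],
                     target_date = table$date[targets],
                     label = table$label[targets],
                     stringsAsFactors = FALSE)
  sequence_samples(vals[keep, , , drop = FALSE],
                   mask[keep, , , drop = FALSE],
                   meta[keep, , drop = FALSE], "multiday", window)
}

#' Split specification for the user-dependent track
#'
#' @param train_fraction fraction of each participant's negatives that
#'   trains the detector (default 0.90, chronologically earliest).
#' @param max_seq_missing total sequence missingness cap (default 0.80).
#' @param max_target_missing target-day missingness cap (default 0.50).
#' @param leakage_exclusion drop multiday training sequences whose window
#'   covers a positive test day (default TRUE).
#' @param pooled split the negatives pooled across participants instead of
#'   per participant (default FALSE).
#' @return a `put_split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.9, max_seq_missing = 0.8,
                       max_target_missing = 0.5, leakage_exclusion = TRUE,
                       pooled = FALSE) {
  check_prob(train_fraction)
  check_prob(max_seq_missing)
  check_prob(max_target_missing)
  structure(list(train_fraction = train_fraction,
                 max_seq_missing = max_seq_missing,
                 max_target_missing = max_target_missing,
                 leakage_exclusion = leakage_exclusion, pooled = pooled),
            class = "put_split_spec")
}

## subset helper for put_sequences
seq_subset <- function(s, idx) {
  sequence_samples(s$values[idx, , , drop = FALSE],
                   s$mask[idx, , , drop = FALSE],
                   s$meta[idx, , drop = FALSE], s$mode, s$window_days)
}

#' Chronological negatives-only split
#'
#' Per participant (default), the chronologically earliest
#' `train_fraction` of negative target days form the training set
#' (floor(f * n) to train); the remaining negatives and all positives form
#' the test set. For multiday sequences, training sequences whose lookback
#' window covers a positive test day of the same participant are excluded
#' to prevent leakage.
#'
#' @param samples a `put_sequences` object.
#' @param spec a [split_spec()].
#' @return list `train`, `test` (both `put_sequences`), plus `counts`
#'   (train negatives, test positives/negatives, per-user means).
#' @export
chronological_negative_split <- function(samples, spec = split_spec()) {
  meta <- samples$meta
  neg <- which(meta$label == "negative")
  pos <- which(meta$label == "positive")
  train_idx <- integer(0)
  if (spec$pooled) {
    ord <- neg[order(meta$target_date[neg])]
    n_train <- floor(spec$train_fraction * length(ord))
    train_idx <- ord[seq_len(n_train)]
  } else {
    for (pid in unique(meta$participant_id)) {
      mine <- neg[meta$participant_id[neg] == pid]
      mine <- mine[order(meta$target_date[mine])]
      if (length(mine) < 2L) next  # all to test, logged via counts
      n_train <- floor(spec$train_fraction * length(mine))
      train_idx <- c(train_idx, mine[seq_len(n_train)])
    }
  }
  test_idx <- sort(c(pos, setdiff(neg, train_idx)))
  ## leakage exclusion: multiday training windows covering positive test
  ## days of the same participant
  if (spec$leakage_exclusion && samples$mode == "multiday" &&
      length(train_idx) > 0L && length(pos) > 0L) {
    w <- samples$window_days
    pos_key <- paste(meta$participant_id[pos], meta$target_date[pos])
    covered <- vapply(train_idx, function(r) {
      days <- meta$target_date[r] - (w - 1L):0
      any(paste(meta$participant_id[r], days) %in% pos_key)
    }, logical(1))
    train_idx <- train_idx[!covered]
  }
  train <- seq_subset(samples, sort(train_idx))
  test <- seq_subset(samples, test_idx)
  per_user_train <- table(train$meta$participant_id)
  per_user_test <- table(test$meta$participant_id)
  list(train = train, test = test,
       counts = list(train_neg = nrow(train$meta),
                     test_pos = sum(test$meta$label == "positive"),
                     test_neg = sum(test$meta$label == "negative"),
                     per_user_train_mean = mean(per_user_train),
                     per_user_train_sd = stats::sd(as.numeric(per_user_train)),
                     per_user_test_mean = mean(per_user_test)))
}
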