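## User-dependent anomaly detection: standardize sequences, train the
## LSTM-autoencoder on negative days only, score reconstruction errors
## (whole sequence for intraday, target day only for multiday), threshold
## at a percentile of training errors, and run repeated-seed experiments.

#' Autoencoder configuration
#'
#' @param mode `"intraday"` (T = 4 epoch steps) or `"multiday"` (T = N
#'   daily steps).
#' @param n_features number of input features k (50, 100 or 150 in the
#'   standard sweeps).
#' @param window multiday lookback N (ignored for intraday).
#' @param hidden encoder layer widths, outermost first (default c(64,
#'   32)); the decoder mirrors them. The topology is fixed at two
#'   recurrent layers per side.
#' @param epochs,batch_size,lr training schedule (defaults 100 / 32 /
#'   1e-3).
#' @param patience early-stopping patience on a held-out slice of the
#'   training negatives (default 10).
#' @param val_fraction fraction of train used for early stopping
#'   (default 0.1).
#' @param threshold_percentile anomaly threshold percentile of training
#'   errors (default 75).
#' @param n_runs randomized repetitions of the experiment (default 10).
#' @param per_user_scaling centre each participant's sequences on their
#'   own (shrunken) training means before global scaling (default TRUE).
#'   Global-only scaling leaves between-user level differences in the
#'   input, and a pooled negatives-only model then scores sparsely
#'   represented users as anomalous regardless of their label; per-user
#'   centring restores chance-level scores under a null cohort.
#' @return an `put_ae_config` list.
#' @export
ae_config <- function(mode = c("multiday", "intraday"), n_features = 50L,
                      window = 7L, hidden = c(64L, 32L), epochs = 100L,
                      batch_size = 32L, lr = 1e-3, patience = 10L,
                      val_fraction = 0.1, threshold_percentile = 75,
                      n_runs = 10L, per_user_scaling = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(hidden) == 2L, threshold_percentile > 0,
            threshold_percentile < 100)
  structure(list(mode = mode, n_features = as.integer(n_features),
                 window = as.integer(window), hidden = as.integer(hidden),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 threshold_percentile = threshold_percentile,
                 n_runs = as.integer(n_runs),
                 per_user_scaling = per_user_scaling),
            class = "put_ae_config")
}

#' Fit a standardization scaler on training sequences
#'
#' Per-feature mean and SD are computed over the observed (unmasked)
#' training entries only; constant features get SD 1 so they scale to 0.
#'
#' @param train a `put_sequences` object.
#' @return a `put_scaler` (feature means and SDs).
#' @export
fit_scaler <- function(train) {
  d <- dim(train$values)
  nf <- d[3]
  mu <- numeric(nf); sd_ <- numeric(nf)
  for (j in seq_len(nf)) {
    v <- train$values[, , j][train$mask[, , j]]
    mu[j] <- if (length(v)) mean(v) else 0
    s <- if (length(v) > 1) stats::sd(v) else 0
    sd_[j] <- if (is.na(s) || s < 1e-12) 1 else s
  }
  structure(list(mean = mu, sd = sd_, features = train$features),
            class = "put_scaler")
}

#' Fit per-user centering on top of a global scaler
#'
#' Computes each participant's per-feature centre as a shrinkage estimate
#' over the observed entries of their training sequences:
#' `(sum + k * global_mean) / (n_observed + k)`. Every user gets a
#' user-specific centre — falling back to the global mean only with no
#' training data at all — so sparsely represented users are not scored
#' against a population centre that reintroduces their user effect. The
#' global SD is kept for scaling (per-user SDs are too noisy at a handful
#' of sequences per user).
#'
#' @param train a `put_sequences` object (training negatives).
#' @param shrink pseudo-observations pulling the centre toward the global
#'   mean (default 2).
#' @return a `put_user_scaler`.
#' @export
fit_user_scaler <- function(train, shrink = 2) {
  global <- fit_scaler(train)
  nf <- dim(train$values)[3]
  centres <- list()
  for (pid in unique(train$meta$participant_id)) {
    idx <- which(train$meta$participant_id == pid)
    mu <- numeric(nf)
    for (j in seq_len(nf)) {
      v <- train$values[idx, , j][train$mask[idx, , j]]
      mu[j] <- (sum(v) + shrink * global$mean[j]) / (length(v) + shrink)
    }
    centres[[pid]] <- mu
  }
  structure(list(global = global, centres = centres),
            class = "put_user_scaler")
}

#' Apply a per-user scaler to sequences
#'
#' @param scaler a [fit_user_scaler()] result.
#' @param sequences a `put_sequences` object.
#' @return standardized sequences (masked entries zero-filled).
#' @export
apply_user_scaler <- function(scaler, sequences) {
  v <- sequences$values
  g <- scaler$global
  pid <- sequences$meta$participant_id
  for (j in seq_len(dim(v)[3])) {
    mu <- vapply(pid, function(p) {
      c <- scaler$centres[[p]]
      if (is.null(c)) g$mean[j] else c[j]
    }, numeric(1))
    v[, , j] <- (v[, , j] - mu) / g$sd[j]
  }
  v[!sequences$mask] <- 0
  sequences$values <- v
  sequences
}

#' Apply a scaler to sequences
#'
#' Standardizes observed entries with the (training) statistics and
#' zero-fills masked entries, so the forward pass never reads sentinels.
#'
#' @param scaler a [fit_scaler()] result.
#' @param sequences a `put_sequences` object.
#' @return the standardized `put_sequences`.
#' @export
apply_scaler <- function(scaler, sequences) {
  v <- sequences$values
  for (j in seq_len(dim(v)[3])) {
    v[, , j] <- (v[, , j] - scaler$mean[j]) / scaler$sd[j]
  }
  v[!sequences$mask] <- 0
  sequences$values <- v
  sequences
}

#' Masked reconstruction error of one sequence
#'
#' Mean of squared differences over observed positions; `scope =
#' "target_day"` restricts to the last row (multiday scoring), `"full"`
#' averages over the whole tensor's observed entries.
#'
#' @param x,xhat T x F matrices (original and reconstruction).
#' @param mask T x F logical observation mask.
#' @param scope `"full"` or `"target_day"`.
#' @return nonnegative scalar, or `NA` if no observed entries in scope
#'   (the sample is unscoreable).
#' @export
masked_reconstruction_error <- function(x, xhat, mask,
                                        scope = c("full", "target_day")) {
  scope <- match.arg(scope)
  stopifnot(all(dim(x) == dim(xhat)), all(dim(x) == dim(mask)))
  if (scope == "target_day") {
    t_last <- nrow(x)
    x <- x[t_last, , drop = FALSE]
    xhat <- xhat[t_last, , drop = FALSE]
    mask <- mask[t_last, , drop = FALSE]
  }
  if (!any(mask)) return(NA_real_)
  mean((x[mask] - xhat[mask])^2)
}

## batch scoring: per-sample masked errors under a scope
batch_errors <- function(vals, xhat, mask, scope) {
  d <- dim(vals)
  if (scope == "target_day") {
    sel <- d[2]
    vals <- vals[, sel, , drop = FALSE]
    xhat <- xhat[, sel, , drop = FALSE]
    mask <- mask[, sel, , drop = FALSE]
  }
  se <- (vals - xhat)^2 * mask
  num <- apply(se, 1, sum)
  den <- apply(mask, 1, sum)
  ifelse(den > 0, num / den, NA_real_)
}

#' Train the LSTM-autoencoder on negative sequences
#'
#' Two stacked LSTM encoder layers compress the sequence into the final
#' hidden state, which is repeated and decoded by two stacked LSTM layers
#' and a time-distributed dense head. Training minimizes the masked MSE
#' by Adam with minibatches, early-stopping on a held-out slice of the
#' training negatives. Deterministic given `seed` and config.
#'
#' @param train standardized `put_sequences` containing only
#'   negative-labeled targets.
#' @param config an [ae_config()].
#' @param seed integer seed (weights, shuffling, validation slice).
#' @return a fitted `put_lstm_ae` model.
#' @export
train_autoencoder <- function(train, config, seed = 1L) {
  stopifnot(inherits(train, "put_sequences"))
  if (nrow(train$meta) == 0L) stop("empty training set")
  if (any(train$meta$label == "positive")) {
    stop("training sequences must be negative-labeled only")
  }
  set.seed(derive_seed(seed, "ae_train"))
  n <- dim(train$values)[1]
  nf <- dim(train$values)[3]
  params <- ae_init_params(nf, config$hidden)
  state <- list(m = list(), v = list(), t = 0L)
  n_val <- max(0L, min(n - 1L, round(config$val_fraction * n)))
  val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    perm <- sample(tr_idx)
    nb <- ceiling(length(perm) / config$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      idx <- perm[((b - 1L) * config$batch_size + 1L):
                    min(b * config$batch_size, length(perm))]
      lg <- ae_loss_grad(train$values[idx, , , drop = FALSE],
                         train$mask[idx, , , drop = FALSE], params)
      upd <- adam_step(params, lg$grads, state, config$lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    history <- c(history, ep_loss / length(tr_idx))
    ## early stopping on the validation slice
    mon <- if (n_val > 0) {
      fw <- ae_forward(train$values[val_idx, , , drop = FALSE], params)
      mean(batch_errors(train$values[val_idx, , , drop = FALSE], fw$xhat,
                        train$mask[val_idx, , , drop = FALSE], "full"),
           na.rm = TRUE)
    } else history[ep]
    if (mon < best$loss - 1e-7) {
      best <- list(loss = mon, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(params = best$params, config = config, history = history,
                 best_epoch = best$epoch, n_train = n, seed = seed),
            class = "put_lstm_ae")
}

#' @export
print.put_lstm_ae <- function(x, ...) {
  cat(sprintf(
    "<put_lstm_ae> mode=%s F=%d hidden=[%s] trained on %d sequences (best epoch %d)\n",
    x$config$mode, dim(x$params$dense$W)[2],
    paste(x$config$hidden, collapse = ","), x$n_train, x$best_epoch))
  invisible(x)
}

#' Reconstruction errors of sequences under a fitted autoencoder
#'
#' @param object a `put_lstm_ae`.
#' @param sequences standardized `put_sequences`.
#' @param scope `"full"` (intraday convention) or `"target_day"`
#'   (multiday convention); defaults to the model's mode.
#' @param ... unused.
#' @return numeric vector of per-sequence masked reconstruction errors
#'   (NA where nothing is observed in scope).
#' @export
predict.put_lstm_ae <- function(object, sequences, scope = NULL, ...) {
  scope <- scope %||%
    (if (object$config$mode == "multiday") "target_day" else "full")
  fw <- ae_forward(sequences$values, object$params)
  batch_errors(sequences$values, fw$xhat, sequences$mask, scope)
}

#' Anomaly threshold from training reconstruction errors
#'
#' Linear-interpolated (type 7) percentile of the training errors.
#'
#' @param train_errors numeric vector of reconstruction errors.
#' @param percentile percentile in (0, 100), default 75.
#' @return the threshold theta.
#' @export
fit_threshold <- function(train_errors, percentile = 75) {
  train_errors <- train_errors[!is.na(train_errors)]
  if (length(train_errors) == 0L) stop("no training errors")
  unname(stats::quantile(train_errors, percentile / 100, type = 7))
}

#' Score sequences and flag anomalies
#'
#' @param model a fitted `put_lstm_ae`.
#' @param samples standardized `put_sequences` (scaled with the training
#'   scaler).
#' @param theta anomaly threshold from [fit_threshold()].
#' @param scope error scope (defaults to the model's mode convention).
#' @return data.frame: participant, target date, label, reconstruction
#'   error, `flagged` (error > theta); unscoreable samples are dropped
#'   with their count recorded in `attr(, "n_skipped")`.
#' @export
score_and_flag <- function(model, samples, theta, scope = NULL) {
  err <- predict(model, samples, scope)
  out <- data.frame(participant_id = samples$meta$participant_id,
                    target_date = samples$meta$target_date,
                    label = samples$meta$label,
                    reconstruction_error = err,
                    flagged = !is.na(err) & err > theta,
                    stringsAsFactors = FALSE)
  skipped <- sum(is.na(err))
  out <- out[!is.na(out$reconstruction_error), , drop = FALSE]
  attr(out, "n_skipped") <- skipped
  out
}

## naive baselines on a test set: label-independent scores/flags
naive_baseline_metrics <- function(test_labels, kind, train_prevalence) {
  n <- length(test_labels)
  scores <- stats::runif(n)
  flags <- switch(kind,
    uniform = stats::runif(n) < 0.5,
    stratified = stats::runif(n) < train_prevalence)
  compute_metrics(test_labels, scores, flags)
}

#' Run the repeated-seed anomaly experiment
#'
#' For each of `n_runs` runs: fit the scaler on the training negatives,
#' train the autoencoder, set the threshold at the configured percentile
#' of training reconstruction errors, score the test set (all positives
#' plus held-out negatives), and compute the metric set from the errors
#' and thresholded flags. Uniform and stratified naive baselines are
#' evaluated on the same test labels.
#'
#' @param split result of [chronological_negative_split()].
#' @param config an [ae_config()].
#' @param seed root seed; run r uses substream `run<r>`.
#' @param train_prevalence positive prevalence used by the stratified
#'   baseline (the labeled-table training prevalence; negative-only
#'   training sets have none, so it must be supplied; default 0.0466).
#' @return a `put_anomaly_experiment`: lists of per-run `MetricSet`s for
#'   the model and both baselines, per-run thresholds and scores.
#' @export
run_anomaly_experiment <- function(split, config, seed = 1L,
                                   train_prevalence = 0.0466) {
  scope <- if (config$mode == "multiday") "target_day" else "full"
  runs <- vector("list", config$n_runs)
  base_u <- vector("list", config$n_runs)
  base_s <- vector("list", config$n_runs)
  thetas <- numeric(config$n_runs)
  scores_log <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    rs <- derive_seed(seed, paste0("run", r))
    if (config$per_user_scaling) {
      scaler <- fit_user_scaler(split$train)
      tr <- apply_user_scaler(scaler, split$train)
      te <- apply_user_scaler(scaler, split$test)
    } else {
      scaler <- fit_scaler(split$train)
      tr <- apply_scaler(scaler, split$train)
      te <- apply_scaler(scaler, split$test)
    }
    model <- train_autoencoder(tr, config, seed = rs)
    tr_err <- predict(model, tr, scope)
    theta <- fit_threshold(tr_err, config$threshold_percentile)
    sc <- score_and_flag(model, te, theta, scope)
    labels <- sc$label == "positive"
    runs[[r]] <- compute_metrics(labels, sc$reconstruction_error, sc$flagged)
    set.seed(derive_seed(rs, "baselines"))
    base_u[[r]] <- naive_baseline_metrics(labels, "uniform", train_prevalence)
    base_s[[r]] <- naive_baseline_metrics(labels, "stratified",
                                          train_prevalence)
    thetas[r] <- theta
    scores_log[[r]] <- sc
  }
  structure(list(model = runs, uniform = base_u, stratified = base_s,
                 thetas = thetas, scores = scores_log, config = config,
                 seed = seed),
            class = "put_anomaly_experiment")
}

#' @export
print.put_anomaly_experiment <- function(x, ...) {
  cat(sprintf("<put_anomaly_experiment> mode=%s k=%d N=%s runs=%d\n",
              x$config$mode, x$config$n_features,
              if (x$config$mode == "multiday") x$config$window else "-",
              length(x$model)))
  print(summary(x))
  invisible(x)
}

#' @export
summary.put_anomaly_experiment <- function(object, ...) {
  rows <- lapply(c(model = "model", uniform = "uniform",
                   stratified = "stratified"), function(k) {
    s <- summarize_runs(object[[k]])
    stats::setNames(s$formatted, s$metric)
  })
  as.data.frame(do.call(rbind, rows))
}
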