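## User-independent classification benchmark: nested stratified group
## cross-validation over five classifier families and three baselines,
## with median imputation, imbalance handling (class weights, SMOTE,
## SVM-SMOTE), prevalence thresholding and information-gain importances.

#' Stratified group fold assignment
#'
#' Greedily assigns participant groups to K folds, balancing positive
#' counts (then totals), so each participant appears in exactly one fold
#' and per-fold class shares track the global share. Deterministic given
#' the seed.
#'
#' @param labels logical/0-1 outcome per row.
#' @param groups participant id per row.
#' @param K number of folds.
#' @param seed integer seed (breaks ties in the greedy order).
#' @return integer vector of fold ids (1..K) per row.
#' @export
make_stratified_group_folds <- function(labels, groups, K, seed = 1L) {
  labels <- as.logical(labels)
  ug <- unique(groups)
  if (K > length(ug)) stop("K exceeds the number of groups")
  set.seed(derive_seed(seed, "folds"))
  pos_by_g <- tapply(labels, groups, sum)[ug]
  tot_by_g <- tapply(rep(1, length(groups)), groups, sum)[ug]
  ## visit groups by descending positive count with random tie-break
  ord <- order(-pos_by_g, -tot_by_g, stats::runif(length(ug)))
  fold_pos <- numeric(K); fold_tot <- numeric(K)
  fold_of <- stats::setNames(integer(length(ug)), ug)
  for (gi in ord) {
    ## positive-carrying groups balance positive counts first; the rest
    ## balance fold sizes so shares stay close to the global share
    f <- if (pos_by_g[gi] > 0) {
      order(fold_pos, fold_tot, stats::runif(K))[1]
    } else {
      order(fold_tot, fold_pos, stats::runif(K))[1]
    }
    fold_of[ug[gi]] <- f
    fold_pos[f] <- fold_pos[f] + pos_by_g[gi]
    fold_tot[f] <- fold_tot[f] + tot_by_g[gi]
  }
  unname(fold_of[as.character(groups)])
}

#' SMOTE oversampling of the minority class
#'
#' Each synthetic minority point is a uniform convex combination of a
#' minority point and one of its k nearest minority neighbors.
#'
#' @param X numeric matrix (complete cases).
#' @param y logical labels (TRUE = minority/positive).
#' @param k neighbors (default 5).
#' @param target_ratio synthetic points are added until the minority
#'   reaches this fraction of the majority count (default 1 = balanced).
#' @param seed integer seed.
#' @return list `X`, `y` with synthetic rows appended.
#' @export
smote <- function(X, y, k = 5L, target_ratio = 1, seed = 1L) {
  y <- as.logical(y)
  set.seed(derive_seed(seed, "smote"))
  n_min <- sum(y); n_maj <- sum(!y)
  n_new <- max(0L, round(target_ratio * n_maj) - n_min)
  if (n_new == 0L || n_min < 2L) return(list(X = X, y = y))
  Xm <- X[y, , drop = FALSE]
  k_eff <- min(k, n_min - 1L)
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_eff)]))
  base_idx <- sample(n_min, n_new, replace = TRUE)
  nb_idx <- nn[cbind(base_idx, sample(k_eff, n_new, replace = TRUE))]
  lam <- stats::runif(n_new)
  X_new <- Xm[base_idx, , drop = FALSE] +
    lam * (Xm[nb_idx, , drop = FALSE] - Xm[base_idx, , drop = FALSE])
  list(X = rbind(X, X_new), y = c(y, rep(TRUE, n_new)))
}

#' SVM-SMOTE oversampling
#'
#' Like [smote()], but synthetic points are seeded only at minority
#' support vectors of an SVM fitted to the training data, concentrating
#' oversampling near the decision boundary.
#'
#' @inheritParams smote
#' @return list `X`, `y`.
#' @export
svm_smote <- function(X, y, k = 5L, target_ratio = 1, seed = 1L) {
  y <- as.logical(y)
  set.seed(derive_seed(seed, "svm_smote"))
  n_min <- sum(y); n_maj <- sum(!y)
  n_new <- max(0L, round(target_ratio * n_maj) - n_min)
  if (n_new == 0L || n_min < 2L) return(list(X = X, y = y))
  fit <- e1071::svm(x = X, y = factor(y), kernel = "linear", cost = 1,
                    scale = TRUE)
  sv_min <- intersect(fit$index, which(y))
  if (length(sv_min) < 2L) sv_min <- which(y)
  Xm <- X[y, , drop = FALSE]
  seed_rows <- match(sv_min, which(y))
  k_eff <- min(k, n_min - 1L)
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_eff)]))
  base_idx <- sample(seed_rows, n_new, replace = TRUE)
  nb_idx <- nn[cbind(base_idx, sample(k_eff, n_new, replace = TRUE))]
  lam <- stats::runif(n_new)
  X_new <- Xm[base_idx, , drop = FALSE] +
    lam * (Xm[nb_idx, , drop = FALSE] - Xm[base_idx, , drop = FALSE])
  list(X = rbind(X, X_new), y = c(y, rep(TRUE, n_new)))
}

#' Fold preprocessing: median imputation and optional resampling
#'
#' Imputation statistics are fit on the training fold only and applied to
#' both folds; resampling touches the training fold only. The
#' gradient-boosted family skips imputation (native missing-value
#' handling).
#'
#' @param X_train,X_test numeric matrices with possible NAs.
#' @param y_train logical training labels.
#' @param impute apply median imputation (default TRUE).
#' @param resample one of `"none"`, `"smote"`, `"svm_smote"`.
#' @param seed integer seed for resampling.
#' @return list `X_train`, `y_train`, `X_test`.
#' @export
preprocess_fold <- function(X_train, X_test, y_train, impute = TRUE,
                            resample = c("none", "smote", "svm_smote"),
                            seed = 1L) {
  resample <- match.arg(resample)
  if (impute) {
    med <- apply(X_train, 2, stats::median, na.rm = TRUE)
    med[is.na(med)] <- 0  # all-missing column
    for (j in seq_len(ncol(X_train))) {
      X_train[is.na(X_train[, j]), j] <- med[j]
      X_test[is.na(X_test[, j]), j] <- med[j]
    }
  }
  if (resample != "none") {
    rs <- if (resample == "smote") smote(X_train, y_train, seed = seed)
          else svm_smote(X_train, y_train, seed = seed)
    X_train <- rs$X; y_train <- rs$y
  }
  list(X_train = X_train, y_train = y_train, X_test = X_test)
}

#' Classification threshold from training prevalence
#'
#' @param train_labels logical/0-1 training labels with at least one
#'   positive.
#' @return tau = positives / total.
#' @export
threshold_from_prevalence <- function(train_labels) {
  train_labels <- as.logical(train_labels)
  if (sum(train_labels) == 0L) stop("no positives in training labels")
  mean(train_labels)
}

#' Model specification for one classifier family
#'
#' @param family one of `"knn"`, `"logistic"`, `"max_margin"`,
#'   `"random_forest"`, `"gradient_boosted_trees"`, `"baseline_uniform"`,
#'   `"baseline_stratified"`, `"baseline_demographic"`.
#' @param grid named list of hyperparameter vectors (crossed); empty
#'   grid = defaults only.
#' @param imbalance one of `"none"`, `"class_weight"`, `"smote"`,
#'   `"svm_smote"`, or several to let the inner loop choose.
#' @return a `put_model_spec`.
#' @export
model_spec <- function(family, grid = list(), imbalance = "class_weight") {
  family <- match.arg(family,
    c("knn", "logistic", "max_margin", "random_forest",
      "gradient_boosted_trees", "baseline_uniform", "baseline_stratified",
      "baseline_demographic"))
  structure(list(family = family, grid = grid, imbalance = imbalance),
            class = "put_model_spec")
}

#' Default benchmark model set
#'
#' The five classifier families with small default grids, plus the three
#' baselines.
#' @return named list of [model_spec()]s.
#' @export
default_model_specs <- function() {
  list(
    knn = model_spec("knn", grid = list(k = c(5, 15, 35)),
                     imbalance = "none"),
    logistic = model_spec("logistic", imbalance = "class_weight"),
    max_margin = model_spec("max_margin", grid = list(cost = c(0.1, 1)),
                            imbalance = "class_weight"),
    random_forest = model_spec("random_forest",
                               grid = list(num.trees = c(100, 300)),
                               imbalance = "smote"),
    gradient_boosted_trees = model_spec(
      "gradient_boosted_trees",
      grid = list(nrounds = c(100, 300), max_depth = c(3, 6)),
      imbalance = "class_weight"),
    baseline_uniform = model_spec("baseline_uniform", imbalance = "none"),
    baseline_stratified = model_spec("baseline_stratified",
                                     imbalance = "none"),
    baseline_demographic = model_spec("baseline_demographic",
                                      imbalance = "class_weight"))
}

is_baseline <- function(spec) startsWith(spec$family, "baseline")

#' Fit one classifier and return a scoring closure
#'
#' All families are trained with a binary cross-entropy-style objective
#' where applicable and expose `score(X)` returning probability-like
#' scores; baselines ignore behavioral features entirely (the demographic
#' baseline sees only `demo_*` columns).
#'
#' @param spec a [model_spec()].
#' @param X numeric training matrix (already preprocessed; the
#'   gradient-boosted family may contain NAs).
#' @param y logical training labels.
#' @param pars named list of hyperparameter values from the spec grid.
#' @param seed integer seed.
#' @return a `put_classifier` with elements `score(X)`,
#'   `predict_flags(X, tau)` and (tree families) `importances`.
#' @export
fit_classifier <- function(spec, X, y, pars = list(), seed = 1L) {
  y <- as.logical(y)
  if (!is_baseline(spec) && length(unique(y)) < 2L) {
    stop("training labels have a single class")
  }
  set.seed(derive_seed(seed, paste0("fit_", spec$family)))
  w <- if (identical(spec$imbalance, "class_weight")) {
    ifelse(y, sum(!y) / max(1, sum(y)), 1)
  } else rep(1, length(y))
  imp <- NULL
  fam <- spec$family
  prevalence <- mean(y)
  score_fun <- switch(fam,
    knn = {
      k <- pars$k %||% 15
      Xtr <- X; ytr <- y
      function(Xn) {
        pr <- class::knn(Xtr, Xn, factor(ytr), k = k, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "TRUE", p, 1 - p)
      }
    },
    logistic = {
      df <- as.data.frame(X)
      keep <- vapply(df, function(v) stats::sd(v) > 1e-10, logical(1))
      fit <- suppressWarnings(stats::glm(
        y ~ ., data = cbind(y = y, df[, keep, drop = FALSE]),
        family = stats::binomial(), weights = w))
      function(Xn) {
        suppressWarnings(stats::predict(
          fit, newdata = as.data.frame(Xn)[, names(df)[keep], drop = FALSE],
          type = "response"))
      }
    },
    max_margin = {
      cw <- if (identical(spec$imbalance, "class_weight")) {
        c("FALSE" = 1, "TRUE" = sum(!y) / max(1, sum(y)))
      } else NULL
      fit <- e1071::svm(x = X, y = factor(y), kernel = "radial",
                        cost = pars$cost %||% 1, class.weights = cw,
                        probability = TRUE, scale = TRUE)
      function(Xn) {
        p <- attr(stats::predict(fit, Xn, probability = TRUE),
                  "probabilities")
        p[, "TRUE"]
      }
    },
    random_forest = {
      dat <- as.data.frame(X); dat$.y <- factor(y)
      cw <- if (identical(spec$imbalance, "class_weight")) {
        c("FALSE" = 1, "TRUE" = sum(!y) / max(1, sum(y)))
      } else NULL
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = dat,
        num.trees = pars$num.trees %||% 300,
        probability = TRUE, class.weights = cw,
        seed = derive_seed(seed, "ranger"), num.threads = 1)
      function(Xn) {
        stats::predict(fit, data = as.data.frame(Xn),
                       num.threads = 1)$predictions[, "TRUE"]
      }
    },
    gradient_boosted_trees = {
      spw <- if (identical(spec$imbalance, "class_weight")) {
        sum(!y) / max(1, sum(y))
      } else 1
      dtr <- xgboost::xgb.DMatrix(X, label = as.numeric(y), nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = pars$max_depth %||% 6,
                      eta = pars$eta %||% 0.1,
                      min_child_weight = pars$min_child_weight %||% 1,
                      subsample = pars$subsample %||% 1,
                      scale_pos_weight = spw, nthread = 1,
                      eval_metric = "logloss"),
        data = dtr, nrounds = pars$nrounds %||% 200, verbose = 0)
      it <- xgboost::xgb.importance(model = fit)
      imp <- stats::setNames(it$Gain, it$Feature)
      function(Xn) {
        stats::predict(fit, xgboost::xgb.DMatrix(Xn, nthread = 1))
      }
    },
    baseline_uniform = function(Xn) stats::runif(nrow(Xn)),
    baseline_stratified = function(Xn) stats::runif(nrow(Xn)),
    baseline_demographic = stop("fit the demographic baseline as gradient_boosted_trees on demo columns")
  )
  flag_fun <- switch(fam,
    baseline_uniform = function(Xn, tau) stats::runif(nrow(Xn)) < 0.5,
    baseline_stratified = function(Xn, tau) stats::runif(nrow(Xn)) < prevalence,
    function(Xn, tau) score_fun(Xn) >= tau)
  structure(list(family = fam, score = score_fun,
                 predict_flags = flag_fun, importances = imp,
                 prevalence = prevalence),
            class = "put_classifier")
}

## expand a hyperparameter grid into a list of named parameter sets
expand_grid_list <- function(grid) {
  if (length(grid) == 0L) return(list(list()))
  eg <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(eg)), function(i) as.list(eg[i, , drop = FALSE]))
}

## evaluate one (spec, pars, resample) candidate by inner-CV mean AUPR
inner_cv_aupr <- function(spec, pars, resample, X, y, groups, K, seed) {
  folds <- make_stratified_group_folds(y, groups, K, seed)
  auprs <- numeric(0)
  for (f in seq_len(K)) {
    tr <- folds != f; te <- !tr
    if (sum(y[te]) == 0L || sum(y[tr]) == 0L) next
    pp <- preprocess_fold(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                          y[tr],
                          impute = spec$family != "gradient_boosted_trees",
                          resample = if (resample %in% c("smote", "svm_smote"))
                            resample else "none",
                          seed = seed + f)
    cl <- fit_classifier(spec, pp$X_train, pp$y_train, pars, seed + f)
    auprs <- c(auprs, aupr(y[te], cl$score(pp$X_test)))
  }
  if (length(auprs) == 0L) return(-Inf)
  mean(auprs)
}

#' Nested stratified group cross-validation benchmark
#'
#' The outer loop (default K=5) splits participants into folds with
#' balanced positive counts; the inner loop (default K=4) tunes
#' hyperparameters and the imbalance strategy by mean AUC-PR; outer test
#' metrics are computed at the prevalence threshold tau from each outer
#' training fold. Repeats re-seed the fold construction, giving
#' `repeats * K` metric sets per model. Baselines bypass inner tuning.
#'
#' @param table labeled feature table (must already satisfy the
#'   minimum-stream filter).
#' @param specs named list of [model_spec()]s (default
#'   [default_model_specs()]).
#' @param outer_k,inner_k fold counts (defaults 5, 4).
#' @param repeats number of repeats (default 5).
#' @param seed root seed.
#' @param tune run the inner tuning loop (default TRUE; FALSE uses the
#'   first grid point, for speed).
#' @return a `put_benchmark` object: per-model lists of `MetricSet`s
#'   (indexed by repeat and fold), chosen hyperparameters and
#'   fold-averaged importances.
#' @export
run_nested_cv <- function(table, specs = default_model_specs(),
                          outer_k = 5L, inner_k = 4L, repeats = 5L,
                          seed = 1L, tune = TRUE) {
  lab_rows <- table$label %in% c("positive", "negative")
  tab <- table[lab_rows, , drop = FALSE]
  y <- tab$label == "positive"
  groups <- tab$participant_id
  feats <- feature_columns(tab)
  X_all <- as.matrix(tab[, feats, drop = FALSE])
  X_demo <- demo_matrix(tab)
  results <- list()
  for (mname in names(specs)) {
    spec <- specs[[mname]]
    X <- if (spec$family == "baseline_demographic") X_demo else X_all
    fit_spec <- if (spec$family == "baseline_demographic") {
      model_spec("gradient_boosted_trees", grid = list(),
                 imbalance = spec$imbalance)
    } else spec
    metric_sets <- list()
    chosen <- list()
    imps <- list()
    for (rep_i in seq_len(repeats)) {
      rseed <- derive_seed(seed, paste0(mname, "_rep", rep_i))
      folds <- make_stratified_group_folds(y, groups, outer_k, rseed)
      for (f in seq_len(outer_k)) {
        tr <- folds != f; te <- !tr
        if (sum(y[te]) == 0L) next
        tau <- threshold_from_prevalence(y[tr])
        ## inner selection
        pars <- list(); resample <- "none"
        if (!is_baseline(spec)) {
          cand_res <- if (identical(spec$imbalance, "class_weight") || !tune)
            spec$imbalance else c("class_weight", spec$imbalance)
          grid_pts <- expand_grid_list(spec$grid)
          if (tune && (length(grid_pts) > 1L || length(cand_res) > 1L)) {
            best <- -Inf
            for (gp in grid_pts) for (rs in cand_res) {
              v <- inner_cv_aupr(spec, gp, rs, X[tr, , drop = FALSE],
                                 y[tr], groups[tr], inner_k, rseed + f)
              if (v > best) { best <- v; pars <- gp; resample <- rs }
            }
          } else {
            pars <- grid_pts[[1]]
            resample <- cand_res[1]
          }
          if (resample == "class_weight") resample <- "none"
        }
        use_spec <- if (spec$family == "baseline_demographic") fit_spec
                    else spec
        pp <- preprocess_fold(
          X[tr, , drop = FALSE], X[te, , drop = FALSE], y[tr],
          impute = !(use_spec$family %in%
                       c("gradient_boosted_trees", "baseline_uniform",
                         "baseline_stratified")),
          resample = if (resample %in% c("smote", "svm_smote")) resample
                     else "none",
          seed = rseed + f)
        cl <- fit_classifier(use_spec, pp$X_train, pp$y_train, pars,
                             rseed + f)
        scores <- cl$score(pp$X_test)
        flags <- cl$predict_flags(pp$X_test, tau)
        metric_sets[[length(metric_sets) + 1L]] <-
          compute_metrics(y[te], scores, flags)
        chosen[[length(chosen) + 1L]] <-
          list(repeat_i = rep_i, fold = f, pars = pars,
               resample = resample, tau = tau)
        if (!is.null(cl$importances)) {
          imps[[length(imps) + 1L]] <- cl$importances
        }
      }
    }
    results[[mname]] <- list(metrics = metric_sets, chosen = chosen,
                             importances = imps, family = spec$family)
  }
  structure(list(models = results, outer_k = outer_k, inner_k = inner_k,
                 repeats = repeats, seed = seed,
                 features = feats),
            class = "put_benchmark")
}

demo_matrix <- function(tab) {
  cols <- grep("^demo_", names(tab), value = TRUE)
  if (length(cols) == 0L) stop("no demo_* columns for the demographic baseline")
  dm <- tab[, cols, drop = FALSE]
  dm$demo_gender <- as.numeric(factor(dm$demo_gender,
                                      levels = c("female", "male",
                                                 "nonbinary")))
  as.matrix(data.frame(lapply(dm, as.numeric)))
}

#' @export
print.put_benchmark <- function(x, ...) {
  cat(sprintf("<put_benchmark> %d models, %d x %d-fold CV (%d estimates each)\n",
              length(x$models), x$repeats, x$outer_k,
              x$repeats * x$outer_k))
  print(summary(x))
  invisible(x)
}

#' @export
summary.put_benchmark <- function(object, ...) {
  rows <- lapply(object$models, function(m) {
    s <- summarize_runs(m$metrics)
    stats::setNames(s$formatted, s$metric)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Fold-averaged feature importances of a tree family
#'
#' Mean information-gain importance per feature across all outer folds
#' (features never split on get 0), ranked descending.
#'
#' @param benchmark a `put_benchmark`.
#' @param model name of a tree-family model in the benchmark (default
#'   `"gradient_boosted_trees"`).
#' @return data.frame `feature`, `importance`, sorted descending.
#' @export
aggregate_importances <- function(benchmark,
                                  model = "gradient_boosted_trees") {
  m <- benchmark$models[[model]]
  if (is.null(m) || length(m$importances) == 0L) {
    stop("model has no stored importances (tree families only)")
  }
  feats <- benchmark$features
  acc <- stats::setNames(numeric(length(feats)), feats)
  for (im in m$importances) {
    v <- stats::setNames(numeric(length(feats)), feats)
    common <- intersect(names(im), feats)
    v[common] <- im[common]
    acc <- acc + v
  }
  acc <- acc / length(m$importances)
  out <- data.frame(feature = names(acc), importance = unname(acc))
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k features by aggregated importance
#'
#' @param importances result of [aggregate_importances()].
#' @param k number of features (50, 100 or 150 in the standard sweeps).
#' @return character vector of feature names.
#' @export
select_top <- function(importances, k = 50L) {
  utils::head(importances$feature, k)
}

#' Pairwise model-vs-baseline comparisons
#'
#' One-sided paired Wilcoxon tests (model > baseline) per metric, pairing
#' the per-(repeat, fold) estimates, with Benjamini-Hochberg adjustment
#' across all comparisons.
#'
#' @param benchmark a `put_benchmark` (or `put_anomaly_experiment`
#'   result lists).
#' @param models,baselines names of model and baseline entries.
#' @return data.frame `model`, `baseline`, `metric`, `p_raw`, `p_adj`.
#' @export
compare_to_baselines <- function(benchmark,
                                 models = NULL, baselines = NULL) {
  get_sets <- function(name) {
    if (inherits(benchmark, "put_benchmark"))
      benchmark$models[[name]]$metrics
    else benchmark[[name]]
  }
  all_names <- if (inherits(benchmark, "put_benchmark"))
    names(benchmark$models) else setdiff(names(benchmark),
                                         c("thetas", "scores", "config",
                                           "seed"))
  baselines <- baselines %||% grep("baseline|uniform|stratified",
                                   all_names, value = TRUE)
  models <- models %||% setdiff(all_names, baselines)
  metrics <- c("auroc", "aupr", "precision", "recall", "f1")
  rows <- list()
  for (m in models) for (b in baselines) for (k in metrics) {
    a <- vapply(get_sets(m), function(s) s[[k]], numeric(1))
    v <- vapply(get_sets(b), function(s) s[[k]], numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      model = m, baseline = b, metric = k,
      p_raw = wilcoxon_paired_one_sided(a, v))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out
}
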