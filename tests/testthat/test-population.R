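test_that("stratified group folds separate participants and balance classes", {
  set.seed(2)
  groups <- rep(sprintf("P%02d", 1:10), each = 8)
  labels <- rbinom(80, 1, 0.2)
  folds <- make_stratified_group_folds(labels, groups, 5, seed = 3)
  ## 10 groups over 5 folds: two groups each, participants never split
  expect_equal(length(unique(folds)), 5)
  for (g in unique(groups)) {
    expect_equal(length(unique(folds[groups == g])), 1)
  }
  expect_true(all(table(tapply(folds, groups, unique)) == 2))
  expect_error(make_stratified_group_folds(labels, groups, 11), "exceeds")
  ## positive shares track the global share on a larger cohort
  groups2 <- rep(sprintf("Q%03d", 1:60), each = 20)
  labels2 <- rbinom(1200, 1, 0.05)
  folds2 <- make_stratified_group_folds(labels2, groups2, 5, seed = 9)
  shares <- tapply(labels2, folds2, mean)
  expect_true(all(abs(shares - mean(labels2)) < 0.02 + 1e-9))
  ## degenerate: all positives in one group still yields one fold each
  labels3 <- as.integer(groups == "P01")
  folds3 <- make_stratified_group_folds(labels3, groups, 5, seed = 1)
  expect_equal(length(unique(folds3[groups == "P01"])), 1)
})

test_that("SMOTE synthesizes convex combinations of minority neighbors", {
  set.seed(4)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(12, 4), 6, 2))
  y <- c(rep(FALSE, 30), rep(TRUE, 6))
  for (fn in list(smote, svm_smote)) {
    out <- fn(X, y, k = 3, seed = 5)
    expect_equal(sum(out$y), sum(!y))  # balanced
    new_pts <- out$X[-(1:36), , drop = FALSE]
    Xm <- X[y, , drop = FALSE]
    for (i in seq_len(nrow(new_pts))) {
      ## each synthetic point lies on a segment between two minority points
      on_segment <- FALSE
      for (a in 1:6) for (b in 1:6) {
        if (a == b) next
        d <- Xm[b, ] - Xm[a, ]
        lam <- sum((new_pts[i, ] - Xm[a, ]) * d) / sum(d * d)
        proj <- Xm[a, ] + lam * d
        if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
            sqrt(sum((proj - new_pts[i, ])^2)) < 1e-8) on_segment <- TRUE
      }
      expect_true(on_segment)
    }
  }
})

test_that("fold preprocessing imputes train medians and resamples train only", {
  X_tr <- matrix(c(1, 2, 3, NA, 10, NA, 30, 40), 4, 2)
  X_te <- matrix(c(NA, 5, NA, 7), 2, 2)
  pp <- preprocess_fold(X_tr, X_te, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(pp$X_train[4, 1], 2)       # train median fills train
  expect_equal(pp$X_test[1, 1], 2)        # and test
  expect_equal(pp$X_test[1, 2], 30)
  ## resample = none leaves train untouched
  pp2 <- preprocess_fold(X_tr, X_te, c(TRUE, FALSE, TRUE, FALSE),
                         resample = "none")
  expect_equal(nrow(pp2$X_train), 4)
  ## all-missing column falls back to zero
  X3 <- cbind(c(NA, NA, NA), 1:3)
  pp3 <- preprocess_fold(X3, X3, c(TRUE, FALSE, TRUE))
  expect_true(all(pp3$X_train[, 1] == 0))
})

test_that("the prevalence threshold is the training positive share", {
  expect_equal(threshold_from_prevalence(c(rep(1, 167), rep(0, 4553))),
               167 / 4720)
  expect_equal(threshold_from_prevalence(c(TRUE, FALSE)), 0.5)
  expect_equal(threshold_from_prevalence(c(TRUE, TRUE)), 1)
  expect_error(threshold_from_prevalence(c(FALSE, FALSE)), "no positives")
})

test_that("classifier wrappers score sensibly on a separable toy", {
  set.seed(6)
  X <- matrix(rnorm(400), 200, 2); colnames(X) <- c("a", "b")
  y <- X[, 1] > 0.5
  gbt <- fit_classifier(model_spec("gradient_boosted_trees"), X, y,
                        list(nrounds = 80, max_depth = 3), seed = 1)
  expect_gt(auroc(y, gbt$score(X)), 0.99)
  expect_true(!is.null(gbt$importances))
  expect_gt(gbt$importances[["a"]], 0.9)
  rf <- fit_classifier(model_spec("random_forest", imbalance = "none"),
                       X, y, list(num.trees = 100), seed = 1)
  expect_gt(auroc(y, rf$score(X)), 0.95)
  lg <- fit_classifier(model_spec("logistic"), X, y, seed = 1)
  expect_gt(auroc(y, lg$score(X)), 0.95)
  kn <- fit_classifier(model_spec("knn", imbalance = "none"), X, y,
                       list(k = 5), seed = 1)
  expect_gt(auroc(y, kn$score(X)), 0.9)
  sv <- fit_classifier(model_spec("max_margin"), X, y, list(cost = 1),
                       seed = 1)
  expect_gt(auroc(y, sv$score(X)), 0.95)
  expect_error(fit_classifier(model_spec("logistic"), X, rep(TRUE, 200)),
               "single class")
})

test_that("naive baselines are label-independent at their design rates", {
  set.seed(7)
  X <- matrix(rnorm(300), 150, 2)
  y <- rbinom(150, 1, 0.3) == 1
  unif <- fit_classifier(model_spec("baseline_uniform"), X, y, seed = 2)
  aucs <- replicate(150, auroc(y, unif$score(X)))
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
  flag_rate <- mean(replicate(100, mean(unif$predict_flags(X, 0.3))))
  expect_equal(flag_rate, 0.5, tolerance = 0.03)
  strat <- fit_classifier(model_spec("baseline_stratified"), X, y, seed = 2)
  strat_rate <- mean(replicate(200, mean(strat$predict_flags(X, 0.3))))
  expect_equal(strat_rate, mean(y), tolerance = 0.03)
})

test_that("nested CV yields repeats x folds estimates without group leakage", {
  cc <- cohort_config(n_participants = 40, n_days = 70, seed = 51)
  g <- generate_feature_table(cc)
  filt <- filter_min_streams(g$features)
  specs <- list(
    gradient_boosted_trees = model_spec("gradient_boosted_trees",
                                        grid = list(nrounds = 60,
                                                    max_depth = 3)),
    baseline_uniform = model_spec("baseline_uniform", imbalance = "none"))
  bm <- run_nested_cv(filt, specs, outer_k = 5, inner_k = 3, repeats = 5,
                      seed = 6, tune = FALSE)
  ## 5 repeats x 5 folds = 25 estimates per model (all folds scoreable
  ## here)
  expect_equal(length(bm$models$gradient_boosted_trees$metrics), 25)
  expect_equal(length(bm$models$baseline_uniform$metrics), 25)
  ## group leakage: rebuild the folds and assert disjoint participants
  y <- filt$label[filt$label != "unlabeled"] == "positive"
  grp <- filt$participant_id[filt$label != "unlabeled"]
  for (rep_i in 1:2) {
    f <- make_stratified_group_folds(
      y, grp, 5, derive_seed(6, paste0("gradient_boosted_trees_rep", rep_i)))
    for (k in 1:5) {
      expect_length(intersect(unique(grp[f == k]), unique(grp[f != k])), 0)
    }
  }
  ## importances exist for the tree family and average across folds
  imp <- aggregate_importances(bm)
  expect_equal(sort(imp$feature), sort(bm$features))
  expect_true(all(diff(imp$importance) <= 1e-12))
  expect_error(aggregate_importances(bm, "baseline_uniform"),
               "importances")
  ## top-k selection
  expect_length(select_top(imp, 50), 50)
  expect_identical(select_top(imp, 10), imp$feature[1:10])
})

test_that("the inner loop tunes by AUC-PR when a grid is given", {
  cc <- cohort_config(n_participants = 25, n_days = 70, seed = 77)
  g <- generate_feature_table(cc)
  filt <- filter_min_streams(g$features)
  specs <- list(gradient_boosted_trees = model_spec(
    "gradient_boosted_trees",
    grid = list(nrounds = c(30, 60), max_depth = 3)))
  bm <- run_nested_cv(filt, specs, outer_k = 4, inner_k = 3, repeats = 1,
                      seed = 10, tune = TRUE)
  chosen <- vapply(bm$models$gradient_boosted_trees$chosen,
                   function(ch) ch$pars$nrounds, numeric(1))
  expect_true(all(chosen %in% c(30, 60)))
  ## a feature never split on has zero importance and ranks last
  imp <- aggregate_importances(bm)
  expect_true(any(imp$importance == 0))
  expect_equal(imp$importance[nrow(imp)], 0)
})

test_that("model-baseline comparisons pair estimates and adjust p-values", {
  set.seed(8)
  mk <- function(auc_shift) lapply(1:10, function(i) {
    labels <- rbinom(60, 1, 0.3)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- rnorm(60) + auc_shift * labels
    compute_metrics(labels, scores, scores > 0.5)
  })
  fake <- list(model = mk(1.5), uniform = mk(0), stratified = mk(0),
               thetas = NULL, scores = NULL, config = NULL, seed = 1)
  cmp <- compare_to_baselines(fake, models = "model",
                              baselines = c("uniform", "stratified"))
  expect_equal(nrow(cmp), 10)
  expect_true(all(cmp$p_adj >= cmp$p_raw - 1e-12))
  expect_lt(cmp$p_raw[cmp$baseline == "uniform" & cmp$metric == "auroc"],
            0.01)
})
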