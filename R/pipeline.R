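## End-to-end pipeline orchestration and report rendering.

#' Pipeline configuration
#'
#' Bundles the stage configurations; all randomness flows from the one
#' root seed through named substreams.
#'
#' @param cohort a [cohort_config()].
#' @param split a [split_spec()].
#' @param model_specs named list of [model_spec()]s for the population
#'   benchmark.
#' @param ae an [ae_config()] for the anomaly track.
#' @param top_k features fed from the benchmark importances into the
#'   anomaly model (default 50).
#' @param cv list `outer_k`, `inner_k`, `repeats`, `tune`.
#' @param fast_features use the fast feature-level generator instead of
#'   event synthesis + extraction (default TRUE).
#' @param min_streams availability filter (default 7).
#' @param seed root seed.
#' @return a `put_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            split = split_spec(),
                            model_specs = default_model_specs(),
                            ae = ae_config(),
                            top_k = 50L,
                            cv = list(outer_k = 5L, inner_k = 4L,
                                      repeats = 5L, tune = TRUE),
                            fast_features = TRUE, min_streams = 7L,
                            seed = 1L) {
  structure(list(cohort = cohort, split = split,
                 model_specs = model_specs, ae = ae,
                 top_k = as.integer(top_k), cv = cv,
                 fast_features = fast_features,
                 min_streams = as.integer(min_streams),
                 seed = as.integer(seed)),
            class = "put_pipeline_config")
}

#' Run the full pipeline
#'
#' simulate -> extract (or fast features) -> assemble -> population
#' benchmark -> top-k selection -> anomaly experiment -> summaries.
#' Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, result CSVs and a
#'   manifest are written there.
#' @return list with `features`, `availability`, `benchmark`,
#'   `importances`, `top_features`, `split_counts`, `anomaly`,
#'   `comparisons`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cc <- config$cohort
  cc$seed <- derive_seed(config$seed, "cohort")
  if (config$fast_features) {
    gen <- generate_feature_table(cc)
    features <- gen$features
  } else {
    gen <- generate_cohort(cc)
    features <- extract_features(gen$bundles)
    features <- join_ema_labels(features, gen$ema)
    demo <- gen$participants[match(features$participant_id,
                                   gen$participants$participant_id),
                             c("age", "gender", "first_generation",
                               "disability")]
    names(demo) <- paste0("demo_", names(demo))
    features <- cbind(features, demo)
  }
  availability <- compute_stream_availability(
    features[, paste0("avail_", PUT_STREAMS)], cc$n_participants, cc$n_days)

  filtered <- filter_min_streams(features, config$min_streams)
  benchmark <- run_nested_cv(filtered, config$model_specs,
                             outer_k = config$cv$outer_k,
                             inner_k = config$cv$inner_k,
                             repeats = config$cv$repeats,
                             seed = derive_seed(config$seed, "cv"),
                             tune = isTRUE(config$cv$tune))
  importances <- aggregate_importances(benchmark)
  top_features <- select_top(importances, config$top_k)

  seqs <- if (config$ae$mode == "multiday") {
    build_multiday_sequences(features, top_features, config$ae$window,
                             config$split$max_seq_missing,
                             config$split$max_target_missing)
  } else {
    build_intraday_sequences(features, top_features,
                             config$split$max_seq_missing)
  }
  split <- chronological_negative_split(seqs, config$split)
  lab <- filtered$label[filtered$label %in% c("positive", "negative")]
  anomaly <- run_anomaly_experiment(split, config$ae,
                                    seed = derive_seed(config$seed, "ae"),
                                    train_prevalence = mean(lab == "positive"))
  comparisons <- rbind(
    cbind(track = "population", compare_to_baselines(benchmark)),
    cbind(track = "anomaly", compare_to_baselines(
      anomaly, models = "model",
      baselines = c("uniform", "stratified"))))
  res <- list(features = features, availability = availability,
              benchmark = benchmark, importances = importances,
              top_features = top_features, split_counts = split$counts,
              anomaly = anomaly, comparisons = comparisons,
              config = config)
  if (!is.null(out_dir)) render_report(res, out_dir)
  res
}

#' Render result tables to a directory
#'
#' Writes CSV analogues of the availability, benchmark, comparison,
#' anomaly and importance tables plus a Markdown summary; absent
#' sections are noted rather than failing.
#'
#' @param results result of [run_pipeline()] (possibly partial).
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  md <- c("# putsense run report", "")
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
  if (!is.null(results$availability)) {
    wcsv(results$availability, "availability_report.csv")
    md <- c(md, "## Stream availability (%)", "",
            sprintf("- %s: %.2f", results$availability$stream,
                    results$availability$availability_pct), "")
  } else md <- c(md, "_Availability section absent._", "")
  if (!is.null(results$benchmark)) {
    s <- summary(results$benchmark)
    wcsv(cbind(model = rownames(s), s), "population_metrics.csv")
    md <- c(md, "## User-independent benchmark (mean (SD))", "",
            paste0("| model | ", paste(colnames(s), collapse = " | "), " |"),
            paste0("|", paste(rep("---", ncol(s) + 1), collapse = "|"), "|"),
            vapply(rownames(s), function(r) {
              paste0("| ", r, " | ", paste(unlist(s[r, ]), collapse = " | "),
                     " |")
            }, character(1)), "")
  } else md <- c(md, "_Population benchmark section absent._", "")
  if (!is.null(results$anomaly)) {
    s <- summary(results$anomaly)
    wcsv(cbind(model = rownames(s), s), "anomaly_metrics.csv")
    md <- c(md, "## User-dependent anomaly detection (mean (SD))", "",
            vapply(rownames(s), function(r) {
              paste0("- ", r, ": ", paste(paste(colnames(s),
                                                unlist(s[r, ])),
                                          collapse = ", "))
            }, character(1)), "")
  } else md <- c(md, "_Anomaly section absent._", "")
  if (!is.null(results$comparisons)) {
    wcsv(results$comparisons, "comparisons.csv")
  }
  if (!is.null(results$importances)) {
    wcsv(results$importances, "importances.csv")
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
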