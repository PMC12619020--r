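## Cohort serialization: one JSONL file per stream per participant,
## plus ema.csv, ground_truth.csv, demographics.csv and manifest.yaml.

#' Write a generated cohort to a directory
#'
#' Layout: `<pid>/<stream>.jsonl` (one JSON object per event, with a
#' `date` field), `ema.csv`, `ground_truth.csv`, `demographics.csv`,
#' `manifest.yaml`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in unique(cohort$ground_truth$participant_id)) {
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    mine <- Filter(function(b) b$participant_id == pid, cohort$bundles)
    for (s in PUT_STREAMS) {
      rows <- list()
      for (b in mine) {
        v <- b[[s]]
        if (is.null(v)) next
        df <- if (s == "steps") {
          idx <- which(!is.na(v) & v > 0)
          data.frame(minute = idx - 1L, steps = v[idx])
        } else v
        if (nrow(df) == 0L) next
        df$date <- format(b$date)
        rows[[length(rows) + 1L]] <- df
      }
      if (length(rows) == 0L) next
      all_rows <- do.call(rbind, rows)
      con <- file(file.path(pdir, paste0(s, ".jsonl")), "w")
      writeLines(vapply(seq_len(nrow(all_rows)), function(i) {
        jsonlite::toJSON(as.list(all_rows[i, , drop = FALSE]),
                         auto_unbox = TRUE, digits = NA)
      }, character(1)), con)
      close(con)
    }
  }
  utils::write.csv(cohort$ema, file.path(dir, "ema.csv"), row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  yaml::write_yaml(cohort$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Reconstructs the event bundles (absent streams stay absent), the EMA
#' table and the ground truth.
#'
#' @param dir cohort directory.
#' @return list `bundles`, `ema`, `ground_truth`, `participants`,
#'   `manifest`.
#' @export
read_cohort <- function(dir) {
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"),
                        stringsAsFactors = FALSE)
  gt$date <- as.Date(gt$date)
  ema <- utils::read.csv(file.path(dir, "ema.csv"), stringsAsFactors = FALSE)
  ema$referenced_date <- as.Date(ema$referenced_date)
  ema$answer[ema$answer == ""] <- NA
  participants <- utils::read.csv(file.path(dir, "demographics.csv"),
                                  stringsAsFactors = FALSE)
  streams_by_pid <- list()
  for (pid in unique(gt$participant_id)) {
    pdir <- file.path(dir, pid)
    streams_by_pid[[pid]] <- lapply(stats::setNames(PUT_STREAMS, PUT_STREAMS),
                                    function(s) {
      f <- file.path(pdir, paste0(s, ".jsonl"))
      if (!file.exists(f)) return(NULL)
      df <- jsonlite::stream_in(file(f), verbose = FALSE)
      df$date <- as.Date(df$date)
      df
    })
  }
  bundles <- lapply(seq_len(nrow(gt)), function(i) {
    pid <- gt$participant_id[i]; d <- gt$date[i]
    args <- list(participant_id = pid, date = d)
    for (s in PUT_STREAMS) {
      df <- streams_by_pid[[pid]][[s]]
      if (is.null(df)) next
      mine <- df[df$date == d, setdiff(names(df), "date"), drop = FALSE]
      if (nrow(mine) == 0L) next
      rownames(mine) <- NULL
      if (s == "steps") {
        v <- numeric(1440L)
        v[mine$minute + 1L] <- mine$steps
        args$steps <- v
      } else {
        args[[s]] <- mine
      }
    }
    do.call(event_bundle, args)
  })
  list(bundles = bundles, ema = ema, ground_truth = gt,
       participants = participants,
       manifest = yaml::read_yaml(file.path(dir, "manifest.yaml")))
}

#' Write a feature table (CSV)
#' @param features a feature table.
#' @param path output .csv path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#' @param path .csv path.
#' @return the feature table with dates restored.
#' @export
read_features <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  tab$date <- as.Date(tab$date)
  tab
}
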