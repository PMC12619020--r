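## Rare-event evaluation statistics: ranking metrics, paired nonparametric
## comparisons with multiplicity control, effect sizes, and run summaries.

#' Area under the ROC curve via the midrank statistic
#'
#' Computes AUROC as the normalized Mann-Whitney U statistic; tied scores
#' receive midranks, so ties contribute 1/2.
#'
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive.
#' @param scores numeric vector of the same length; higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores), !anyNA(labels), !anyNA(scores))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC undefined: need at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integration of the precision-recall curve over distinct score
#' thresholds (average precision), the usual estimator for imbalanced
#' rare-event reporting; no trapezoidal interpolation is applied.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(labels, scores) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores), !anyNA(labels), !anyNA(scores))
  n_pos <- sum(labels)
  if (n_pos == 0L || all(labels)) {
    stop("AUPR undefined: need at least one positive and one negative")
  }
  ## sweep thresholds over distinct score values, descending
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  ## threshold boundaries = last index of each tied block
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  d_rec <- diff(c(0, rec))
  sum(prec * d_rec)
}

#' Compute the full metric set for one evaluation run
#'
#' @param labels logical or 0/1 vector of true labels.
#' @param scores numeric anomaly/probability scores (higher = more positive).
#' @param flags logical predicted-positive indicators (thresholded decisions).
#' @return a `MetricSet`: list with `auroc`, `aupr`, `precision`, `recall`,
#'   `f1`, `n_pos`, `n_neg`.
#' @export
compute_metrics <- function(labels, scores, flags) {
  labels <- as.logical(labels)
  flags <- as.logical(flags)
  stopifnot(length(labels) == length(scores), length(labels) == length(flags))
  tp <- sum(flags & labels)
  fp <- sum(flags & !labels)
  fn <- sum(!flags & labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision > 0 && recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(
    list(auroc = auroc(labels, scores), aupr = aupr(labels, scores),
         precision = precision, recall = recall, f1 = f1,
         n_pos = sum(labels), n_neg = sum(!labels)),
    class = "put_metric_set"
  )
}

#' @export
print.put_metric_set <- function(x, ...) {
  cat(sprintf(
    "MetricSet (n_pos=%d, n_neg=%d): AUROC %.3f | AUPR %.3f | P %.3f | R %.3f | F1 %.3f\n",
    x$n_pos, x$n_neg, x$auroc, x$aupr, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Paired one-sided Wilcoxon signed-rank test
#'
#' Tests the alternative `a > b` on paired vectors. Zero differences are
#' dropped. With no ties among the absolute differences the exact
#' signed-rank null distribution is used for `n <= 25`; otherwise a normal
#' approximation with tie correction (and continuity correction) is applied.
#'
#' @param a,b numeric vectors of equal length (paired observations).
#' @return the one-sided p-value, or `NA` if all differences are zero.
#' @export
wilcoxon_paired_one_sided <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(NA_real_)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  has_ties <- any(duplicated(r))
  if (n <= 14L) {
    ## exact by sign-flip enumeration of the (mid)ranks: valid with ties
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    mean(w_all >= w - 1e-9)
  } else if (!has_ties && n <= 25L) {
    ## exact: P(W+ >= w) under the signed-rank null
    stats::psignrank(w - 1, n, lower.tail = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    tie_sizes <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    z <- (w - mu - 0.5) / sqrt(sigma2)
    stats::pnorm(z, lower.tail = FALSE)
  }
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1; input
#' order is preserved. `NA` entries stay `NA` and do not count toward m.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, elementwise `>=` the input.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Standardized mean difference with pooled standard deviation
#'
#' `smd = (m1 - m2) / sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param m1,s1,n1 mean, SD and size of group 1 (e.g. PUT days).
#' @param m2,s2,n2 mean, SD and size of group 2 (e.g. non-PUT days).
#' @return signed effect size; sign follows `m1 - m2`.
#' @export
standardized_mean_difference <- function(m1, s1, n1, m2, s2, n2) {
  if (any(c(s1, s2) <= 0)) stop("group SDs must be positive")
  if (any(c(n1, n2) < 2)) stop("group sizes must be >= 2")
  pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m1 - m2) / pooled
}

#' SMD of one feature between labeled groups of a feature table
#'
#' @param values numeric vector (may contain `NA`).
#' @param positive logical vector marking group-1 membership.
#' @return a list `SMDRecord` with group moments, sizes and `smd`.
#' @export
smd_record <- function(values, positive) {
  positive <- as.logical(positive)
  v1 <- values[positive & !is.na(values)]
  v2 <- values[!positive & !is.na(values)]
  if (length(v1) < 2 || length(v2) < 2) {
    return(list(mean_pos = NA_real_, sd_pos = NA_real_, n_pos = length(v1),
                mean_neg = NA_real_, sd_neg = NA_real_, n_neg = length(v2),
                smd = NA_real_))
  }
  list(mean_pos = mean(v1), sd_pos = stats::sd(v1), n_pos = length(v1),
       mean_neg = mean(v2), sd_neg = stats::sd(v2), n_neg = length(v2),
       smd = standardized_mean_difference(mean(v1), stats::sd(v1), length(v1),
                                          mean(v2), stats::sd(v2), length(v2)))
}

#' Relative improvement of a value over a reference, in percent
#'
#' @param value,reference numeric scalars; `reference` must be nonzero.
#' @param digits decimals for reporting (default 1, as in tabled summaries).
#' @return `100 * (value - reference) / reference`, rounded.
#' @export
relative_improvement <- function(value, reference, digits = 1) {
  if (reference == 0) stop("reference must be nonzero")
  round(100 * (value - reference) / reference, digits)
}

#' Summarize metric sets across runs as mean (SD)
#'
#' @param metric_sets list of `put_metric_set` objects.
#' @return a data.frame with one row per metric: `mean`, `sd`, and a
#'   `"0.xxx (0.yyy)"` formatted column.
#' @export
summarize_runs <- function(metric_sets) {
  stopifnot(length(metric_sets) >= 1L)
  metrics <- c("auroc", "aupr", "precision", "recall", "f1")
  m <- sapply(metrics, function(k) {
    vals <- vapply(metric_sets, function(s) s[[k]], numeric(1))
    c(mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0)
  })
  out <- data.frame(metric = metrics, mean = m["mean", ], sd = m["sd", ],
                    row.names = NULL)
  out$formatted <- sprintf("%.3f (%.3f)", out$mean, out$sd)
  out
}
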