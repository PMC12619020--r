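## Independent brute-force oracles used across the suite. These stay
## deliberately naive (loops, enumeration) and never share code with the
## implementation they check.

## AUROC as the probability that a random positive outscores a random
## negative (ties count 1/2), by exhaustive pairwise comparison
oracle_auroc <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

## average precision by walking the ranked list threshold by threshold
oracle_aupr <- function(labels, scores) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  ap <- 0
  prev_rec <- 0
  for (t in thr) {
    flag <- scores >= t
    tp <- sum(flag & labels)
    prec <- tp / sum(flag)
    rec <- tp / n_pos
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

## one-sided signed-rank p by enumerating every sign assignment
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  count <- 0
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    if (sum(r[signs == 1]) >= w_obs - 1e-9) count <- count + 1
  }
  count / 2^n
}

## BH step-up computed literally from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

## masked MSE by explicit looping over positions
oracle_masked_mse <- function(x, xhat, mask, scope = "full") {
  rows <- if (scope == "target_day") nrow(x) else seq_len(nrow(x))
  num <- 0; den <- 0
  for (t in rows) for (j in seq_len(ncol(x))) {
    if (mask[t, j]) {
      num <- num + (x[t, j] - xhat[t, j])^2
      den <- den + 1
    }
  }
  if (den == 0) NA_real_ else num / den
}

## minute-sweep duration of interval overlap with an epoch, in minutes
oracle_clip_minutes <- function(start_s, end_s, ep_start_s, ep_end_s) {
  secs <- 0
  for (s in seq(floor(ep_start_s), ceiling(ep_end_s) - 1)) {
    if (s >= start_s && s < end_s) secs <- secs + 1
  }
  secs / 60
}
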