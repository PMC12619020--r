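## LSTM-autoencoder numerics: stacked LSTM encoder -> repeated code ->
## stacked LSTM decoder -> time-distributed dense head, trained by Adam on
## the mask-aware mean squared reconstruction error. Implemented directly
## in (vectorized) base R; gradients are exact backpropagation through
## time and are verified against finite differences in the test suite.

sigm <- function(x) 1 / (1 + exp(-x))

## Glorot-uniform initialization of one LSTM layer (gate order i, f, g, o;
## forget-gate bias starts at 1)
lstm_layer_init <- function(d_in, d_h) {
  lim <- sqrt(6 / (d_in + 4 * d_h))
  limh <- sqrt(6 / (d_h + 4 * d_h))
  b <- numeric(4 * d_h)
  b[(d_h + 1):(2 * d_h)] <- 1
  list(Wx = matrix(stats::runif(d_in * 4 * d_h, -lim, lim), d_in, 4 * d_h),
       Wh = matrix(stats::runif(d_h * 4 * d_h, -limh, limh), d_h, 4 * d_h),
       b = b)
}

## forward pass of one LSTM layer over a list of T input matrices (n x D);
## returns hidden states and the per-step cache for backprop
lstm_forward <- function(Xs, layer) {
  Tn <- length(Xs)
  n <- nrow(Xs[[1]])
  H <- ncol(layer$Wh)/4
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  hs <- vector("list", Tn); cache <- vector("list", Tn)
  gi <- 1:H; gf <- H + gi; gg <- 2 * H + gi; go <- 3 * H + gi
  for (t in seq_len(Tn)) {
    z <- Xs[[t]] %*% layer$Wx + h %*% layer$Wh +
      matrix(layer$b, n, 4 * H, byrow = TRUE)
    i <- sigm(z[, gi, drop = FALSE])
    f <- sigm(z[, gf, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE])
    o <- sigm(z[, go, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(x = Xs[[t]], h_prev = h, c_prev = cc, i = i, f = f,
                       g = g, o = o, tc = tc)
    h <- h_new; cc <- c_new
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

## backward pass of one LSTM layer; dhs is a list of gradients w.r.t. each
## hidden state (zero matrices where no loss attaches). Returns input
## gradients and parameter gradients.
lstm_backward <- function(dhs, layer, cache) {
  Tn <- length(dhs)
  n <- nrow(dhs[[1]])
  H <- ncol(layer$Wh)/4
  dWx <- layer$Wx * 0; dWh <- layer$Wh * 0; db <- layer$b * 0
  dxs <- vector("list", Tn)
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(Tn))) {
    k <- cache[[t]]
    dh <- dhs[[t]] + dh_next
    do_ <- dh * k$tc
    dc <- dh * k$o * (1 - k$tc^2) + dc_next
    di <- dc * k$g
    df <- dc * k$c_prev
    dg <- dc * k$i
    dc_next <- dc * k$f
    dz <- cbind(di * k$i * (1 - k$i), df * k$f * (1 - k$f),
                dg * (1 - k$g^2), do_ * k$o * (1 - k$o))
    dWx <- dWx + crossprod(k$x, dz)
    dWh <- dWh + crossprod(k$h_prev, dz)
    db <- db + colSums(dz)
    dxs[[t]] <- dz %*% t(layer$Wx)
    dh_next <- dz %*% t(layer$Wh)
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

## initialize the full autoencoder parameter set
ae_init_params <- function(n_features, hidden = c(64, 32)) {
  h1 <- hidden[1]; h2 <- hidden[2]
  list(enc1 = lstm_layer_init(n_features, h1),
       enc2 = lstm_layer_init(h1, h2),
       dec1 = lstm_layer_init(h2, h2),
       dec2 = lstm_layer_init(h2, h1),
       dense = list(W = matrix(stats::runif(h1 * n_features,
                                            -sqrt(6 / (h1 + n_features)),
                                            sqrt(6 / (h1 + n_features))),
                               h1, n_features),
                    b = numeric(n_features)))
}

## full forward pass: values (n x T x F, masked entries zero-filled)
## -> reconstruction (n x T x F) plus caches
ae_forward <- function(vals, params) {
  d <- dim(vals)
  n <- d[1]; Tn <- d[2]; nf <- d[3]
  Xs <- lapply(seq_len(Tn), function(t) matrix(vals[, t, ], nrow = n))
  e1 <- lstm_forward(Xs, params$enc1)
  e2 <- lstm_forward(e1$hs, params$enc2)
  code <- e2$hs[[Tn]]
  rep_code <- rep(list(code), Tn)
  d1 <- lstm_forward(rep_code, params$dec1)
  d2 <- lstm_forward(d1$hs, params$dec2)
  xhat <- array(0, d)
  for (t in seq_len(Tn)) {
    xhat[, t, ] <- d2$hs[[t]] %*% params$dense$W +
      matrix(params$dense$b, n, nf, byrow = TRUE)
  }
  list(xhat = xhat, Xs = Xs, e1 = e1, e2 = e2, d1 = d1, d2 = d2)
}

## loss + exact gradients of the masked MSE over a batch
ae_loss_grad <- function(vals, mask, params) {
  fw <- ae_forward(vals, params)
  d <- dim(vals)
  n <- d[1]; Tn <- d[2]; nf <- d[3]
  n_obs <- sum(mask)
  if (n_obs == 0) stop("batch has no observed entries")
  resid <- (fw$xhat - vals) * mask
  loss <- sum(resid^2) / n_obs
  dxhat <- 2 * resid / n_obs
  gW <- params$dense$W * 0; gb <- params$dense$b * 0
  dh_d2 <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dm <- matrix(dxhat[, t, ], nrow = n)
    gW <- gW + crossprod(fw$d2$hs[[t]], dm)
    gb <- gb + colSums(dm)
    dh_d2[[t]] <- dm %*% t(params$dense$W)
  }
  b2 <- lstm_backward(dh_d2, params$dec2, fw$d2$cache)
  b1 <- lstm_backward(b2$dxs, params$dec1, fw$d1$cache)
  dcode <- Reduce(`+`, b1$dxs)
  H2 <- ncol(dcode)
  zero2 <- matrix(0, n, H2)
  dh_e2 <- rep(list(zero2), Tn)
  dh_e2[[Tn]] <- dcode
  be2 <- lstm_backward(dh_e2, params$enc2, fw$e2$cache)
  be1 <- lstm_backward(be2$dxs, params$enc1, fw$e1$cache)
  grads <- list(
    enc1 = list(Wx = be1$dWx, Wh = be1$dWh, b = be1$db),
    enc2 = list(Wx = be2$dWx, Wh = be2$dWh, b = be2$db),
    dec1 = list(Wx = b1$dWx, Wh = b1$dWh, b = b1$db),
    dec2 = list(Wx = b2$dWx, Wh = b2$dWh, b = b2$db),
    dense = list(W = gW, b = gb))
  list(loss = loss, grads = grads)
}

## Adam update (in place on the param list); state carries m, v, step
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  state$t <- state$t + 1L
  ## global gradient-norm clipping
  gn <- sqrt(sum(unlist(lapply(grads, function(l)
    lapply(l, function(g) sum(g^2))))))
  scale <- if (gn > clip) clip / gn else 1
  for (mod in names(grads)) {
    for (p in names(grads[[mod]])) {
      g <- grads[[mod]][[p]] * scale
      key <- paste(mod, p)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0; state$v[[key]] <- g * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      mhat <- state$m[[key]] / (1 - beta1^state$t)
      vhat <- state$v[[key]] / (1 - beta2^state$t)
      params[[mod]][[p]] <- params[[mod]][[p]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}
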