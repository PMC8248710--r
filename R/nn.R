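# Native neural-network primitives for the detector zoo: LSTM and GRU
# layers (GRU with separate input/recurrent biases, the convention whose
# parameter count is 3*(dH + H^2 + 2H)), bidirectional wrapping, a small
# 2-D convolutional front end, a time-distributed dense head, and Adam.
#
# Batches of equal-length sequences are stored as a single (B*T) x d
# matrix with rows ordered (t, b): row (t-1)*B + b holds sequence b at
# frame t. Input projections are then one large BLAS matmul; only the
# O(B x H) recurrence runs in an R loop.

sigmoid <- function(x) 1 / (1 + exp(-x))

rows_of_t <- function(t, B) ((t - 1L) * B + 1L):(t * B)

# Reverse the time axis of a (B*T) x d stacked batch.
reverse_time <- function(M, B, T) {
  idx <- rep((T:1) - 1L, each = B) * B + rep(seq_len(B), times = T)
  M[idx, , drop = FALSE]
}

# Stack a list of T x d matrices into the (B*T) x d layout.
stack_batch <- function(xs) {
  B <- length(xs); T <- nrow(xs[[1]]); d <- ncol(xs[[1]])
  out <- matrix(0, B * T, d)
  for (b in seq_len(B)) out[seq(b, B * T, by = B), ] <- xs[[b]]
  out
}

stack_targets <- function(ys) {
  B <- length(ys); T <- length(ys[[1]])
  out <- numeric(B * T)
  for (b in seq_len(B)) out[seq(b, B * T, by = B)] <- ys[[b]]
  out
}

# -- initializers ------------------------------------------------------------

glorot_uniform <- function(fan_in, fan_out, nrow = fan_in, ncol = fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -l, l), nrow, ncol)
}

orthogonal_init <- function(H, n_gates) {
  blocks <- lapply(seq_len(n_gates), function(i) {
    qr.Q(qr(matrix(stats::rnorm(H * H), H, H)))
  })
  do.call(cbind, blocks)
}

# Cached per-step activations are stored time-contiguously as B x (H*T)
# matrices (block t in columns (t-1)*H+1 .. t*H), so the per-step reads and
# writes in the recurrence touch contiguous memory. bt_layout() converts a
# block matrix back to the (B*T) x H stacked layout for the BLAS matmuls.

bt_layout <- function(M, B, T, H) {
  dim(M) <- c(B, H, T)
  M <- aperm(M, c(1, 3, 2))
  dim(M) <- c(B * T, H)
  M
}

tb_layout <- function(M, B, T, H) {
  dim(M) <- c(B, T, H)
  M <- aperm(M, c(1, 3, 2))
  dim(M) <- c(B, H * T)
  M
}

# Previous-state stack: zeros at t=1, then blocks 1..T-1.
shift_blocks <- function(M, B, T, H) {
  cbind(matrix(0, B, H), M[, seq_len(H * (T - 1)), drop = FALSE])
}

# -- LSTM --------------------------------------------------------------------
# Gate order i, f, g (cell candidate), o; single bias; forget bias 1.

init_lstm <- function(d, H) {
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1
  list(Wx = glorot_uniform(d, 4 * H), Wh = orthogonal_init(H, 4), b = b)
}

lstm_forward <- function(p, X, B, T, keep_cache = TRUE) {
  H <- ncol(p$Wh) / 4
  Xp <- X %*% p$Wx
  Bb <- matrix(p$b, B, 4 * H, byrow = TRUE)
  ii <- 1:H; fi <- (H + 1):(2 * H); gi <- (2 * H + 1):(3 * H); oi <- (3 * H + 1):(4 * H)
  G <- if (keep_cache) matrix(0, B, 4 * H * T)
  Cc <- if (keep_cache) matrix(0, B, H * T)
  TC <- if (keep_cache) matrix(0, B, H * T)
  Hc <- matrix(0, B, H * T)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  for (t in seq_len(T)) {
    r <- rows_of_t(t, B)
    a <- Xp[r, , drop = FALSE] + h %*% p$Wh + Bb
    i <- sigmoid(a[, ii, drop = FALSE]); f <- sigmoid(a[, fi, drop = FALSE])
    g <- tanh(a[, gi, drop = FALSE]);    o <- sigmoid(a[, oi, drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    ct <- ((t - 1) * H + 1):(t * H)
    if (keep_cache) {
      G[, ((t - 1) * 4 * H + 1):(t * 4 * H)] <- cbind(i, f, g, o)
      Cc[, ct] <- cc; TC[, ct] <- tc
    }
    Hc[, ct] <- h
  }
  list(out = bt_layout(Hc, B, T, H),
       cache = if (keep_cache) list(G = G, C = Cc, TC = TC, Hc = Hc))
}

lstm_backward <- function(p, X, cache, dOut, B, T) {
  H <- ncol(p$Wh) / 4
  dOutC <- tb_layout(dOut, B, T, H)
  Cprev <- shift_blocks(cache$C, B, T, H)
  dA <- matrix(0, B, 4 * H * T)
  dh <- matrix(0, B, H); dc <- matrix(0, B, H)
  tWh <- t(p$Wh)
  for (t in rev(seq_len(T))) {
    ct <- ((t - 1) * H + 1):(t * H)
    gt <- ((t - 1) * 4 * H + 1):(t * 4 * H)
    dh <- dh + dOutC[, ct, drop = FALSE]
    G <- cache$G[, gt, drop = FALSE]
    i <- G[, 1:H, drop = FALSE]; f <- G[, (H + 1):(2 * H), drop = FALSE]
    g <- G[, (2 * H + 1):(3 * H), drop = FALSE]; o <- G[, (3 * H + 1):(4 * H), drop = FALSE]
    tc <- cache$TC[, ct, drop = FALSE]
    dc <- dc + dh * o * (1 - tc^2)
    da <- cbind(
      dc * g * i * (1 - i),
      dc * Cprev[, ct, drop = FALSE] * f * (1 - f),
      dc * i * (1 - g^2),
      dh * tc * o * (1 - o)
    )
    dA[, gt] <- da
    dh <- da %*% tWh
    dc <- dc * f
  }
  dA <- bt_layout(dA, B, T, 4 * H)
  Hprev <- bt_layout(shift_blocks(cache$Hc, B, T, H), B, T, H)
  list(
    dX = dA %*% t(p$Wx),
    grads = list(Wx = crossprod(X, dA), Wh = crossprod(Hprev, dA),
                 b = colSums(dA))
  )
}

# -- GRU (separate input and recurrent biases) -------------------------------
# Gate order z (update), r (reset), c (candidate); the reset gate is
# applied after the recurrent matmul.

init_gru <- function(d, H) {
  list(Wx = glorot_uniform(d, 3 * H), Wh = orthogonal_init(H, 3),
       b_in = numeric(3 * H), b_rec = numeric(3 * H))
}

gru_forward <- function(p, X, B, T, keep_cache = TRUE) {
  H <- ncol(p$Wh) / 3
  Xp <- X %*% p$Wx
  Ball <- matrix(p$b_in + p$b_rec, B, 3 * H, byrow = TRUE)
  Ball[, (2 * H + 1):(3 * H)] <- matrix(p$b_in[(2 * H + 1):(3 * H)], B, H, byrow = TRUE)
  Brec_c <- matrix(p$b_rec[(2 * H + 1):(3 * H)], B, H, byrow = TRUE)
  zi <- 1:H; ri <- (H + 1):(2 * H); ci <- (2 * H + 1):(3 * H)
  Whc <- p$Wh[, ci, drop = FALSE]
  Whzr <- p$Wh[, 1:(2 * H), drop = FALSE]
  Z <- if (keep_cache) matrix(0, B, H * T)
  R <- if (keep_cache) matrix(0, B, H * T)
  Cc <- if (keep_cache) matrix(0, B, H * T)
  HHR <- if (keep_cache) matrix(0, B, H * T)
  Hc <- matrix(0, B, H * T)
  h <- matrix(0, B, H)
  for (t in seq_len(T)) {
    rws <- rows_of_t(t, B)
    a <- Xp[rws, , drop = FALSE] + Ball
    azr <- a[, 1:(2 * H), drop = FALSE] + h %*% Whzr
    z <- sigmoid(azr[, zi, drop = FALSE])
    r <- sigmoid(azr[, ri, drop = FALSE])
    hhr <- h %*% Whc + Brec_c
    cnd <- tanh(a[, ci, drop = FALSE] + r * hhr)
    ct <- ((t - 1) * H + 1):(t * H)
    if (keep_cache) {
      Z[, ct] <- z; R[, ct] <- r; Cc[, ct] <- cnd; HHR[, ct] <- hhr
    }
    h <- z * h + (1 - z) * cnd
    Hc[, ct] <- h
  }
  list(out = bt_layout(Hc, B, T, H),
       cache = if (keep_cache) list(Z = Z, R = R, C = Cc, HHR = HHR, Hc = Hc))
}

gru_backward <- function(p, X, cache, dOut, B, T) {
  H <- ncol(p$Wh) / 3
  dOutC <- tb_layout(dOut, B, T, H)
  Hprev <- shift_blocks(cache$Hc, B, T, H)
  dXp <- matrix(0, B, 3 * H * T)
  dHp <- matrix(0, B, 3 * H * T)
  dh <- matrix(0, B, H)
  tWh <- t(p$Wh)
  for (t in rev(seq_len(T))) {
    ct <- ((t - 1) * H + 1):(t * H)
    gt <- ((t - 1) * 3 * H + 1):(t * 3 * H)
    dh <- dh + dOutC[, ct, drop = FALSE]
    z <- cache$Z[, ct, drop = FALSE]; r <- cache$R[, ct, drop = FALSE]
    cnd <- cache$C[, ct, drop = FALSE]; hhr <- cache$HHR[, ct, drop = FALSE]
    hprev <- Hprev[, ct, drop = FALSE]
    dz <- dh * (hprev - cnd) * z * (1 - z)
    dac <- dh * (1 - z) * (1 - cnd^2)
    dr <- dac * hhr * r * (1 - r)
    dhhr <- dac * r
    dXp[, gt] <- cbind(dz, dr, dac)
    dhp <- cbind(dz, dr, dhhr)
    dHp[, gt] <- dhp
    dh <- dh * z + dhp %*% tWh
  }
  dXp <- bt_layout(dXp, B, T, 3 * H)
  dHp <- bt_layout(dHp, B, T, 3 * H)
  HprevS <- bt_layout(Hprev, B, T, H)
  list(
    dX = dXp %*% t(p$Wx),
    grads = list(Wx = crossprod(X, dXp), Wh = crossprod(HprevS, dHp),
                 b_in = colSums(dXp), b_rec = colSums(dHp))
  )
}

# -- recurrent layer wrapper (uni/bidirectional) -----------------------------

init_rnn_layer <- function(cell, d, H, bidirectional) {
  init1 <- if (cell == "lstm") init_lstm else init_gru
  layer <- list(type = "rnn", cell = cell, units = H, input_dim = d,
                bidirectional = bidirectional,
                params = list(fwd = init1(d, H)))
  if (bidirectional) layer$params$bwd <- init1(d, H)
  layer
}

rnn_layer_forward <- function(layer, X, B, T, keep_cache = TRUE) {
  fwd_fn <- if (layer$cell == "lstm") lstm_forward else gru_forward
  f <- fwd_fn(layer$params$fwd, X, B, T, keep_cache)
  if (!layer$bidirectional) {
    return(list(out = f$out, cache = list(fwd = f$cache)))
  }
  Xr <- reverse_time(X, B, T)
  bwd <- fwd_fn(layer$params$bwd, Xr, B, T, keep_cache)
  out <- cbind(f$out, reverse_time(bwd$out, B, T))
  list(out = out, cache = list(fwd = f$cache, bwd = bwd$cache, Xr = if (keep_cache) Xr))
}

rnn_layer_backward <- function(layer, X, cache, dOut, B, T) {
  bwd_fn <- if (layer$cell == "lstm") lstm_backward else gru_backward
  H <- layer$units
  if (!layer$bidirectional) {
    res <- bwd_fn(layer$params$fwd, X, cache$fwd, dOut, B, T)
    return(list(dX = res$dX, grads = list(fwd = res$grads)))
  }
  dF <- dOut[, 1:H, drop = FALSE]
  dB <- reverse_time(dOut[, (H + 1):(2 * H), drop = FALSE], B, T)
  rf <- bwd_fn(layer$params$fwd, X, cache$fwd, dF, B, T)
  rb <- bwd_fn(layer$params$bwd, cache$Xr, cache$bwd, dB, B, T)
  list(dX = rf$dX + reverse_time(rb$dX, B, T),
       grads = list(fwd = rf$grads, bwd = rb$grads))
}

# -- time-distributed dense head ---------------------------------------------

init_head <- function(d, hidden = 32) {
  list(W1 = glorot_uniform(d, hidden), b1 = numeric(hidden),
       W2 = glorot_uniform(hidden, 1), b2 = numeric(1))
}

head_forward <- function(p, X, keep_cache = TRUE) {
  A1 <- sweep(X %*% p$W1, 2, p$b1, `+`)
  R1 <- pmax(A1, 0)
  logit <- as.numeric(R1 %*% p$W2) + p$b2
  list(scores = sigmoid(logit), logit = logit,
       cache = if (keep_cache) list(R1 = R1))
}

head_backward <- function(p, X, cache, dlogit) {
  dlogit <- as.numeric(dlogit)
  dR1 <- outer(dlogit, as.numeric(p$W2))
  dA1 <- dR1 * (cache$R1 > 0)
  list(
    dX = dA1 %*% t(p$W1),
    grads = list(W1 = crossprod(X, dA1), b1 = colSums(dA1),
                 W2 = matrix(colSums(cache$R1 * dlogit), ncol = 1),
                 b2 = sum(dlogit))
  )
}

# -- convolutional front end -------------------------------------------------
# Conv2D(32, 3x5, same) + BatchNorm + ReLU, Conv2D(64, 3x11, same) + ReLU,
# MaxPool 2x2 (same padding on odd axes). Input is one sequence's T x F
# feature matrix treated as a 1-channel image; output is (T/2) x (ceil(F/2)*64).

init_conv_front <- function(F_in = 193) {
  list(
    W1 = glorot_uniform(3 * 5 * 1, 32, nrow = 15, ncol = 32), b1 = numeric(32),
    gamma = rep(1, 32), beta = numeric(32),
    run_mean = numeric(32), run_var = rep(1, 32),
    W2 = glorot_uniform(3 * 11 * 32, 64, nrow = 3 * 11 * 32, ncol = 64),
    b2 = numeric(64)
  )
}

# im2col for a T x F x C stack (C matrices of T x F), kernel kt x kf, same
# padding: returns (T*F) x (kt*kf*C), rows in column-major (t fastest) order.
im2col_same <- function(chans, kt, kf) {
  T <- nrow(chans[[1]]); F <- ncol(chans[[1]])
  pt <- (kt - 1) %/% 2; pf <- (kf - 1) %/% 2
  C <- length(chans)
  out <- matrix(0, T * F, kt * kf * C)
  col <- 0L
  for (c in seq_len(C)) {
    padded <- matrix(0, T + 2 * pt, F + 2 * pf)
    padded[(pt + 1):(pt + T), (pf + 1):(pf + F)] <- chans[[c]]
    for (df in seq_len(kf)) {
      for (dt in seq_len(kt)) {
        col <- col + 1L
        out[, col] <- as.vector(padded[dt:(dt + T - 1), df:(df + F - 1)])
      }
    }
  }
  out
}

# Scatter-add transpose of im2col_same: dcols is (T*F) x (kt*kf*C).
col2im_same <- function(dcols, T, F, C, kt, kf) {
  pt <- (kt - 1) %/% 2; pf <- (kf - 1) %/% 2
  chans <- vector("list", C)
  col <- 0L
  for (c in seq_len(C)) {
    padded <- matrix(0, T + 2 * pt, F + 2 * pf)
    for (df in seq_len(kf)) {
      for (dt in seq_len(kt)) {
        col <- col + 1L
        padded[dt:(dt + T - 1), df:(df + F - 1)] <-
          padded[dt:(dt + T - 1), df:(df + F - 1)] + matrix(dcols[, col], T, F)
      }
    }
    chans[[c]] <- padded[(pt + 1):(pt + T), (pf + 1):(pf + F)]
  }
  chans
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

conv_front_forward <- function(p, X, training = FALSE, keep_cache = TRUE) {
  T <- nrow(X); F <- ncol(X)
  cols1 <- im2col_same(list(X), 3, 5)
  A1 <- sweep(cols1 %*% p$W1, 2, p$b1, `+`)          # (T*F) x 32
  if (training) {
    mu <- colMeans(A1)
    v <- colMeans(sweep(A1, 2, mu, `-`)^2)
  } else {
    mu <- p$run_mean; v <- p$run_var
  }
  Ahat <- sweep(sweep(A1, 2, mu, `-`), 2, sqrt(v + BN_EPS), `/`)
  Bn <- sweep(sweep(Ahat, 2, p$gamma, `*`), 2, p$beta, `+`)
  R1 <- pmax(Bn, 0)
  chans1 <- lapply(seq_len(32), function(c) matrix(R1[, c], T, F))
  # second conv, chunked over time to bound the im2col working set
  A2 <- matrix(0, T * F, 64)
  chunk <- 128L
  padded <- lapply(chans1, function(m) {
    pm <- matrix(0, T + 2, F)  # time padding only; freq handled inside im2col
    pm[2:(T + 1), ] <- m
    pm
  })
  for (t0 in seq(1, T, by = chunk)) {
    t1 <- min(T, t0 + chunk - 1L)
    sub <- lapply(padded, function(m) m[t0:(t1 + 2), , drop = FALSE])
    cols <- im2col_valid_time(sub, 3, 11)
    Ac <- sweep(cols %*% p$W2, 2, p$b2, `+`)
    rows <- as.vector(outer(t0:t1, (seq_len(F) - 1) * T, `+`))
    A2[rows, ] <- Ac
  }
  R2 <- pmax(A2, 0)
  # max pool 2x2, same padding (ceil) on both axes
  poolres <- pool2x2(R2, T, F, 64)
  list(out = poolres$out, cache = if (keep_cache) {
    list(cols1 = cols1, A1 = A1, mu = mu, v = v, Ahat = Ahat, Bn = Bn,
         R1 = R1, A2 = A2, R2 = R2, argmax = poolres$argmax, T = T, F = F)
  }, batch_mu = if (training) mu, batch_var = if (training) v)
}

# im2col over channels already padded in time by pt=1; freq same-padded here.
im2col_valid_time <- function(chans, kt, kf) {
  Tp <- nrow(chans[[1]]); F <- ncol(chans[[1]])
  T <- Tp - (kt - 1)
  pf <- (kf - 1) %/% 2
  C <- length(chans)
  out <- matrix(0, T * F, kt * kf * C)
  col <- 0L
  for (c in seq_len(C)) {
    padded <- matrix(0, Tp, F + 2 * pf)
    padded[, (pf + 1):(pf + F)] <- chans[[c]]
    for (df in seq_len(kf)) {
      for (dt in seq_len(kt)) {
        col <- col + 1L
        out[, col] <- as.vector(padded[dt:(dt + T - 1), df:(df + F - 1)])
      }
    }
  }
  out
}

# 2x2 max pool with ceil semantics on a (T*F) x C column-major stack.
# Output is T2 x (F2*C) with feature order (freq-major, channel within).
pool2x2 <- function(R2, T, F, C) {
  T2 <- (T + 1) %/% 2; F2 <- (F + 1) %/% 2
  neg <- -Inf
  out <- matrix(0, T2, F2 * C)
  argmax <- integer(T2 * F2 * C)
  for (c in seq_len(C)) {
    M <- matrix(R2[, c], T, F)
    Mp <- matrix(neg, 2 * T2, 2 * F2)
    Mp[1:T, 1:F] <- M
    q11 <- Mp[seq(1, 2 * T2, 2), seq(1, 2 * F2, 2), drop = FALSE]
    q21 <- Mp[seq(2, 2 * T2, 2), seq(1, 2 * F2, 2), drop = FALSE]
    q12 <- Mp[seq(1, 2 * T2, 2), seq(2, 2 * F2, 2), drop = FALSE]
    q22 <- Mp[seq(2, 2 * T2, 2), seq(2, 2 * F2, 2), drop = FALSE]
    mx <- pmax(q11, q21, q12, q22)
    which4 <- (q21 == mx) * 1L
    which4[q12 == mx] <- 2L
    which4[q22 == mx] <- 3L
    which4[q11 == mx] <- 0L   # ties prefer top-left, deterministic
    cols <- ((c - 1) * F2 + 1):(c * F2)
    out[, cols] <- mx
    argmax[((c - 1) * T2 * F2 + 1):(c * T2 * F2)] <- as.vector(which4)
  }
  list(out = out, argmax = argmax)
}

conv_front_backward <- function(p, X, cache, dOut) {
  T <- cache$T; F <- cache$F
  T2 <- (T + 1) %/% 2; F2 <- (F + 1) %/% 2
  # unpool
  dR2 <- matrix(0, T * F, 64)
  for (c in seq_len(64)) {
    dM <- matrix(0, T, F)
    dP <- matrix(dOut[, ((c - 1) * F2 + 1):(c * F2), drop = FALSE], T2, F2)
    wh <- matrix(cache$argmax[((c - 1) * T2 * F2 + 1):(c * T2 * F2)], T2, F2)
    tt <- rep(seq_len(T2), F2); ff <- rep(seq_len(F2), each = T2)
    rt <- 2 * tt - 1 + (as.vector(wh) %in% c(1L, 3L))
    rf <- 2 * ff - 1 + (as.vector(wh) %in% c(2L, 3L))
    ok <- rt <= T & rf <= F
    dM[cbind(rt[ok], rf[ok])] <- as.vector(dP)[ok]
    dR2[, c] <- as.vector(dM)
  }
  dA2 <- dR2 * (cache$A2 > 0)
  # conv2 backward (chunked)
  chans1 <- lapply(seq_len(32), function(c) matrix(cache$R1[, c], T, F))
  padded <- lapply(chans1, function(m) { pm <- matrix(0, T + 2, F); pm[2:(T + 1), ] <- m; pm })
  dW2 <- matrix(0, nrow(p$W2), 64); db2 <- numeric(64)
  dR1 <- matrix(0, T * F, 32)
  dpadded <- lapply(seq_len(32), function(c) matrix(0, T + 2, F))
  chunk <- 128L
  for (t0 in seq(1, T, by = chunk)) {
    t1 <- min(T, t0 + chunk - 1L)
    sub <- lapply(padded, function(m) m[t0:(t1 + 2), , drop = FALSE])
    cols <- im2col_valid_time(sub, 3, 11)
    rows <- as.vector(outer(t0:t1, (seq_len(F) - 1) * T, `+`))
    dAc <- dA2[rows, , drop = FALSE]
    dW2 <- dW2 + crossprod(cols, dAc)
    db2 <- db2 + colSums(dAc)
    dcols <- dAc %*% t(p$W2)
    dsub <- col2im_valid_time(dcols, t1 - t0 + 3L, F, 32, 3, 11)
    for (c in seq_len(32)) {
      dpadded[[c]][t0:(t1 + 2), ] <- dpadded[[c]][t0:(t1 + 2), ] + dsub[[c]]
    }
  }
  for (c in seq_len(32)) dR1[, c] <- as.vector(dpadded[[c]][2:(T + 1), ])
  dBn <- dR1 * (cache$Bn > 0)
  # batch-norm backward (batch statistics)
  n <- nrow(dBn)
  dgamma <- colSums(dBn * cache$Ahat)
  dbeta <- colSums(dBn)
  dAhat <- sweep(dBn, 2, p$gamma, `*`)
  inv_sd <- 1 / sqrt(cache$v + BN_EPS)
  xmu <- sweep(cache$A1, 2, cache$mu, `-`)
  dvar <- colSums(dAhat * xmu) * (-0.5) * inv_sd^3
  dmu <- colSums(sweep(dAhat, 2, -inv_sd, `*`)) + dvar * colMeans(-2 * xmu)
  dA1 <- sweep(dAhat, 2, inv_sd, `*`) +
    sweep(xmu, 2, 2 * dvar / n, `*`) +
    matrix(dmu / n, n, 32, byrow = TRUE)
  dW1 <- crossprod(cache$cols1, dA1)
  db1 <- colSums(dA1)
  list(grads = list(W1 = dW1, b1 = db1, gamma = dgamma, beta = dbeta,
                    W2 = dW2, b2 = db2))
}

col2im_valid_time <- function(dcols, Tp, F, C, kt, kf) {
  T <- Tp - (kt - 1)
  pf <- (kf - 1) %/% 2
  chans <- vector("list", C)
  col <- 0L
  for (c in seq_len(C)) {
    padded <- matrix(0, Tp, F + 2 * pf)
    for (df in seq_len(kf)) {
      for (dt in seq_len(kt)) {
        col <- col + 1L
        padded[dt:(dt + T - 1), df:(df + F - 1)] <-
          padded[dt:(dt + T - 1), df:(df + F - 1)] + matrix(dcols[, col], T, F)
      }
    }
    chans[[c]] <- padded[, (pf + 1):(pf + F), drop = FALSE]
  }
  chans
}

# -- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_step <- function(params, grads, m, v, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mhat <- m2 / (1 - beta1^step)
      vhat <- v2 / (1 - beta2^step)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    }
  }
  walk(params, grads, m, v)
}
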