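# Low-level neural-network operations: LSTM cell with sequence masking,
# bidirectional wrapper, masked max pooling over time, softmax, and Adam.
# All batched: a timestep is a (batch x dim) matrix, a sequence a list of
# timesteps, a mask a (batch x T) 0/1 matrix. Analytic gradients are verified
# against central finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Masked LSTM over T timesteps. At masked steps the hidden and cell states are
# carried through unchanged, so padding never influences the encoding.
# W: (din x 4h), U: (h x 4h), b: length 4h; gate order i, f, o, g.
lstm_forward <- function(X, mask, W, U, b) {
  T_ <- length(X)
  B <- nrow(X[[1L]])
  h <- nrow(U)
  bmat <- matrix(b, B, 4L * h, byrow = TRUE)
  idx_i <- seq_len(h); idx_f <- h + idx_i; idx_o <- 2L * h + idx_i
  idx_g <- 3L * h + idx_i
  Hprev <- matrix(0, B, h)
  Cprev <- matrix(0, B, h)
  H <- vector("list", T_)
  steps <- vector("list", T_)
  for (t in seq_len(T_)) {
    A <- X[[t]] %*% W + Hprev %*% U + bmat
    i <- sigmoid(A[, idx_i, drop = FALSE])
    f <- sigmoid(A[, idx_f, drop = FALSE])
    o <- sigmoid(A[, idx_o, drop = FALSE])
    g <- tanh(A[, idx_g, drop = FALSE])
    ctilde <- f * Cprev + i * g
    tanhc <- tanh(ctilde)
    htilde <- o * tanhc
    m <- mask[, t]
    Ht <- htilde * m + Hprev * (1 - m)
    Ct <- ctilde * m + Cprev * (1 - m)
    steps[[t]] <- list(x = X[[t]], hprev = Hprev, cprev = Cprev,
                       i = i, f = f, o = o, g = g, tanhc = tanhc, m = m)
    Hprev <- Ht
    Cprev <- Ct
    H[[t]] <- Ht
  }
  list(H = H, steps = steps, W = W, U = U)
}

# dH: list over t of gradients w.r.t. the (post-mask) hidden outputs.
lstm_backward <- function(fw, dH) {
  steps <- fw$steps
  W <- fw$W; U <- fw$U
  T_ <- length(steps)
  B <- nrow(steps[[1L]]$x)
  h <- nrow(U)
  dW <- matrix(0, nrow(W), ncol(W))
  dU <- matrix(0, h, 4L * h)
  db <- numeric(4L * h)
  dX <- vector("list", T_)
  dh_next <- matrix(0, B, h)
  dc_next <- matrix(0, B, h)
  for (t in rev(seq_len(T_))) {
    st <- steps[[t]]
    dh <- dH[[t]] + dh_next
    dc <- dc_next
    m <- st$m
    dhtilde <- dh * m
    dctilde <- dc * m + dhtilde * st$o * (1 - st$tanhc^2)
    do_ <- dhtilde * st$tanhc
    di <- dctilde * st$g
    df <- dctilde * st$cprev
    dg <- dctilde * st$i
    da <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do_ * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    dX[[t]] <- da %*% t(W)
    dW <- dW + crossprod(st$x, da)
    dU <- dU + crossprod(st$hprev, da)
    db <- db + colSums(da)
    dh_next <- dh * (1 - m) + da %*% t(U)
    dc_next <- dctilde * st$f + dc * (1 - m)
  }
  list(dX = dX, dW = dW, dU = dU, db = db)
}

# Bidirectional LSTM: forward read plus a reversed-time read; per-step output
# is the concatenation [h_forward(t), h_backward(t)].
bilstm_forward <- function(X, mask, p) {
  T_ <- length(X)
  fw <- lstm_forward(X, mask, p$Wf, p$Uf, p$bf)
  Xr <- X[rev(seq_len(T_))]
  maskr <- mask[, rev(seq_len(T_)), drop = FALSE]
  bw <- lstm_forward(Xr, maskr, p$Wb, p$Ub, p$bb)
  H <- vector("list", T_)
  for (t in seq_len(T_)) {
    H[[t]] <- cbind(fw$H[[t]], bw$H[[T_ - t + 1L]])
  }
  list(H = H, fw = fw, bw = bw, T_ = T_, h = nrow(p$Uf))
}

bilstm_backward <- function(bi, dH) {
  T_ <- bi$T_
  h <- bi$h
  dHf <- lapply(dH, function(d) d[, seq_len(h), drop = FALSE])
  dHb <- vector("list", T_)
  for (s in seq_len(T_)) {
    dHb[[s]] <- dH[[T_ - s + 1L]][, h + seq_len(h), drop = FALSE]
  }
  gf <- lstm_backward(bi$fw, dHf)
  gb <- lstm_backward(bi$bw, dHb)
  dX <- vector("list", T_)
  for (t in seq_len(T_)) {
    dX[[t]] <- gf$dX[[t]] + gb$dX[[T_ - t + 1L]]
  }
  list(dX = dX,
       dWf = gf$dW, dUf = gf$dU, dbf = gf$db,
       dWb = gb$dW, dUb = gb$dU, dbb = gb$db)
}

# Element-wise max over valid timesteps; argmax kept for gradient routing.
masked_max_pool <- function(H, mask) {
  T_ <- length(H)
  B <- nrow(H[[1L]])
  D <- ncol(H[[1L]])
  pooled <- matrix(-Inf, B, D)
  arg <- matrix(0L, B, D)
  for (t in seq_len(T_)) {
    Z <- H[[t]]
    Z[mask[, t] == 0, ] <- -Inf
    upd <- Z > pooled
    pooled[upd] <- Z[upd]
    arg[upd] <- t
  }
  list(pooled = pooled, arg = arg)
}

masked_max_pool_backward <- function(dpool, arg, T_) {
  lapply(seq_len(T_), function(t) dpool * (arg == t))
}

# "final" pooling: last valid forward state and the full-read backward state
final_pool <- function(H, h) {
  T_ <- length(H)
  cbind(H[[T_]][, seq_len(h), drop = FALSE],
        H[[1L]][, h + seq_len(h), drop = FALSE])
}

final_pool_backward <- function(dpool, T_, h, B) {
  dH <- lapply(seq_len(T_), function(t) matrix(0, B, 2L * h))
  dH[[T_]][, seq_len(h)] <- dpool[, seq_len(h), drop = FALSE]
  dH[[1L]][, h + seq_len(h)] <- dpool[, h + seq_len(h), drop = FALSE]
  dH
}

# scatter-add rows of `part` into `acc` at (possibly duplicated) indices
scatter_add <- function(acc, idx, part) {
  agg <- rowsum(part, group = idx)
  rows <- as.integer(rownames(agg))
  acc[rows, ] <- acc[rows, , drop = FALSE] + agg
  acc
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# flatten/unflatten parameter lists (used by the finite-difference check)
flatten_params <- function(params) {
  unlist(lapply(params, as.numeric), use.names = FALSE)
}

unflatten_params <- function(flat, template) {
  out <- template
  k <- 0L
  for (nm in names(template)) {
    p <- template[[nm]]
    len <- length(p)
    piece <- flat[k + seq_len(len)]
    out[[nm]] <- if (is.matrix(p)) matrix(piece, nrow(p), ncol(p)) else piece
    k <- k + len
  }
  out
}
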