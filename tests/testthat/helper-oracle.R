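# Independent scalar-loop oracles for the sequence model. These deliberately
# avoid every vectorised code path of the package: plain double loops over
# hidden units and input dimensions, per-gate weight matrices, no reuse of
# package internals beyond the weight container layout.

oracle_lstm_step <- function(x, h, c, w) {
  L <- length(w$b_i)
  i <- f <- o <- g <- numeric(L)
  for (l in seq_len(L)) {
    zi <- w$b_i[l]; zf <- w$b_f[l]; zo <- w$b_o[l]; zg <- w$b_g[l]
    for (m in seq_along(h)) {
      zi <- zi + w$W_hi[m, l] * h[m]
      zf <- zf + w$W_hf[m, l] * h[m]
      zo <- zo + w$W_ho[m, l] * h[m]
      zg <- zg + w$W_hg[m, l] * h[m]
    }
    for (m in seq_along(x)) {
      zi <- zi + w$W_xi[m, l] * x[m]
      zf <- zf + w$W_xf[m, l] * x[m]
      zo <- zo + w$W_xo[m, l] * x[m]
      zg <- zg + w$W_xg[m, l] * x[m]
    }
    i[l] <- 1 / (1 + exp(-zi))
    f[l] <- 1 / (1 + exp(-zf))
    o[l] <- 1 / (1 + exp(-zo))
    g[l] <- tanh(zg)
  }
  cn <- f * c + i * g
  list(h = o * tanh(cn), c = cn)
}

oracle_lstm_forward <- function(X, w) {
  L <- length(w$b_i)
  h <- numeric(L); c <- numeric(L)
  out <- matrix(0, nrow(X), L)
  for (t in seq_len(nrow(X))) {
    st <- oracle_lstm_step(X[t, ], h, c, w)
    h <- st$h; c <- st$c
    out[t, ] <- h
  }
  out
}

# Scalar flatten + dense + softmax/sigmoid.
oracle_flatten_dense <- function(H, W, b) {
  x <- numeric(nrow(H) * ncol(H))
  k <- 0
  for (t in seq_len(nrow(H))) for (l in seq_len(ncol(H))) {
    k <- k + 1
    x[k] <- H[t, l]
  }
  P <- length(b)
  z <- numeric(P)
  for (p in seq_len(P)) {
    z[p] <- b[p]
    for (j in seq_along(x)) z[p] <- z[p] + x[j] * W[j, p]
  }
  if (P == 1) return(1 / (1 + exp(-z)))
  e <- exp(z - max(z))
  e / sum(e)
}

random_gate_weights <- function(L, v, scale = 0.8) {
  split_lstm_weights(list(Wx = matrix(rnorm(v * 4 * L, sd = scale), v),
                          Wh = matrix(rnorm(L * 4 * L, sd = scale), L),
                          b = rnorm(4 * L, sd = scale)))
}
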