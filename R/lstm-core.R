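sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# --- weight layout -----------------------------------------------------------
# Internally the four gate weight blocks are stored column-bound as
# Wx (v x 4L), Wh (L x 4L), b (4L) in gate order i, f, o, g; this lets one
# matrix product per timestep compute all gate pre-activations for a whole
# mini-batch. `split_lstm_weights()` exposes the per-gate matrices
# (W_xi, W_hi, b_i, ...) that mirror the model equations.

gate_cols <- function(L) list(i = 1:L, f = L + 1:L, o = 2 * L + 1:L, g = 3 * L + 1:L)

#' Split or combine LSTM gate weights
#'
#' The package stores the input (`i`), forget (`f`), output (`o`) and input
#' modulation (`g`) gate weights column-bound for speed.
#' `split_lstm_weights()` returns the familiar per-gate form: `W_x*`
#' (`v x L`) input matrices, `W_h*` (`L x L`) recurrent matrices and `b_*`
#' biases of the gate equations; `combine_lstm_weights()` is its inverse.
#'
#' @param params a parameter list with elements `Wx`, `Wh`, `b` (combined
#'   form), e.g. `coef(model)$lstm_combined`.
#' @return a list `W_xi, W_xf, W_xo, W_xg, W_hi, W_hf, W_ho, W_hg, b_i, b_f,
#'   b_o, b_g`.
#' @export
split_lstm_weights <- function(params) {
  L <- ncol(params$Wh) / 4
  gc <- gate_cols(L)
  out <- list()
  for (gname in names(gc)) {
    out[[paste0("W_x", gname)]] <- params$Wx[, gc[[gname]], drop = FALSE]
    out[[paste0("W_h", gname)]] <- params$Wh[, gc[[gname]], drop = FALSE]
    out[[paste0("b_", gname)]] <- params$b[gc[[gname]]]
  }
  out
}

#' @rdname split_lstm_weights
#' @param weights a per-gate weight list as returned by
#'   `split_lstm_weights()`.
#' @export
combine_lstm_weights <- function(weights) {
  list(Wx = cbind(weights$W_xi, weights$W_xf, weights$W_xo, weights$W_xg),
       Wh = cbind(weights$W_hi, weights$W_hf, weights$W_ho, weights$W_hg),
       b = c(weights$b_i, weights$b_f, weights$b_o, weights$b_g))
}

# One LSTM timestep for a batch: Xt (n x v), H/C (n x L).
lstm_cell_batch <- function(Xt, H, C, Wx, Wh, b) {
  L <- ncol(Wh) / 4
  Z <- Xt %*% Wx + H %*% Wh
  Z <- sweep(Z, 2, b, "+")
  gc <- gate_cols(L)
  i <- sigmoid(Z[, gc$i, drop = FALSE])
  f <- sigmoid(Z[, gc$f, drop = FALSE])
  o <- sigmoid(Z[, gc$o, drop = FALSE])
  g <- tanh(Z[, gc$g, drop = FALSE])
  Cn <- f * C + i * g
  tanhC <- tanh(Cn)
  list(i = i, f = f, o = o, g = g, C = Cn, tanhC = tanhC, H = o * tanhC)
}

#' One step of the LSTM recurrence
#'
#' Applies the gate equations for a single timestep: the input, forget and
#' output gates are sigmoids of affine maps of the previous hidden state and
#' the current input, the input modulation gate is the tanh counterpart; the
#' memory cell is `c_t = f * c_{t-1} + i * g` and the hidden state
#' `h_t = o * tanh(c_t)`.
#'
#' @param x_t input vector of length `v` (an embedded token).
#' @param state list with `h` and `c`, each length `L`; `NULL` means the
#'   zero initial state.
#' @param weights per-gate weights as returned by [split_lstm_weights()].
#' @return list with the new `h` and `c` vectors.
#' @export
#' @examples
#' w <- split_lstm_weights(list(Wx = matrix(0, 2, 8), Wh = matrix(0, 2, 8),
#'                              b = numeric(8)))
#' lstm_step(c(1, -1), NULL, w)$h   # all zero: tanh(0) gates everything off
lstm_step <- function(x_t, state = NULL, weights) {
  L <- length(weights$b_i)
  if (is.null(state)) state <- list(h = numeric(L), c = numeric(L))
  comb <- combine_lstm_weights(weights)
  cell <- lstm_cell_batch(matrix(x_t, 1), matrix(state$h, 1), matrix(state$c, 1),
                          comb$Wx, comb$Wh, comb$b)
  list(h = drop(cell$H), c = drop(cell$C))
}

#' Run the LSTM over an embedded document
#'
#' Iterates [lstm_step()] over the rows of an embedded document starting
#' from the zero state; row `t` of the result is the hidden state after
#' consuming token `t`.
#'
#' @param X a `T x v` matrix of embedded tokens.
#' @param weights per-gate weights ([split_lstm_weights()]).
#' @return a `T x L` matrix of hidden states.
#' @export
lstm_forward <- function(X, weights) {
  comb <- combine_lstm_weights(weights)
  L <- length(weights$b_i)
  H <- matrix(0, 1, L); C <- H
  out <- matrix(0, nrow(X), L)
  for (t in seq_len(nrow(X))) {
    cell <- lstm_cell_batch(X[t, , drop = FALSE], H, C, comb$Wx, comb$Wh, comb$b)
    H <- cell$H; C <- cell$C
    out[t, ] <- H
  }
  out
}

#' Embed an integer-encoded document
#'
#' Looks up each token id (0-based; 0 is the padding id, which has its own
#' learned row) in the embedding matrix.
#'
#' @param ids integer vector of token ids in `[0, V)`.
#' @param embedding `V x v` embedding matrix; row `k + 1` embeds id `k`.
#' @return a `length(ids) x v` matrix.
#' @export
embed_tokens <- function(ids, embedding) {
  if (any(ids < 0 | ids >= nrow(embedding)))
    stop_cfg("token id out of range [0, %d)", nrow(embedding))
  embedding[ids + 1L, , drop = FALSE]
}

#' Flatten hidden states and apply the dense prediction head
#'
#' Row-major flattens a `T x L` hidden-state matrix to length `T * L`,
#' applies the affine dense map, then SoftMax over `P > 1` death-window
#' classes (or the logistic function when `P = 1`, the mortality-risk
#' head).
#'
#' @param H `T x L` hidden-state matrix.
#' @param W dense weights, `(T*L) x P`.
#' @param b dense bias, length `P`.
#' @return probability vector of length `P` (sums to 1 under SoftMax).
#' @export
flatten_dense <- function(H, W, b) {
  x <- as.vector(t(H))                     # row-major: timestep-major blocks
  if (length(x) != nrow(W)) stop_cfg("dense weight shape mismatch: need %d x P", length(x))
  z <- drop(x %*% W) + b
  if (length(z) > 1) drop(softmax_rows(matrix(z, 1))) else sigmoid(z)
}

# --- parameter initialisation ------------------------------------------------

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

init_model_params <- function(V, v, T, L, P, seed) {
  with_seed(seed, {
    b <- numeric(4 * L)
    b[gate_cols(L)$f] <- 1          # forget-gate bias 1: standard retention init
    list(emb = matrix(runif(V * v, -0.05, 0.05), V, v),
         Wx = glorot(v, 4 * L),
         Wh = glorot(L, 4 * L),
         b = b,
         Wd = glorot(T * L, P),
         bd = numeric(P))
  })
}

# --- batched forward / backward ---------------------------------------------

# Full forward pass for a batch of integer-encoded documents.
# Returns the per-timestep caches needed by the backward pass.
forward_batch <- function(ids, par, keep_cache = TRUE) {
  n <- nrow(ids); T <- ncol(ids)
  L <- ncol(par$Wh) / 4
  H <- matrix(0, n, L); C <- H
  Hs <- vector("list", T)
  cache <- if (keep_cache) vector("list", T) else NULL
  for (t in seq_len(T)) {
    Xt <- par$emb[ids[, t] + 1L, , drop = FALSE]
    cell <- lstm_cell_batch(Xt, H, C, par$Wx, par$Wh, par$b)
    if (keep_cache) {
      cell$C_prev <- C
      cell$H_prev <- H
      cache[[t]] <- cell
    }
    H <- cell$H; C <- cell$C
    Hs[[t]] <- H
  }
  Hflat <- do.call(cbind, Hs)              # n x (T*L), timestep-major
  logits <- sweep(Hflat %*% par$Wd, 2, par$bd, "+")
  P <- ncol(logits)
  probs <- if (P > 1) softmax_rows(logits) else sigmoid(logits)
  list(Hflat = Hflat, probs = probs, cache = cache)
}

# Cross-entropy loss and analytic gradients for one mini-batch.
# y: 0-based class labels (P > 1) or 0/1 outcomes (P = 1).
loss_grad_batch <- function(ids, y, par, grad = TRUE) {
  n <- nrow(ids); T <- ncol(ids)
  L <- ncol(par$Wh) / 4
  P <- ncol(par$Wd)
  fw <- forward_batch(ids, par, keep_cache = grad)
  probs <- fw$probs
  eps <- 1e-12
  if (P > 1) {
    py <- probs[cbind(seq_len(n), y + 1L)]
    loss <- -mean(log(pmax(py, eps)))
  } else {
    p <- drop(probs)
    loss <- -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  }
  if (!grad) return(list(loss = loss))

  if (P > 1) {
    Y <- matrix(0, n, P); Y[cbind(seq_len(n), y + 1L)] <- 1
    dlogits <- (probs - Y) / n
  } else {
    dlogits <- matrix((drop(probs) - y) / n, n, 1)
  }
  gWd <- crossprod(fw$Hflat, dlogits)
  gbd <- colSums(dlogits)
  dHflat <- tcrossprod(dlogits, par$Wd)    # n x (T*L)

  gWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  gWh <- matrix(0, L, 4 * L)
  gb <- numeric(4 * L)
  dh <- matrix(0, n, L)
  dc <- matrix(0, n, L)
  emb_idx <- vector("list", T)
  emb_grad <- vector("list", T)
  tWx <- t(par$Wx); tWh <- t(par$Wh)
  for (t in rev(seq_len(T))) {
    cell <- fw$cache[[t]]
    dH <- dHflat[, (t - 1) * L + seq_len(L), drop = FALSE] + dh
    do_ <- dH * cell$tanhC
    dc <- dc + dH * cell$o * (1 - cell$tanhC^2)
    di <- dc * cell$g
    dg <- dc * cell$i
    df <- dc * cell$C_prev
    dc <- dc * cell$f
    dZ <- cbind(di * cell$i * (1 - cell$i),
                df * cell$f * (1 - cell$f),
                do_ * cell$o * (1 - cell$o),
                dg * (1 - cell$g^2))
    Xt <- par$emb[ids[, t] + 1L, , drop = FALSE]
    gWx <- gWx + crossprod(Xt, dZ)
    gWh <- gWh + crossprod(cell$H_prev, dZ)
    gb <- gb + colSums(dZ)
    dh <- dZ %*% tWh
    emb_idx[[t]] <- ids[, t] + 1L
    emb_grad[[t]] <- dZ %*% tWx
  }
  gEmb <- matrix(0, nrow(par$emb), ncol(par$emb))
  all_idx <- unlist(emb_idx)
  all_grad <- do.call(rbind, emb_grad)
  agg <- rowsum(all_grad, group = all_idx)
  gEmb[as.integer(rownames(agg)), ] <- agg
  list(loss = loss,
       grads = list(emb = gEmb, Wx = gWx, Wh = gWh, b = gb, Wd = gWd, bd = gbd))
}

# Clip the global gradient norm; keeps early training stable under the
# plain-SGD optimiser.
clip_grads <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(max_norm) && total > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

sgd_update <- function(par, grads, lr) {
  for (nm in names(grads)) par[[nm]] <- par[[nm]] - lr * grads[[nm]]
  par
}
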