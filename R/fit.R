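#' Fit the four-layer death-window sequence model
#'
#' Trains the embedding -> LSTM -> flatten -> dense stack by mini-batch
#' gradient descent on categorical cross-entropy (binary cross-entropy when
#' `P = 1`, the mortality head). Each daily sample — the integer-encoded
#' merge of one patient's notes on one day — is classified into the `B`-day
#' window before death in which it was written. Dimensions follow the chain
#' `(T) -> (T, v) -> (T, L) -> (T*L) -> (P)` per sample.
#'
#' Mini-batches are drawn by shuffling samples each epoch (`batch = "shuffle"`,
#' the default) or by grouping each initial `B`-day time window into one
#' batch (`batch = "window"`, giving the `N = D / B` batch semantics); class-
#' homogeneous window batches train noticeably worse, which is why shuffling
#' is the default.
#'
#' @param samples a [make_samples()] object.
#' @param L number of LSTM hidden units.
#' @param v embedding dimension (default 64).
#' @param epochs training epochs.
#' @param learning_rate plain SGD learning rate (default 0.01).
#' @param batch `"shuffle"`, `"window"`, or an integer batch size.
#' @param batch_size chunk size used to bound memory (and, under
#'   `"shuffle"`, the mini-batch size).
#' @param clip global gradient-norm clip; `Inf` disables.
#' @param seed integer seed controlling initialisation and batch order.
#' @param verbose print per-epoch loss.
#' @return an object of class `copd_lstm` with components `params` (all
#'   weights), `config` (V, v, T, D, B, N, L, P), `loss` (per-epoch training
#'   log) and the call arguments. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`.
#' @seealso [predict.copd_lstm()], [segment_signal()], [lstm_accuracy()]
#' @export
copd_lstm <- function(samples, L = 16, v = 64, epochs = 10,
                      learning_rate = 0.01, batch = "shuffle",
                      batch_size = 32, clip = 5, seed = 1, verbose = FALSE) {
  stopifnot(inherits(samples, "daily_samples"))
  n <- length(samples$label)
  if (n == 0) stop_cfg("no samples to train on")
  P <- samples$P
  if (P > 1 && length(unique(samples$label)) < 2)
    stop_cfg("need at least 2 classes present to train a %d-class head", P)
  par <- init_model_params(samples$V, v, samples$T, L, P, seed)
  loss_log <- numeric(epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      batches <- make_batches(samples, batch, batch_size)
      ep_loss <- 0; ep_n <- 0
      for (bi in batches) {
        lg <- loss_grad_batch(samples$ids[bi, , drop = FALSE],
                              samples$label[bi], par)
        par <- sgd_update(par, clip_grads(lg$grads, clip), learning_rate)
        ep_loss <- ep_loss + lg$loss * length(bi)
        ep_n <- ep_n + length(bi)
      }
      loss_log[ep] <- ep_loss / ep_n
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f", ep, loss_log[ep]))
    }
  })
  structure(list(
    params = par,
    config = list(V = samples$V, v = as.integer(v), T = samples$T, D = n,
                  B = samples$B, N = ceiling(max(samples$days_before_death) / samples$B) + 0L,
                  L = as.integer(L), P = P),
    loss = loss_log,
    learning_rate = learning_rate, epochs = as.integer(epochs),
    batch = batch, clip = clip, seed = as.integer(seed)
  ), class = "copd_lstm")
}

make_batches <- function(samples, batch, batch_size) {
  n <- length(samples$label)
  if (identical(batch, "window")) {
    w <- samples$days_before_death %/% samples$B
    groups <- split(seq_len(n), w)
    groups <- groups[sample(length(groups))]
    # bound batch memory: split large windows into chunks
    unlist(lapply(groups, function(g)
      split(g, ceiling(seq_along(g) / batch_size))), recursive = FALSE)
  } else {
    idx <- sample(n)
    split(idx, ceiling(seq_along(idx) / batch_size))
  }
}

#' @export
print.copd_lstm <- function(x, ...) {
  cfg <- x$config
  cat("Four-layer LSTM death-window model\n")
  cat(sprintf("  vocabulary V = %d, embedding v = %d, document length T = %d\n",
              cfg$V, cfg$v, cfg$T))
  cat(sprintf("  hidden units L = %d, classes P = %d, initial window B = %d days\n",
              cfg$L, cfg$P, cfg$B))
  cat(sprintf("  trained on D = %d daily samples, final loss %.4f (%d epochs)\n",
              cfg$D, x$loss[length(x$loss)], x$epochs))
  invisible(x)
}

#' @export
summary.copd_lstm <- function(object, ...) {
  npar <- sum(vapply(object$params, length, numeric(1)))
  out <- list(config = object$config, n_parameters = npar,
              loss = object$loss, learning_rate = object$learning_rate,
              batch = object$batch, seed = object$seed)
  class(out) <- "summary.copd_lstm"
  out
}

#' @export
print.summary.copd_lstm <- function(x, ...) {
  cat("Four-layer LSTM death-window model\n")
  cat(sprintf("  parameters: %d  (V=%d v=%d T=%d L=%d P=%d, B=%d days)\n",
              x$n_parameters, x$config$V, x$config$v, x$config$T,
              x$config$L, x$config$P, x$config$B))
  cat(sprintf("  SGD lr %.3g, %s batches, seed %d\n",
              x$learning_rate, if (identical(x$batch, "window")) "per-window"
              else "shuffled", x$seed))
  cat("  training loss: ", paste(sprintf("%.4f", x$loss), collapse = " "), "\n")
  invisible(x)
}

#' Extract model weights
#'
#' Returns the embedding matrix, the LSTM gate weights (both in the
#' per-gate form of the gate equations and in the combined column-bound
#' form), and the dense head.
#'
#' @param object a `copd_lstm` model.
#' @param ... unused.
#' @return list with `embedding`, `lstm` (per-gate `W_x*`, `W_h*`, `b_*`),
#'   `lstm_combined`, `dense` (`W`, `b`).
#' @export
coef.copd_lstm <- function(object, ...) {
  p <- object$params
  list(embedding = p$emb,
       lstm = split_lstm_weights(p),
       lstm_combined = list(Wx = p$Wx, Wh = p$Wh, b = p$b),
       dense = list(W = p$Wd, b = p$bd))
}

#' Predict death windows for daily samples
#'
#' Runs the forward pass and returns, per sample, the SoftMax probability
#' over the `P` death-window classes and the predicted class (argmax, ties
#' toward the smaller class id, i.e. the window closer to death).
#'
#' @param object a `copd_lstm` model.
#' @param samples a `daily_samples` object or an integer id matrix with `T`
#'   columns.
#' @param type `"class"` for 0-based class ids, `"prob"` for the
#'   probability matrix.
#' @param chunk forward-pass chunk size (memory bound only).
#' @param ... unused.
#' @return integer vector of classes, or an `n x P` probability matrix.
#' @export
predict.copd_lstm <- function(object, samples, type = c("class", "prob"),
                              chunk = 256, ...) {
  type <- match.arg(type)
  ids <- if (inherits(samples, "daily_samples")) samples$ids else samples
  stopifnot(ncol(ids) == object$config$T)
  n <- nrow(ids)
  probs <- matrix(0, n, object$config$P)
  for (s in split(seq_len(n), ceiling(seq_len(n) / chunk)))
    probs[s, ] <- forward_batch(ids[s, , drop = FALSE], object$params,
                                keep_cache = FALSE)$probs
  if (type == "prob") return(probs)
  if (object$config$P == 1) as.integer(probs >= 0.5)
  else max.col(probs, ties.method = "first") - 1L
}

#' @export
plot.copd_lstm <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training cross-entropy",
                 main = "Death-window model training loss", ...)
  invisible(x)
}

# --- checkpointing -----------------------------------------------------------

#' Save or load a model checkpoint
#'
#' A checkpoint is a single JSON file holding the config, the call
#' arguments, and every weight array with its dimensions at full numeric
#' precision; `read_model()` validates all shapes against the config before
#' reconstructing the model. The file is byte-deterministic for a given
#' model.
#'
#' @param model a `copd_lstm` model.
#' @param path file path (conventionally `model.json`).
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "copd_lstm"))
  ser <- list(
    format = "copdatlas-checkpoint-1",
    config = model$config,
    training = list(loss = model$loss, learning_rate = model$learning_rate,
                    epochs = model$epochs, batch = model$batch,
                    clip = model$clip, seed = model$seed),
    # %.17g round-trips IEEE doubles exactly; plain JSON numbers lose the
    # last bit through the writer
    params = lapply(model$params, function(w)
      list(dim = if (is.matrix(w)) dim(w) else length(w),
           data = sprintf("%.17g", as.vector(w))))
  )
  json <- jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  ser <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(ser$format, "copdatlas-checkpoint-1"))
    stop_cfg("not a copdatlas checkpoint: %s", path)
  cfg <- ser$config
  par <- lapply(ser$params, function(w) {
    x <- as.numeric(w$data)
    if (length(w$dim) == 2) matrix(x, w$dim[1], w$dim[2]) else x
  })
  expect <- list(emb = c(cfg$V, cfg$v), Wx = c(cfg$v, 4 * cfg$L),
                 Wh = c(cfg$L, 4 * cfg$L), b = 4 * cfg$L,
                 Wd = c(cfg$T * cfg$L, cfg$P), bd = cfg$P)
  for (nm in names(expect)) {
    got <- if (is.matrix(par[[nm]])) dim(par[[nm]]) else length(par[[nm]])
    if (!identical(as.integer(got), as.integer(expect[[nm]])))
      stop_cfg("checkpoint weight '%s' has shape (%s), expected (%s)",
               nm, paste(got, collapse = ","), paste(expect[[nm]], collapse = ","))
  }
  structure(list(params = par, config = cfg, loss = ser$training$loss,
                 learning_rate = ser$training$learning_rate,
                 epochs = ser$training$epochs, batch = ser$training$batch,
                 clip = ser$training$clip, seed = ser$training$seed),
            class = "copd_lstm")
}
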