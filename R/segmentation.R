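#' Derive the binary segment-boundary signal from a trained model
#'
#' Pools the cohort's daily samples into consecutive initial `B`-day
#' windows on the days-before-death axis (window 0 adjacent to death) and
#' emits, per window, a 0/1 boundary decision: 1 means the window starts a
#' new irregular time-lapse segment.
#'
#' The decision is made by a dedicated sigmoid head on the flattened LSTM
#' output: each window is represented by the mean flattened hidden-state
#' vector (length `T * L`) of its samples, and a logistic head (weights
#' `(T*L) x 1`) is fitted to a self-supervised change signal — windows whose
#' mean representation drifts (cosine distance to the preceding window a
#' robust outlier over the cohort's windows: above the median plus three
#' median absolute deviations) are treated as boundary windows. The head's thresholded output is the signal; window 0 is always
#' 1 so segments partition the timeline, and empty windows emit 0 (no
#' boundary can be opened without evidence).
#'
#' @param model a [copd_lstm()] model.
#' @param samples the cohort's `daily_samples`.
#' @param threshold sigmoid decision threshold (default 0.5).
#' @param head_steps,head_lr gradient-descent schedule for the boundary
#'   head.
#' @return an object of class `copd_signal`: list with `signal` (integer
#'   0/1 vector, window 0 first), `B`, `N`, `change` (the cosine-drift
#'   statistic per window) and `head` (the fitted sigmoid head).
#' @seealso [signal_to_segments()]
#' @export
segment_signal <- function(model, samples, threshold = 0.5,
                           head_steps = 400, head_lr = 0.5) {
  stopifnot(inherits(model, "copd_lstm"), inherits(samples, "daily_samples"))
  B <- samples$B
  w <- samples$days_before_death %/% B
  N <- max(w) + 1L
  TL <- model$config$T * model$config$L
  means <- matrix(NA_real_, N, TL)
  counts <- integer(N)
  for (j in seq_len(N) - 1L) {
    idx <- which(w == j)
    counts[j + 1L] <- length(idx)
    if (length(idx)) {
      Hf <- forward_flat(model, samples$ids[idx, , drop = FALSE])
      means[j + 1L, ] <- colMeans(Hf)
    }
  }
  change <- window_change(means)
  labels <- change_labels(change, counts)
  head <- fit_sigmoid_head(means, labels, head_steps, head_lr)
  signal <- integer(N)
  filled <- which(counts > 0)
  p <- sigmoid(drop(means[filled, , drop = FALSE] %*% head$w) + head$b)
  signal[filled] <- as.integer(p >= threshold)
  signal[1L] <- 1L                      # the window at death always opens a segment
  structure(list(signal = signal, B = B, N = N, change = change,
                 counts = counts, head = head, threshold = threshold),
            class = "copd_signal")
}

# Flattened hidden representation (n x T*L) for a block of samples.
forward_flat <- function(model, ids) {
  forward_batch(ids, model$params, keep_cache = FALSE)$Hflat
}

# Cosine drift between consecutive non-empty window representations.
window_change <- function(means) {
  N <- nrow(means)
  change <- numeric(N)
  prev <- NULL
  for (j in seq_len(N)) {
    cur <- means[j, ]
    if (anyNA(cur)) { change[j] <- 0; next }
    if (!is.null(prev)) {
      denom <- sqrt(sum(cur^2)) * sqrt(sum(prev^2))
      change[j] <- if (denom > 0) 1 - sum(cur * prev) / denom else 0
    }
    prev <- cur
  }
  change
}

# Self-supervised boundary labels: drift flagged as a robust outlier among
# observed windows (median + 3 MAD; a mean/sd cut would be inflated by the
# boundary spikes themselves). Window 0 is always a boundary.
change_labels <- function(change, counts) {
  obs <- which(counts > 0)
  labels <- integer(length(change))
  d <- change[obs[-1]]
  if (length(d) >= 2) {
    cut <- if (stats::mad(d) > 0) stats::median(d) + 3 * stats::mad(d)
           else if (stats::sd(d) > 0) mean(d) + stats::sd(d)
           else Inf
    labels[obs[-1]] <- as.integer(change[obs[-1]] > cut)
  }
  labels[obs[1]] <- 1L
  labels
}

fit_sigmoid_head <- function(means, labels, steps, lr) {
  obs <- which(!apply(means, 1, anyNA))
  X <- means[obs, , drop = FALSE]
  y <- labels[obs]
  w <- numeric(ncol(X)); b <- 0
  n <- length(y)
  for (s in seq_len(steps)) {
    p <- sigmoid(drop(X %*% w) + b)
    g <- (p - y) / n
    w <- w - lr * drop(crossprod(X, g))
    b <- b - lr * sum(g)
  }
  list(w = w, b = b)
}

#' @export
print.copd_signal <- function(x, ...) {
  cat(sprintf("Boundary signal over %d initial %d-day windows (death-first):\n  %s\n",
              x$N, x$B, paste(x$signal, collapse = " ")))
  invisible(x)
}

#' Convert a boundary signal into irregular time-lapse segments
#'
#' Windows are indexed from death backward (window 0 covers days
#' `[0, B)` before death). Each maximal run of windows beginning at a 1 in
#' the signal is merged into one segment: a run over windows `j, ..., j'-1`
#' covers days `[j' * B, j * B)` before death. The signal must open with a
#' 1 so that the segments partition the covered timeline.
#'
#' @param signal integer 0/1 vector (or a `copd_signal`).
#' @param B initial window length in days (taken from the `copd_signal` if
#'   one is given).
#' @return an object of class `copd_segments`: list with `segments` (data
#'   frame `start_days`, `end_days`, death-first) , `windows` (list of
#'   member window indices per segment), `signal` and `B`.
#' @export
#' @examples
#' signal_to_segments(c(1, 0, 0, 1), B = 90)$segments  # [270,0) and [360,270)
signal_to_segments <- function(signal, B) {
  if (inherits(signal, "copd_signal")) {
    B <- signal$B
    signal <- signal$signal
  }
  signal <- as.integer(signal)
  B <- as.integer(B)
  if (!length(signal)) stop_cfg("empty signal")
  if (!all(signal %in% 0:1)) stop_cfg("signal must be binary")
  if (signal[1] != 1)
    stop_cfg("signal[1] must be 1: the window adjacent to death opens a segment")
  starts <- which(signal == 1)
  ends <- c(starts[-1] - 1L, length(signal))
  windows <- Map(function(s, e) (s:e) - 1L, starts, ends)
  seg <- data.frame(
    start_days = vapply(windows, function(w) (max(w) + 1L) * B, integer(1)),
    end_days = vapply(windows, function(w) min(w) * B, integer(1))
  )
  structure(list(segments = seg, windows = windows,
                 signal = signal, B = as.integer(B)),
            class = "copd_segments")
}

#' @export
print.copd_segments <- function(x, ...) {
  cat(sprintf("%d irregular time-lapse segments (B = %d days), death-first:\n",
              nrow(x$segments), x$B))
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  [%d, %d) days before death  (windows %s)\n",
                x$segments$start_days[i], x$segments$end_days[i],
                paste(x$windows[[i]], collapse = ",")))
  invisible(x)
}

#' Select the n segments closest to death
#'
#' @param segments a `copd_segments` object or a segment data frame with
#'   `start_days`/`end_days`.
#' @param n number of segments to keep (all if fewer are available).
#' @return segment data frame, death-first.
#' @export
most_recent_segments <- function(segments, n) {
  stopifnot(n >= 1)
  seg <- if (inherits(segments, "copd_segments")) segments$segments else segments
  seg <- seg[order(seg$end_days), , drop = FALSE]
  out <- head(seg, n)
  rownames(out) <- NULL
  out
}

#' Equal-window baseline segmentation
#'
#' The regional-classifier baseline: consecutive fixed `B`-day windows from
#' death backward over the whole horizon (the oldest window may be shorter
#' when the horizon is not a multiple of `B`).
#'
#' @param horizon_days days of history before death to cover.
#' @param B window length in days.
#' @return segment data frame (`start_days`, `end_days`), death-first.
#' @export
#' @examples
#' equal_window_baseline(100, 30)  # 4 windows, the oldest spanning 10 days
equal_window_baseline <- function(horizon_days, B) {
  stopifnot(horizon_days >= 1, B >= 1)
  ends <- seq(0L, horizon_days - 1L, by = B)
  data.frame(start_days = as.integer(pmin(ends + B, horizon_days)),
             end_days = as.integer(ends))
}
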