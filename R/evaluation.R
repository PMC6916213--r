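#' Patient-level train/test split
#'
#' Splits samples 70:30 (by default) at the PATIENT level — every sample of
#' a patient lands on one side — so no patient's notes leak across the
#' split. The number of training patients is `round(ratio * n_patients)`.
#'
#' @param samples a `daily_samples` object.
#' @param ratio training fraction, in (0, 1).
#' @param seed integer seed for the patient shuffle.
#' @return list with `train` and `test` `daily_samples`.
#' @export
split_samples <- function(samples, ratio = 0.7, seed = 1) {
  stopifnot(inherits(samples, "daily_samples"), ratio > 0, ratio < 1)
  patients <- unique(samples$patient_id)
  if (length(patients) < 2)
    stop_cfg("need at least 2 patients to split; got %d", length(patients))
  with_seed(seed, {
    shuffled <- sample(patients)
    n_train <- max(1L, min(length(patients) - 1L,
                           round(ratio * length(patients))))
    train_pat <- shuffled[seq_len(n_train)]
    list(train = subset_samples(samples, samples$patient_id %in% train_pat),
         test = subset_samples(samples, !samples$patient_id %in% train_pat))
  })
}

#' Positive predictive value of a death-date prediction
#'
#' 1 if the absolute difference between predicted and actual death offsets
#' is within the given time window (boundary inclusive), else 0.
#'
#' @param predicted_death_day,actual_death_day day offsets (any common
#'   origin; only the difference matters).
#' @param window_days the tolerance window in days.
#' @return integer 0/1 vector.
#' @export
#' @examples
#' accuracy_within_window(30, 0, 30)  # boundary counts as correct
accuracy_within_window <- function(predicted_death_day, actual_death_day,
                                   window_days) {
  as.integer(abs(predicted_death_day - actual_death_day) <= window_days)
}

new_eval_result <- function(correct, tag) {
  structure(list(accuracy = mean(correct), correct = as.integer(correct),
                 model = tag, n = length(correct)),
            class = "copd_eval")
}

#' @export
print.copd_eval <- function(x, ...) {
  cat(sprintf("%s: prediction accuracy %.2f%% on %d held-out samples\n",
              toupper(x$model), 100 * x$accuracy, x$n))
  invisible(x)
}

#' Held-out prediction accuracy of the sequence model
#'
#' A sample counts as correct when the SoftMax argmax equals its true
#' death-window class, i.e. the predicted `B`-day date range contains the
#' actual death offset. Undefined for the `P = 1` mortality head.
#'
#' @param model a `copd_lstm` model.
#' @param samples held-out `daily_samples`.
#' @return a `copd_eval` result: `accuracy` (fraction), per-sample
#'   `correct` indicators, and the model tag.
#' @export
lstm_accuracy <- function(model, samples) {
  stopifnot(inherits(model, "copd_lstm"))
  if (model$config$P == 1)
    stop_cfg("window accuracy is undefined for the P = 1 mortality head")
  pred <- predict(model, samples, type = "class")
  new_eval_result(pred == samples$label, "lstm")
}

# Bag-of-words count features over the vocabulary ids (pad excluded, OOV
# kept as its own column).
bow_features <- function(samples) {
  n <- nrow(samples$ids)
  V <- samples$V
  X <- matrix(0, n, V - 1L)
  for (i in seq_len(n)) {
    ids <- samples$ids[i, ]
    X[i, ] <- tabulate(ids[ids > 0L], nbins = V - 1L)
  }
  colnames(X) <- paste0("w", seq_len(V - 1L))
  X
}

#' Fit a baseline death-date regressor
#'
#' The two reference models: ordinary linear regression (`"lr"`) and
#' support-vector regression (`"svm"`, radial kernel via \pkg{e1071}). Both
#' predict a continuous days-before-death target from bag-of-words counts
#' over the model vocabulary.
#'
#' @param kind `"lr"` or `"svm"`.
#' @param samples training `daily_samples`.
#' @param seed integer seed (SVM internals).
#' @return an object of class `copd_baseline` with a `predict` method
#'   returning predicted days before death.
#' @export
fit_baseline <- function(kind = c("lr", "svm"), samples, seed = 1) {
  kind <- match.arg(kind)
  X <- bow_features(samples)
  y <- samples$days_before_death
  fit <- if (kind == "lr") {
    f <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    cf <- f$coefficients
    cf[is.na(cf)] <- 0                 # rank deficiency: drop aliased columns
    list(coef = cf)
  } else {
    with_seed(seed, e1071::svm(x = X, y = y, type = "eps-regression",
                               scale = FALSE))
  }
  structure(list(kind = kind, fit = fit), class = "copd_baseline")
}

#' @export
predict.copd_baseline <- function(object, samples, ...) {
  X <- bow_features(samples)
  if (object$kind == "lr") drop(cbind(1, X) %*% object$fit$coef)
  else unname(stats::predict(object$fit, X))
}

#' @export
print.copd_baseline <- function(x, ...) {
  cat(sprintf("%s death-date baseline (bag-of-words features)\n",
              toupper(x$kind)))
  invisible(x)
}

#' Held-out accuracy of a baseline regressor
#'
#' Accuracy is the mean positive predictive value: the fraction of held-out
#' samples whose predicted death offset falls within `window_days` of the
#' true offset ([accuracy_within_window()]).
#'
#' @param baseline a [fit_baseline()] model.
#' @param samples held-out `daily_samples`.
#' @param window_days tolerance window in days (typically the initial
#'   window size `B`).
#' @return a `copd_eval` result.
#' @export
baseline_accuracy <- function(baseline, samples, window_days) {
  stopifnot(inherits(baseline, "copd_baseline"))
  pred <- predict(baseline, samples)
  new_eval_result(
    accuracy_within_window(pred, samples$days_before_death, window_days),
    baseline$kind)
}

#' Accuracy table across models and initial window sizes
#'
#' Convenience wrapper reproducing the layout of the headline comparison:
#' one row per (model, initial window size) with prediction accuracy in
#' percent. The LSTM is retrained per window size (its class structure
#' depends on `B`); the baselines are refitted on the same training split
#' and scored with the matching window tolerance.
#'
#' @param samples full-cohort `daily_samples` (labelled at the finest `B`).
#' @param windows data frame with columns `B` and `P`, one row per setting.
#' @param ratio train fraction.
#' @param seed split and training seed.
#' @param ... passed to [copd_lstm()].
#' @return data frame: `model`, `window_days`, `accuracy_pct`.
#' @export
evaluation_table <- function(samples, windows = data.frame(B = c(30, 90),
                                                           P = c(6, 2)),
                             ratio = 0.7, seed = 1, ...) {
  rows <- list()
  for (i in seq_len(nrow(windows))) {
    B <- windows$B[i]; P <- windows$P[i]
    rel <- coarsen_labels(samples, B, P)
    sp <- split_samples(rel, ratio, seed)
    model <- copd_lstm(sp$train, seed = seed, ...)
    acc <- lstm_accuracy(model, sp$test)$accuracy
    lr <- baseline_accuracy(fit_baseline("lr", sp$train, seed), sp$test, B)$accuracy
    sv <- baseline_accuracy(fit_baseline("svm", sp$train, seed), sp$test, B)$accuracy
    rows[[i]] <- data.frame(
      model = c("lstm", "svm", "lr"), window_days = B,
      accuracy_pct = 100 * c(acc, sv, lr))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
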