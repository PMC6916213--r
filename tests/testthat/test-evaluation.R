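test_that("the 70:30 split is by patient, seeded, and leak-free", {
  s <- separable_samples(n_per_class = 10, P = 3)   # 30 distinct patients
  s$patient_id <- rep(sprintf("P%02d", 1:10), 3)
  sp <- split_samples(s, 0.7, seed = 4)
  expect_length(unique(sp$train$patient_id), 7)
  expect_length(unique(sp$test$patient_id), 3)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  sp2 <- split_samples(s, 0.7, seed = 4)
  expect_identical(sp$train$patient_id, sp2$train$patient_id)
  one <- s; one$patient_id <- rep("P01", length(one$label))
  expect_error(split_samples(one, 0.7, 1), "at least 2 patients")
})

test_that("window accuracy is inclusive at the boundary", {
  expect_equal(accuracy_within_window(100, 100, 30), 1L)
  expect_equal(accuracy_within_window(131, 100, 30), 0L)
  expect_equal(accuracy_within_window(130, 100, 30), 1L)
  expect_equal(accuracy_within_window(c(0, 50, 29), c(10, 100, 0), 30),
               c(1L, 0L, 1L))
})

test_that("sequence-model accuracy equals the class-match rate", {
  s <- separable_samples(n_per_class = 4, P = 3)
  m <- copd_lstm(s, L = 2, v = 3, epochs = 1, learning_rate = 0, seed = 1)
  m0 <- constant_class_model(m, 0)
  res <- lstm_accuracy(m0, s)
  expect_equal(res$accuracy, mean(s$label == 0))
  expect_equal(res$accuracy, mean(res$correct))
  # all-class-0 samples with the constant-0 predictor: perfect accuracy
  s0 <- copdatlas:::subset_samples(s, which(s$label == 0))
  expect_equal(lstm_accuracy(m0, s0)$accuracy, 1)
  # permutation invariance
  perm <- copdatlas:::subset_samples(s, rev(seq_along(s$label)))
  expect_equal(lstm_accuracy(m0, perm)$accuracy, res$accuracy)
  # P = 1 head has no window-class accuracy
  s1 <- s; s1$P <- 1L
  m1 <- copd_lstm(s1, L = 2, v = 3, epochs = 1, learning_rate = 0, seed = 1)
  expect_error(lstm_accuracy(m1, s1), "undefined")
})

test_that("linear regression interpolates when samples <= features", {
  s <- separable_samples(n_per_class = 1, P = 2, T = 6, V = 10)
  s$days_before_death <- c(12L, 77L)
  lr <- fit_baseline("lr", s)
  expect_equal(predict(lr, s), s$days_before_death, tolerance = 1e-8)
  expect_equal(baseline_accuracy(lr, s, 30)$accuracy, 1)
})

test_that("LR coefficients match the normal-equations oracle", {
  set.seed(6)
  n <- 12
  ids <- matrix(0L, n, 5)   # varying document lengths keep the design full rank
  for (i in seq_len(n)) {
    len <- sample(2:5, 1)
    ids[i, seq_len(len)] <- sample(2:4, len, replace = TRUE)
  }
  s <- structure(list(ids = ids, label = integer(n),
                      days_before_death = sample(0:180, n),
                      patient_id = sprintf("P%02d", seq_len(n)),
                      date = as.Date("2017-01-01") + seq_len(n),
                      text = rep("x", n), B = 30L, P = 6L, T = 5L, V = 5L),
                 class = "daily_samples")
  lr <- fit_baseline("lr", s)
  X <- copdatlas:::bow_features(s)
  live <- which(colSums(X) > 0)
  Xd <- cbind(1, X[, live])
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% s$days_before_death)
  expect_equal(unname(lr$fit$coef[c(1L, live + 1L)]), unname(drop(beta)),
               tolerance = 1e-6)
})

test_that("SVM baseline fits and predicts finite day offsets", {
  s <- separable_samples(n_per_class = 8, P = 3)
  sv <- fit_baseline("svm", s, seed = 2)
  p <- predict(sv, s)
  expect_length(p, length(s$label))
  expect_true(all(is.finite(p)))
  expect_true(baseline_accuracy(sv, s, 30)$accuracy >= 0)
})

test_that("baseline accuracy averages the window indicator", {
  s <- separable_samples(n_per_class = 2, P = 2)
  s$days_before_death <- c(0L, 10L, 100L, 200L)
  fake <- structure(list(kind = "lr",
                         fit = list(coef = c(40, numeric(s$V - 1)))),
                    class = "copd_baseline")    # constant prediction 40
  res <- baseline_accuracy(fake, s, 30)
  # |40 - days| = 40, 30, 60, 160 -> only the day-10 sample is within 30
  expect_equal(res$correct, c(0L, 1L, 0L, 0L))
  expect_equal(res$accuracy, 0.25)
  far <- structure(list(kind = "lr",
                        fit = list(coef = c(1e6, numeric(s$V - 1)))),
                   class = "copd_baseline")
  expect_equal(baseline_accuracy(far, s, 30)$accuracy, 0)
})

test_that("the accuracy table covers every model at every window setting", {
  corp <- generate_corpus(tiny_synthetic_config(seed = 15, n_patients = 12))
  vocab <- build_vocab(corp$notes, V = 300)
  samples <- make_samples(corp$notes, corp$deaths, vocab, B = 30, P = 6, T = 40)
  tab <- evaluation_table(samples, windows = data.frame(B = c(30, 90), P = c(6, 2)),
                          seed = 2, L = 4, v = 8, epochs = 2,
                          learning_rate = 0.2)
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$model), c("lstm", "svm", "lr"))
  expect_setequal(unique(tab$window_days), c(30, 90))
  expect_true(all(tab$accuracy_pct >= 0 & tab$accuracy_pct <= 100))
})
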