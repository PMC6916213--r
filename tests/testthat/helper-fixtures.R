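# Small corpora and sample sets built in code, shared across test files.

tiny_synthetic_config <- function(seed = 1, n_patients = 20,
                                  boundaries = c(120, 60, 0),
                                  horizon = 180, fraction = 0.4) {
  synthetic_config(
    n_patients = n_patients,
    stage_boundaries_days = boundaries,
    horizon_days = horizon,
    vocab_background = word_list("bg", 120),
    vocab_stage = lapply(seq_along(boundaries),
                         function(k) word_list(paste0("s", letters[k]), 30)),
    theme_word_fraction = fraction,
    seed = seed)
}

# A small fully separable sample set: P classes, each with its own token.
separable_samples <- function(n_per_class = 10, P = 3, T = 12, V = 20,
                              B = 30, seed = 1) {
  set.seed(seed)
  n <- n_per_class * P
  lab <- rep(0:(P - 1), each = n_per_class)
  ids <- matrix(0L, n, T)
  for (i in seq_len(n)) {
    len <- sample(6:T, 1)
    ids[i, seq_len(len)] <- as.integer(lab[i] + 2L)  # class token
  }
  structure(list(ids = ids, label = lab,
                 days_before_death = lab * B + B %/% 2L,
                 patient_id = sprintf("P%03d", seq_len(n)),
                 date = as.Date("2017-01-01") + seq_len(n),
                 text = rep("x", n),
                 B = as.integer(B), P = as.integer(P), T = as.integer(T),
                 V = as.integer(V)),
            class = "daily_samples")
}

planted_sentences <- function(vocab, n, len = 11, seed = 1) {
  set.seed(seed)
  replicate(n, paste(sample(vocab, len, replace = TRUE), collapse = " "))
}

# Force a trained model into a constant predictor for a given class.
constant_class_model <- function(model, class) {
  model$params$Wd[] <- 0
  model$params$bd[] <- 0
  model$params$bd[class + 1L] <- 10
  model
}
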