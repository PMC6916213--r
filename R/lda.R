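#' Fit a latent Dirichlet allocation theme model on segment sentences
#'
#' Sentences are the documents: each is tokenized, mapped onto the
#' segment-local vocabulary, and a collapsed Gibbs sampler (implemented in
#' C++, symmetric Dirichlet priors) assigns every token to one of
#' `n_topics` latent themes. The per-topic theme words are the `m` highest-
#' probability words of the smoothed topic-word distribution. With
#' `n_topics = 1` this reduces to frequency ranking of the segment's
#' tokens.
#'
#' @param sentences character vector of sentences (>= `n_topics` distinct
#'   non-empty sentences required; segments too small to theme should be
#'   merged with a neighbour).
#' @param n_topics number of latent themes.
#' @param m_theme_words theme words kept per topic.
#' @param alpha,beta symmetric Dirichlet priors on document-topic and
#'   topic-word distributions.
#' @param iters Gibbs sweeps.
#' @param seed integer seed; fits are deterministic given the seed.
#' @return an object of class `copd_lda`: list with `theme_words` (list of
#'   `m` words per topic), `phi` (topic-word probabilities, rows sum to 1),
#'   `theta` (per-sentence topic mixture), `vocab`, and the kept sentence
#'   index.
#' @export
fit_lda <- function(sentences, n_topics = 5, m_theme_words = 10,
                    alpha = 0.1, beta = 0.1, iters = 200, seed = 1) {
  stopifnot(n_topics >= 1, m_theme_words >= 1)
  toks <- lapply(sentences, tokenize)
  keep <- which(lengths(toks) > 0)
  if (length(unique(sentences[keep])) < n_topics)
    stop_cfg(paste("segment has %d distinct non-empty sentences but %d topics",
                   "were requested; merge this segment with a neighbour"),
             length(unique(sentences[keep])), n_topics)
  toks <- toks[keep]
  vocab <- sort(unique(unlist(toks)))
  docs <- lapply(toks, function(tk) match(tk, vocab) - 1L)
  res <- with_seed(seed,
    lda_gibbs_cpp(docs, length(vocab), as.integer(n_topics),
                  alpha, beta, as.integer(iters)))
  phi <- (res$nkw + beta) / (rowSums(res$nkw) + length(vocab) * beta)
  colnames(phi) <- vocab
  theta <- (res$ndk + alpha) / (rowSums(res$ndk) + n_topics * alpha)
  m <- min(m_theme_words, length(vocab))
  theme_words <- lapply(seq_len(n_topics), function(k) {
    ord <- order(-phi[k, ], vocab)       # probability desc, ties lexicographic
    vocab[ord][seq_len(m)]
  })
  structure(list(theme_words = theme_words, phi = phi, theta = theta,
                 vocab = vocab, n_topics = as.integer(n_topics),
                 m = m, kept = keep, seed = as.integer(seed)),
            class = "copd_lda")
}

#' @export
print.copd_lda <- function(x, ...) {
  cat(sprintf("LDA theme model: %d topics over %d words (%d sentences)\n",
              x$n_topics, length(x$vocab), nrow(x$theta)))
  for (k in seq_len(x$n_topics))
    cat(sprintf("  theme %d: %s\n", k, paste(x$theme_words[[k]], collapse = " ")))
  invisible(x)
}

#' Theme words of a fitted LDA model
#'
#' @param model a `copd_lda` model.
#' @param topic topic index (all topics if omitted).
#' @return character vector, or list of vectors.
#' @export
theme_words <- function(model, topic = NULL) {
  stopifnot(inherits(model, "copd_lda"))
  if (is.null(topic)) model$theme_words else model$theme_words[[topic]]
}
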