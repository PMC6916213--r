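#' Tokenize clinical text
#'
#' Lowercases and splits on runs of non-alphanumeric characters; empty
#' tokens are dropped. Numbers are kept as tokens (heart rates, volumes and
#' day counts carry signal in clinical notes).
#'
#' @param text a character string.
#' @return character vector of tokens (empty for empty input).
#' @export
#' @examples
#' tokenize("Sinus tachycardia 127 bpm")
tokenize <- function(text) {
  if (!length(text) || !nzchar(text)) return(character())
  toks <- strsplit(tolower(text), "[^[:alnum:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Build a frequency-ranked vocabulary
#'
#' The `V - 2` most frequent tokens of the corpus receive the integer ids
#' `2 .. V-1`; id 0 is reserved for padding and id 1 for out-of-vocabulary
#' tokens. Frequency ties are broken lexicographically so the mapping is
#' deterministic.
#'
#' @param texts character vector of documents (or a notes data frame, whose
#'   `text` column is used).
#' @param V maximum vocabulary size including the two reserved ids
#'   (default 10000).
#' @return an object of class `copd_vocab`: list with `ids` (named integer
#'   vector, token to id), `V`, and `size` (2 + number of mapped tokens).
#' @export
#' @examples
#' v <- build_vocab(c("severe dyspnea", "dyspnea at rest"), V = 10)
#' v$ids[["dyspnea"]]
build_vocab <- function(texts, V = 10000) {
  if (V < 3) stop_cfg("V must be at least 3 (pad + oov + one token)")
  if (is.data.frame(texts)) texts <- texts$text
  toks <- unlist(lapply(texts, tokenize))
  freq <- table(toks)
  ord <- order(-as.integer(freq), names(freq))  # frequency desc, then lexicographic
  keep <- names(freq)[ord][seq_len(min(length(freq), V - 2))]
  ids <- setNames(seq_along(keep) + 1L, keep)
  structure(list(ids = ids, V = as.integer(V), size = length(ids) + 2L),
            class = "copd_vocab")
}

#' @export
print.copd_vocab <- function(x, ...) {
  cat(sprintf("Vocabulary: %d tokens mapped (capacity V = %d; 0 = pad, 1 = oov)\n",
              x$size - 2L, x$V))
  invisible(x)
}

#' Merge one patient-day's notes into a single document
#'
#' Note texts are concatenated with single spaces, pulmonary notes first,
#' then radiology, then cardiology, preserving the incoming order within
#' each type. One patient-day yields one sample downstream.
#'
#' @param notes data frame of notes, all for one patient and calendar day.
#' @return a single character string.
#' @export
merge_day_notes <- function(notes) {
  if (!nrow(notes)) stop_cfg("merge_day_notes: no notes for this patient-day")
  ord <- order(match(notes$note_type, NOTE_TYPES))
  paste(notes$text[ord], collapse = " ")
}

#' Integer-encode a token sequence to fixed length
#'
#' Tokens are mapped through the vocabulary (unknown tokens to the
#' out-of-vocabulary id 1); sequences longer than `T` keep their first `T`
#' ids, shorter ones are post-padded with the padding id 0.
#'
#' @param tokens character vector of tokens.
#' @param vocab a [build_vocab()] vocabulary.
#' @param T target sequence length.
#' @return integer vector of exactly length `T`, values in `[0, V)`.
#' @export
encode_pad <- function(tokens, vocab, T) {
  stopifnot(inherits(vocab, "copd_vocab"), T >= 1)
  ids <- unname(vocab$ids[tokens])
  ids[is.na(ids)] <- 1L
  if (length(ids) >= T) ids[seq_len(T)] else c(ids, integer(T - length(ids)))
}

#' Build per-patient-day training samples
#'
#' One sample per patient-day with at least one note: the day's notes are
#' merged ([merge_day_notes()]), tokenized, integer-encoded to length `T`,
#' and labelled with the death-window class
#' `min(floor(days_before_death / B), P - 1)` — the index of the `B`-day
#' window before death into which the day falls, with all days beyond
#' `(P-1) * B` collapsed into the last class.
#'
#' @param notes notes data frame (see [read_notes()]).
#' @param deaths death-record data frame (see [read_deaths()]); every
#'   patient in `notes` must appear.
#' @param vocab a [build_vocab()] vocabulary.
#' @param B initial time-window length in days.
#' @param P number of death-window classes.
#' @param T tokens per sample (truncation/padding length).
#' @return an object of class `daily_samples`: list with `ids` (n x T
#'   integer matrix), `label` (death-window class, 0-based), `days_before_death`,
#'   `patient_id`, `date`, `text` (the merged document) and the `B`, `P`,
#'   `T`, `V` used. Rows are sorted by patient, then day.
#' @export
make_samples <- function(notes, deaths, vocab, B, P, T) {
  stopifnot(inherits(vocab, "copd_vocab"), B >= 1, P >= 1, T >= 1)
  B <- as.integer(B); P <- as.integer(P); T <- as.integer(T)
  dd <- days_before_death(notes, deaths)
  key <- paste(notes$patient_id, format(notes$date, "%Y-%m-%d"))
  ord <- order(notes$patient_id, notes$date)
  groups <- split(ord, key[ord])
  groups <- groups[order(names(groups))]
  n <- length(groups)
  ids <- matrix(0L, n, T)
  text <- character(n)
  lab <- integer(n)
  day_bd <- integer(n)
  pid <- character(n)
  date <- rep(notes$date[1], n)
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    text[g] <- merge_day_notes(notes[rows, , drop = FALSE])
    ids[g, ] <- encode_pad(tokenize(text[g]), vocab, T)
    day_bd[g] <- dd[rows[1]]
    pid[g] <- notes$patient_id[rows[1]]
    date[g] <- notes$date[rows[1]]
    lab[g] <- min(day_bd[g] %/% B, P - 1L)
  }
  structure(list(ids = ids, label = lab, days_before_death = day_bd,
                 patient_id = pid, date = date, text = text,
                 B = B, P = P, T = T, V = vocab$V),
            class = "daily_samples")
}

#' @export
print.daily_samples <- function(x, ...) {
  cat(sprintf("%d daily samples (%d patients), T = %d, B = %d days, P = %d classes\n",
              length(x$label), length(unique(x$patient_id)), x$T, x$B, x$P))
  invisible(x)
}

#' @export
length.daily_samples <- function(x) length(x$label)

# Subset samples by row index, keeping metadata.
subset_samples <- function(samples, idx) {
  out <- samples
  out$ids <- samples$ids[idx, , drop = FALSE]
  for (f in c("label", "days_before_death", "patient_id", "date", "text"))
    out[[f]] <- samples[[f]][idx]
  out
}

#' One-hot label matrix for a set of samples
#'
#' Expands the death-window class of each sample into a one-hot row over
#' the `P` classes (each row sums to 1; the argmax recovers the label).
#'
#' @param samples a `daily_samples` object.
#' @return n x P indicator matrix.
#' @export
one_hot_labels <- function(samples) {
  n <- length(samples$label)
  m <- matrix(0L, n, samples$P)
  m[cbind(seq_len(n), samples$label + 1L)] <- 1L
  m
}

#' Relabel samples at a coarser initial window
#'
#' Maps each sample's days-before-death onto classes of a coarser window
#' `B2 >= B` with `P2` classes — used to compare prediction accuracy across
#' initial window sizes (30, 90, 360 days) on one corpus.
#'
#' @param samples a `daily_samples` object.
#' @param B2 coarser window length in days.
#' @param P2 number of classes at the coarser window.
#' @return a `daily_samples` object relabelled at (`B2`, `P2`).
#' @export
coarsen_labels <- function(samples, B2, P2) {
  stopifnot(B2 >= 1, P2 >= 1)
  out <- samples
  out$B <- as.integer(B2)
  out$P <- as.integer(P2)
  out$label <- pmin(samples$days_before_death %/% as.integer(B2), P2 - 1L)
  out
}
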