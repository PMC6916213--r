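#' Split free text into sentences
#'
#' Sentence boundaries are `.`, `!` or `?` followed by whitespace (clinical
#' notes carry no richer punctuation structure); trailing terminators are
#' stripped and empty pieces dropped. Text without terminators is one
#' sentence.
#'
#' @param text character string.
#' @return character vector of sentences.
#' @export
split_sentences <- function(text) {
  if (!length(text) || !nzchar(text)) return(character())
  parts <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- sub("[.!?]+$", "", parts)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Representative-sentence decision
#'
#' A sentence represents a theme when the fraction of its tokens that are
#' theme words reaches the threshold — by default 30%, the 3-to-4 theme
#' words expected of a 10-to-14-word clinical sentence. Repeated theme
#' words count once (distinct hits); the boundary is inclusive, so 3 hits
#' in a 10-token sentence qualifies.
#'
#' @param tokens tokenized sentence (non-empty), e.g. from [tokenize()].
#' @param theme_words character vector of one topic's theme words.
#' @param threshold minimum theme-word fraction (default 0.30).
#' @return list with `representative` (logical), `fraction`, `hits` and
#'   `token_count`.
#' @export
#' @examples
#' is_representative(tokenize("sinus tachycardia 127 bpm nonspecific st t wave changes noted today"),
#'                   c("tachycardia", "st", "wave", "nonspecific"))
is_representative <- function(tokens, theme_words, threshold = 0.30) {
  if (!length(tokens)) stop_cfg("cannot score an empty sentence")
  hits <- length(intersect(unique(tokens), theme_words))
  fraction <- hits / length(tokens)
  list(representative = fraction >= threshold, fraction = fraction,
       hits = hits, token_count = length(tokens))
}

#' Rank a segment's representative sentences
#'
#' Every sentence is attributed to its best theme (most distinct theme-word
#' hits; ties to the lower topic index), kept if its theme-word fraction
#' reaches the threshold, deduplicated on exact text, and ranked by
#' fraction (descending), then hits (descending), then first occurrence.
#' The top `k` survive.
#'
#' @param sentences character vector of the segment's sentences.
#' @param model a [fit_lda()] theme model for the segment.
#' @param k maximum sentences returned (default 10).
#' @param threshold representative threshold (default 0.30).
#' @return data frame: `text`, `topic`, `hits`, `token_count`, `fraction`,
#'   at most `k` rows, best first.
#' @export
top_k_sentences <- function(sentences, model, k = 10, threshold = 0.30) {
  stopifnot(inherits(model, "copd_lda"))
  rows <- list()
  seen <- character()
  for (s in seq_along(sentences)) {
    toks <- tokenize(sentences[s])
    if (!length(toks)) next
    if (sentences[s] %in% seen) next
    seen <- c(seen, sentences[s])
    hits <- vapply(model$theme_words,
                   function(tw) length(intersect(unique(toks), tw)), integer(1))
    best <- which.max(hits)              # ties: lower topic index
    fraction <- hits[best] / length(toks)
    if (fraction >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        text = sentences[s], topic = as.integer(best),
        hits = hits[best], token_count = length(toks),
        fraction = fraction, order = s, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(text = character(), topic = integer(), hits = integer(),
                      token_count = integer(), fraction = numeric()))
  df <- do.call(rbind, rows)
  df <- df[order(-df$fraction, -df$hits, df$order), , drop = FALSE]
  df$order <- NULL
  out <- head(df, k)
  rownames(out) <- NULL
  out
}

#' Build the COPD atlas
#'
#' For the `n` irregular time-lapse segments closest to death: collect the
#' sentences of all notes falling in the segment (by days before death),
#' fit a per-segment LDA theme model, and keep the top `k` representative
#' sentences. Segments with no sentences are kept (with a warning) so the
#' timeline stays complete. Optionally restrict to one note type — the
#' published atlas uses pulmonary notes only.
#'
#' @param segments a `copd_segments` object or a segment data frame
#'   (`start_days`, `end_days`).
#' @param notes notes data frame ([read_notes()]).
#' @param deaths death records ([read_deaths()]).
#' @param n segments closest to death to include (default 7).
#' @param k representative sentences per segment (default 10).
#' @param n_topics,m_theme_words,threshold,iters,seed LDA and
#'   representative-rule settings (see [fit_lda()], [top_k_sentences()]).
#' @param note_type optional note-type filter (e.g. `"pulmonary"`).
#' @return an object of class `copd_atlas`: list of per-segment entries
#'   (`start_days`, `end_days`, `theme_words`, `sentences`) ordered
#'   death-first, plus the settings used.
#' @export
build_atlas <- function(segments, notes, deaths, n = 7, k = 10,
                        n_topics = 5, m_theme_words = 10, threshold = 0.30,
                        iters = 200, seed = 1, note_type = NULL) {
  seg <- most_recent_segments(segments, n)
  if (!is.null(note_type)) {
    stopifnot(note_type %in% NOTE_TYPES)
    notes <- notes[notes$note_type == note_type, , drop = FALSE]
  }
  dd <- days_before_death(notes, deaths)
  entries <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    in_seg <- dd >= seg$end_days[i] & dd < seg$start_days[i]
    sentences <- unlist(lapply(notes$text[in_seg], split_sentences))
    entry <- list(start_days = seg$start_days[i], end_days = seg$end_days[i],
                  n_sentences = length(sentences))
    if (!length(sentences)) {
      warning(sprintf("segment [%d, %d) has no sentences; kept empty",
                      seg$start_days[i], seg$end_days[i]), call. = FALSE)
      entry$theme_words <- list()
      entry$sentences <- top_k_sentences(character(), empty_lda(), k, threshold)
    } else {
      lda <- fit_lda(sentences, n_topics = min(n_topics, length(unique(sentences))),
                     m_theme_words = m_theme_words, iters = iters,
                     seed = seed + i)
      entry$theme_words <- lda$theme_words
      entry$sentences <- top_k_sentences(sentences, lda, k, threshold)
    }
    entries[[i]] <- entry
  }
  structure(list(segments = entries, k = k, n_topics = n_topics,
                 threshold = threshold, seed = seed,
                 note_type = note_type %||% "all"),
            class = "copd_atlas")
}

empty_lda <- function() {
  structure(list(theme_words = list(), phi = NULL, theta = NULL,
                 vocab = character(), n_topics = 0L, m = 0L),
            class = "copd_lda")
}

#' @export
print.copd_atlas <- function(x, ...) {
  cat(sprintf("COPD atlas: %d time segments (death-first), top %d sentences each\n",
              length(x$segments), x$k))
  for (e in x$segments)
    cat(sprintf("  [%d, %d) days before death: %d sentence(s) kept of %d\n",
                e$start_days, e$end_days, nrow(e$sentences), e$n_sentences))
  invisible(x)
}

#' Serialize an atlas
#'
#' `write_atlas_json()` writes the full atlas (segments, theme words,
#' ranked sentences, settings) to JSON; `atlas_markdown()` renders the
#' textual atlas — one section per segment with its day range, themes and
#' numbered representative sentences.
#'
#' @param atlas a `copd_atlas`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_atlas_json <- function(atlas, path) {
  stopifnot(inherits(atlas, "copd_atlas"))
  json <- jsonlite::toJSON(unclass(atlas), auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_atlas_json
#' @export
atlas_markdown <- function(atlas, path = NULL) {
  stopifnot(inherits(atlas, "copd_atlas"))
  lines <- c("# COPD atlas", "",
             sprintf("Most recent %d irregular time-lapse segments before death (%s notes).",
                     length(atlas$segments), atlas$note_type), "")
  for (e in atlas$segments) {
    lines <- c(lines,
               sprintf("## Days [%d, %d) before death", e$start_days, e$end_days),
               "")
    if (length(e$theme_words)) {
      lines <- c(lines, "Theme words:", "")
      for (k in seq_along(e$theme_words))
        lines <- c(lines, sprintf("- theme %d: %s", k,
                                  paste(e$theme_words[[k]], collapse = ", ")))
      lines <- c(lines, "")
    }
    if (nrow(e$sentences)) {
      lines <- c(lines, "Representative sentences:", "")
      for (i in seq_len(nrow(e$sentences)))
        lines <- c(lines, sprintf("%d. %s (theme %d, %d/%d theme words)",
                                  i, e$sentences$text[i], e$sentences$topic[i],
                                  e$sentences$hits[i], e$sentences$token_count[i]))
      lines <- c(lines, "")
    } else {
      lines <- c(lines, "(no representative sentences)", "")
    }
  }
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
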