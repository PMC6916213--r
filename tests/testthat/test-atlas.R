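stub_theme_model <- function(theme_words) {
  structure(list(theme_words = theme_words, phi = NULL, theta = NULL,
                 vocab = sort(unique(unlist(theme_words))),
                 n_topics = length(theme_words),
                 m = max(lengths(theme_words))),
            class = "copd_lda")
}

test_that("sentence splitting handles clinical punctuation", {
  expect_equal(split_sentences("Sinus tachycardia. Nonspecific ST/T- wave changes."),
               c("Sinus tachycardia", "Nonspecific ST/T- wave changes"))
  expect_equal(split_sentences("no terminator here"), "no terminator here")
  expect_equal(split_sentences("Worse? Yes! Stop."), c("Worse", "Yes", "Stop"))
  expect_equal(split_sentences(""), character())
})

test_that("the 30% theme-word rule is boundary-inclusive with distinct hits", {
  tw <- c("dyspnea", "oxygen", "hypoxemia", "edema")
  s12 <- c("dyspnea", "oxygen", "hypoxemia", "edema", paste0("w", 1:8))
  r <- is_representative(s12, tw)
  expect_true(r$representative)
  expect_equal(r$fraction, 4 / 12)
  expect_equal(r$hits, 4)

  none <- is_representative(paste0("w", 1:10), tw)
  expect_false(none$representative)
  expect_equal(none$hits, 0)

  s10 <- c("dyspnea", "oxygen", "hypoxemia", paste0("w", 1:7))
  expect_true(is_representative(s10, tw)$representative)   # 3/10 = 0.30 exactly

  # repeated theme words count once
  rep3 <- is_representative(c(rep("dyspnea", 3), paste0("w", 1:7)), tw)
  expect_equal(rep3$hits, 1)
  expect_false(rep3$representative)

  expect_error(is_representative(character(), tw), "empty sentence")
})

test_that("every 3-4-hit sentence of 10-14 words passes at the default threshold", {
  tw <- paste0("t", 1:4)
  for (len in 10:14) for (hits in 3:4) {
    toks <- c(tw[seq_len(hits)], paste0("w", seq_len(len - hits)))
    r <- is_representative(toks, tw)
    expect_equal(r$representative, hits / len >= 0.30,
                 label = sprintf("len %d hits %d", len, hits))
  }
  # enumerating the grid: 3 hits pass only in a 10-word sentence (0.30
  # exactly); 4 hits pass up to 13 words (4/13 = 0.308) but not 14 (0.286)
  expect_true(is_representative(c(tw[1:3], paste0("w", 1:7)), tw)$representative)
  expect_false(is_representative(c(tw[1:3], paste0("w", 1:11)), tw)$representative)
})

test_that("threshold monotonicity: 0 keeps every sentence, >1 keeps none", {
  sentences <- planted_sentences(c(word_list("t", 5), word_list("w", 10)),
                                 15, seed = 2)
  model <- stub_theme_model(list(word_list("t", 5)))
  all_kept <- top_k_sentences(sentences, model, k = 100, threshold = 0)
  expect_equal(nrow(all_kept), length(unique(sentences)))
  expect_equal(nrow(top_k_sentences(sentences, model, k = 100, threshold = 1.01)), 0)
})

test_that("a 20-sentence fixture ranks exactly as the enumeration oracle", {
  tw <- list(paste0("a", 1:5), paste0("b", 1:5))
  set.seed(17)
  sentences <- vapply(1:20, function(i) {
    len <- sample(10:14, 1)
    hits <- sample(0:5, 1)
    topic <- sample(1:2, 1)
    toks <- c(sample(tw[[topic]], hits),
              sample(word_list("filler", 40), len - hits))
    paste(sample(toks), collapse = " ")
  }, character(1))
  model <- stub_theme_model(tw)

  # independent oracle: hand enumeration with explicit loops
  oracle <- do.call(rbind, lapply(seq_along(sentences), function(i) {
    toks <- tokenize(sentences[i])
    h1 <- length(intersect(unique(toks), tw[[1]]))
    h2 <- length(intersect(unique(toks), tw[[2]]))
    topic <- if (h2 > h1) 2L else 1L
    hits <- max(h1, h2)
    data.frame(text = sentences[i], topic = topic, hits = hits,
               token_count = length(toks), fraction = hits / length(toks),
               order = i, stringsAsFactors = FALSE)
  }))
  oracle <- oracle[oracle$fraction >= 0.30, ]
  oracle <- oracle[order(-oracle$fraction, -oracle$hits, oracle$order), ]
  oracle$order <- NULL
  rownames(oracle) <- NULL

  got <- top_k_sentences(sentences, model, k = 10, threshold = 0.30)
  expect_equal(got, utils::head(oracle, 10))
  expect_lte(nrow(got), 10)
  # per-sentence fractions recomputed by brute force equal the stored ones
  for (i in seq_len(nrow(got))) {
    toks <- tokenize(got$text[i])
    expect_equal(got$fraction[i],
                 length(intersect(unique(toks), tw[[got$topic[i]]])) / length(toks))
  }
})

test_that("ranking clamps at k and breaks fraction ties by hit count", {
  model <- stub_theme_model(list(c("x1", "x2", "x3", "x4")))
  sentences <- c("x1 w1 w2",                       # 1/3
                 "x1 x2 x3 x4 w1 w2 w3 w4",        # 4/8 = 0.5
                 "x1 x2 w1 w2",                    # 2/4 = 0.5, fewer hits
                 "x1 w1 w2")                       # duplicate, dropped
  got <- top_k_sentences(sentences, model, k = 10, threshold = 0.3)
  expect_equal(got$text, c("x1 x2 x3 x4 w1 w2 w3 w4", "x1 x2 w1 w2", "x1 w1 w2"))
  expect_equal(nrow(top_k_sentences(sentences, model, k = 2, threshold = 0.3)), 2)
  expect_equal(top_k_sentences(sentences, model, k = 1, threshold = 0.3)$text,
               "x1 x2 x3 x4 w1 w2 w3 w4")
})

test_that("the atlas pairs each segment with its planted stage vocabulary", {
  cfg <- tiny_synthetic_config(seed = 21, n_patients = 25)
  corp <- generate_corpus(cfg)
  truth_sig <- c(1, 0, 1, 0, 1, 0)           # stages at 120/60/0, B = 30
  segs <- signal_to_segments(truth_sig, B = 30)
  atlas <- build_atlas(segs, corp$notes, corp$deaths, n = 3, k = 10,
                       n_topics = 2, seed = 7)
  expect_length(atlas$segments, 3)
  # stage vocabularies are ordered earliest first; segment 1 is nearest death
  for (i in 1:3) {
    seg <- atlas$segments[[i]]
    expect_lte(nrow(seg$sentences), 10)
    expect_gt(nrow(seg$sentences), 0)
    stage_v <- cfg$vocab_stage[[cfg$n_stages - i + 1L]]
    toks <- unlist(lapply(seg$sentences$text, tokenize))
    expect_gte(mean(toks %in% c(stage_v, cfg$vocab_background)), 0.999)
    expect_gte(mean(toks %in% stage_v), 0.3)
  }
  one <- build_atlas(segs, corp$notes, corp$deaths, n = 1, k = 1,
                     n_topics = 2, seed = 7)
  expect_length(one$segments, 1)
  expect_equal(nrow(one$segments[[1]]$sentences), 1)
})

test_that("empty segments are kept with a warning", {
  corp <- generate_corpus(tiny_synthetic_config(seed = 22, n_patients = 4))
  far <- data.frame(start_days = 4000L, end_days = 3000L)
  expect_warning(atlas <- build_atlas(far, corp$notes, corp$deaths, n = 1,
                                      k = 5, n_topics = 2, seed = 1),
                 "no sentences")
  expect_equal(atlas$segments[[1]]$n_sentences, 0)
  expect_equal(nrow(atlas$segments[[1]]$sentences), 0)
})

test_that("atlas serialization and the markdown report are faithful", {
  corp <- generate_corpus(tiny_synthetic_config(seed = 23, n_patients = 12))
  segs <- signal_to_segments(c(1, 0, 1, 0, 1, 0), B = 30)
  atlas <- build_atlas(segs, corp$notes, corp$deaths, n = 3, k = 4,
                       n_topics = 2, seed = 3)
  fjson <- withr::local_tempfile(fileext = ".json")
  write_atlas_json(atlas, fjson)
  back <- jsonlite::fromJSON(fjson, simplifyVector = FALSE)
  expect_length(back$segments, 3)
  expect_equal(back$k, 4)
  md <- atlas_markdown(atlas)
  expect_match(md, "## Days \\[60, 0\\) before death")
  expect_match(md, "Theme words:")
  expect_match(md, atlas$segments[[1]]$sentences$text[1], fixed = TRUE)
})

test_that("the spiral rendering is deterministic and draws both timelines", {
  corp <- generate_corpus(tiny_synthetic_config(seed = 24, n_patients = 12))
  segs <- signal_to_segments(c(1, 0, 1, 0, 1, 0), B = 30)
  atlas <- build_atlas(segs, corp$notes, corp$deaths, n = 3, k = 3,
                       n_topics = 2, seed = 3)
  base <- equal_window_baseline(360, 30)
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_spiral(atlas, base, f1)
  render_spiral(atlas, base, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 1),
                   readBin(f2, "raw", file.size(f2) + 1))
  svg <- readLines(f1)
  expect_equal(sum(grepl("^<text.*\\[\\d+-\\d+\\]</text>$", svg)), 3)
  expect_equal(sum(grepl('fill="#2e8b57"/>$', svg) & grepl("circle", svg)), 12)
  expect_true(any(grepl("polyline.*#c0392b", svg)))

  # seven irregular segments draw seven labelled arcs
  seven <- signal_to_segments(rep(1, 7), B = 90)
  f3 <- withr::local_tempfile(fileext = ".svg")
  render_spiral(seven$segments, equal_window_baseline(630, 30), f3)
  expect_equal(sum(grepl("^<text.*\\[\\d+-\\d+\\]</text>$", readLines(f3))), 7)
})
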