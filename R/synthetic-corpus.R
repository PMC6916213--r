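#' Default vocabularies for the synthetic note generator
#'
#' `background_vocab()` returns a list of generic clinical tokens that occur
#' in every disease stage; `stage_vocab()` returns per-stage theme
#' vocabularies (chest-symptom, exacerbation and end-of-life terminology for
#' up to six stages, synthetic tokens beyond that). Stage vocabularies are
#' pairwise disjoint and disjoint from the background list, which is what
#' lets topic recovery and segmentation be verified against planted truth.
#'
#' @param n_stages number of stage vocabularies to return.
#' @return a character vector (`background_vocab`) or a list of character
#'   vectors, one per stage, earliest stage first (`stage_vocab`).
#' @export
#' @examples
#' length(background_vocab())
#' stage_vocab(3)[[3]][1:5]
background_vocab <- function() {
  c("patient", "history", "exam", "noted", "stable", "chronic", "daily",
    "left", "right", "mild", "moderate", "severe", "chest", "lung", "lungs",
    "airway", "breath", "sounds", "clear", "report", "impression", "findings",
    "compared", "prior", "study", "unchanged", "increased", "decreased",
    "normal", "abnormal", "follow", "clinic", "visit", "medication", "dose",
    "therapy", "treatment", "plan", "review", "status", "year", "old",
    "smoker", "former", "pack", "rate", "pressure", "blood", "heart", "test",
    "results", "with", "without", "shows", "seen", "present", "absent",
    "bilateral", "upper", "lower", "lobe", "field", "silhouette", "contour",
    "recommend", "continue", "assess", "monitor", "baseline", "interval",
    "overall", "evidence", "consistent", "suggest", "likely", "possible")
}

#' @rdname background_vocab
#' @export
stage_vocab <- function(n_stages) {
  pool <- list(
    c("spirometry", "fev1", "fvc", "ratio", "obstruction", "bronchodilator",
      "albuterol", "inhaler", "intermittent", "cough", "sputum", "wheeze",
      "exertion", "walking", "stairs", "tobacco", "cessation", "counseling",
      "vaccination", "maintenance"),
    c("exacerbation", "prednisone", "steroid", "taper", "antibiotics",
      "azithromycin", "hyperinflation", "emphysema", "bullae", "dyspnea",
      "tiotropium", "salmeterol", "nebulizer", "admission", "flare",
      "bronchitis", "purulent", "fatigue", "limitation", "rehab"),
    c("hypoxemia", "oxygen", "liters", "cannula", "saturation", "desaturation",
      "retention", "hypercapnia", "bipap", "cor", "pulmonale", "edema",
      "diuretics", "tachycardia", "arrhythmia", "infiltrate", "pneumonia",
      "intubation", "ventilator", "icu"),
    c("hospice", "palliative", "comfort", "morphine", "opioid", "anxiolytic",
      "bedbound", "cachexia", "anorexia", "confusion", "somnolence",
      "respiratory", "failure", "terminal", "goals", "care", "dnr",
      "family", "meeting", "prognosis"),
    c("cyanosis", "accessory", "muscles", "tripod", "pursed", "gasping",
      "agonal", "unresponsive", "mottling", "apnea", "bradycardia",
      "hypotension", "anuria", "obtunded", "secretions", "rales",
      "gurgling", "moribund", "vigil", "imminent"),
    c("asymptomatic", "screening", "incidental", "nodule", "surveillance",
      "wellness", "annual", "physical", "routine", "immunization",
      "osteopenia", "vitamin", "exercise", "diet", "weight", "referral",
      "education", "pamphlet", "questionnaire", "baseline2")
  )
  stopifnot(n_stages >= 1)
  out <- vector("list", n_stages)
  for (k in seq_len(n_stages)) {
    out[[k]] <- if (k <= length(pool)) pool[[k]]
    else sprintf("stage%dword%02d", k, 1:20)
  }
  out
}

#' Generate an arbitrary disjoint synthetic word list
#'
#' Convenience for building large vocabularies (e.g. to reach a target
#' vocabulary size V in experiments): tokens are `<prefix>0001`, ... and are
#' disjoint across distinct prefixes.
#'
#' @param prefix token prefix.
#' @param n number of tokens.
#' @return character vector of length `n`.
#' @export
word_list <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

#' Configuration for the synthetic clinical-note corpus
#'
#' Describes a cohort of deceased COPD patients whose free-text notes are
#' generated backward from death. Each patient's history spans
#' `horizon_days` days before death, partitioned into latent disease stages
#' by `stage_boundaries_days` (strictly decreasing day offsets before death,
#' ending at 0). Sentences mix stage-specific theme words (a fraction
#' `theme_word_fraction` of each sentence) with background vocabulary, and
#' note density increases by `density_boost_near_death` inside the final
#' stage, emulating the clinical reality that encounters become more
#' frequent as patients deteriorate.
#'
#' @param n_patients number of patients in the cohort.
#' @param stage_boundaries_days strictly decreasing day offsets before death
#'   ending at 0; one latent stage per entry (the earliest stage also covers
#'   the remainder up to `horizon_days`).
#' @param horizon_days length of each patient's generated history, in days
#'   before death.
#' @param vocab_background character vector of stage-independent tokens.
#' @param vocab_stage list of per-stage token vectors, earliest stage first;
#'   must be pairwise disjoint and disjoint from `vocab_background`.
#' @param sentence_len_range integer min/max words per sentence.
#' @param notes_per_day_rate expected notes per patient-day (Poisson
#'   intensity) outside the final stage.
#' @param density_boost_near_death multiplier applied to the note intensity
#'   inside the final (closest-to-death) stage.
#' @param theme_word_fraction fraction of each sentence's words drawn from
#'   the stage vocabulary (the rest are background words).
#' @param sentences_per_note integer min/max sentences per note.
#' @param seed integer seed; the corpus is a pure function of the config.
#' @return an object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_patients = 5, seed = 1)
#' corp <- generate_corpus(cfg)
#' nrow(corp$notes)
synthetic_config <- function(n_patients = 100,
                             stage_boundaries_days = c(120, 60, 0),
                             horizon_days = 180,
                             vocab_background = background_vocab(),
                             vocab_stage = stage_vocab(length(stage_boundaries_days)),
                             sentence_len_range = c(10, 14),
                             notes_per_day_rate = 0.05,
                             density_boost_near_death = 3,
                             theme_word_fraction = 0.4,
                             sentences_per_note = c(3, 6),
                             seed = 1) {
  n_stages <- length(stage_boundaries_days)
  if (n_stages < 2)
    stop_cfg("need at least 2 stages; got %d boundary value(s)", n_stages)
  if (any(diff(stage_boundaries_days) >= 0))
    stop_cfg("stage_boundaries_days must be strictly decreasing")
  if (stage_boundaries_days[n_stages] != 0)
    stop_cfg("stage_boundaries_days must end at 0 (death)")
  if (stage_boundaries_days[1] >= horizon_days)
    stop_cfg("earliest stage boundary (%d) must lie inside the horizon (%d)",
             stage_boundaries_days[1], horizon_days)
  if (length(vocab_stage) != n_stages)
    stop_cfg("vocab_stage must supply one word list per stage (%d)", n_stages)
  all_stage <- unlist(vocab_stage)
  if (anyDuplicated(all_stage))
    stop_cfg("stage vocabularies must be pairwise disjoint")
  if (length(intersect(all_stage, vocab_background)))
    stop_cfg("stage vocabularies must be disjoint from the background vocabulary")
  if (sentence_len_range[1] < 1 || sentence_len_range[2] < sentence_len_range[1])
    stop_cfg("invalid sentence_len_range")
  if (theme_word_fraction < 0 || theme_word_fraction > 1)
    stop_cfg("theme_word_fraction must be in [0, 1]")
  structure(list(
    n_patients = as.integer(n_patients),
    n_stages = n_stages,
    stage_boundaries_days = as.integer(stage_boundaries_days),
    horizon_days = as.integer(horizon_days),
    vocab_background = vocab_background,
    vocab_stage = vocab_stage,
    sentence_len_range = as.integer(sentence_len_range),
    notes_per_day_rate = notes_per_day_rate,
    density_boost_near_death = density_boost_near_death,
    theme_word_fraction = theme_word_fraction,
    sentences_per_note = as.integer(sentences_per_note),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Latent stage of a day offset before death: stage k is the first whose
# boundary is <= the offset (boundaries are decreasing and end at 0).
stage_of_day <- function(days_before_death, boundaries) {
  idx <- outer(days_before_death, boundaries, ">=")
  max.col(idx, ties.method = "first")
}

one_sentence <- function(stage_words, bg_words, len_range, fraction) {
  len <- if (len_range[1] == len_range[2]) len_range[1]
         else sample(len_range[1]:len_range[2], 1L)
  n_theme <- round(fraction * len)
  words <- c(
    if (n_theme > 0) sample(stage_words, n_theme, replace = TRUE),
    if (len - n_theme > 0) sample(bg_words, len - n_theme, replace = TRUE)
  )
  paste0(paste(sample(words), collapse = " "), ".")
}

#' Generate a synthetic clinical-note corpus with planted stage structure
#'
#' Draws, for every patient and every day before death, a Poisson number of
#' notes (intensity `notes_per_day_rate`, multiplied by
#' `density_boost_near_death` inside the final stage). Each note is assigned
#' a type (pulmonary, radiology or cardiology) and composed of sentences
#' whose words mix the day's stage vocabulary with background vocabulary in
#' the configured proportion. All death dates sit at a common simulation
#' origin and calendar note dates are derived backward from it, mirroring
#' the death-anchored design of the downstream analyses. Patients that draw
#' no notes receive one note on a random day so every patient is observable.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_corpus`: a list with `notes` (data
#'   frame: patient_id, date, note_type, text), `deaths` (patient_id,
#'   death_date), `truth` (per-note planted stage, stage boundaries,
#'   horizon) and the generating `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    origin <- as.Date("2017-06-30")  # common death date (day 0)
    final_stage <- config$n_stages
    pid <- sprintf("P%04d", seq_len(config$n_patients))
    rows <- vector("list", config$n_patients)
    stages_all <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      days <- seq_len(config$horizon_days)  # 1 .. horizon days before death
      stg <- stage_of_day(days, config$stage_boundaries_days)
      lam <- config$notes_per_day_rate *
        ifelse(stg == final_stage, config$density_boost_near_death, 1)
      n_notes <- rpois(length(days), lam)
      if (sum(n_notes) == 0L) n_notes[sample(length(days), 1L)] <- 1L
      day_rep <- rep(days, n_notes)
      stg_rep <- rep(stg, n_notes)
      txt <- character(length(day_rep))
      typ <- sample(NOTE_TYPES, length(day_rep), replace = TRUE)
      for (j in seq_along(day_rep)) {
        ns <- sample(config$sentences_per_note[1]:config$sentences_per_note[2], 1L)
        txt[j] <- paste(vapply(seq_len(ns), function(s) one_sentence(
          config$vocab_stage[[stg_rep[j]]], config$vocab_background,
          config$sentence_len_range, config$theme_word_fraction
        ), character(1)), collapse = " ")
      }
      rows[[i]] <- data.frame(
        patient_id = pid[i],
        date = origin - day_rep,
        note_type = typ,
        text = txt,
        stringsAsFactors = FALSE
      )
      stages_all[[i]] <- stg_rep
    }
    notes <- do.call(rbind, rows)
    rownames(notes) <- NULL
    structure(list(
      notes = notes,
      deaths = data.frame(patient_id = pid, death_date = rep(origin, length(pid)),
                          stringsAsFactors = FALSE),
      truth = list(
        note_stage = unlist(stages_all),
        stage_boundaries_days = config$stage_boundaries_days,
        horizon_days = config$horizon_days
      ),
      config = config
    ), class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("Synthetic COPD note corpus: %d notes, %d patients, %d stages over %d days\n",
              nrow(x$notes), nrow(x$deaths), x$config$n_stages,
              x$truth$horizon_days))
  invisible(x)
}

#' Planted stage windows as day-before-death segments
#'
#' `stage_segments()` converts stage boundaries into the segments they
#' induce on the days-before-death axis: boundaries `c(270, 90, 0)` over a
#' 360-day horizon give `[90,0)`, `[270,90)` and the remainder `[360,270)`,
#' ordered from death backward. `corpus_truth_segments()` looks the planted
#' truth up for one patient of a synthetic corpus (all patients share the
#' cohort-level boundaries by construction).
#'
#' @param boundaries strictly decreasing day offsets ending at 0.
#' @param horizon_days history length in days before death.
#' @return a data frame with `start_days` (inclusive, farther from death)
#'   and `end_days` (exclusive, closer to death), ordered death-first.
#' @export
#' @examples
#' stage_segments(c(270, 90, 0), 360)
stage_segments <- function(boundaries, horizon_days) {
  b <- rev(as.integer(boundaries))          # ascending: 0, ..., earliest
  data.frame(start_days = c(b[-1], as.integer(horizon_days)),
             end_days = b)
}

#' @rdname stage_segments
#' @param corpus a `synthetic_corpus`.
#' @param patient_id patient identifier present in the corpus.
#' @export
corpus_truth_segments <- function(corpus, patient_id) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (!patient_id %in% corpus$deaths$patient_id)
    stop_cfg("unknown patient '%s'", patient_id)
  stage_segments(corpus$truth$stage_boundaries_days, corpus$truth$horizon_days)
}
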