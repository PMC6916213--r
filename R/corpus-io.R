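#' Read and write clinical-note corpora
#'
#' Notes travel as JSON lines (UTF-8, one object per line with fields
#' `patient_id`, `date`, `note_type`, `text`); death dates as a CSV with
#' header `patient_id,death_date`. Both formats round-trip exactly:
#' `read_notes(write_notes(x))` recovers `x`. Dates are calendar dates (ISO
#' 8601, day resolution) because all downstream analysis works on merged
#' notes within one day.
#'
#' @param path file path.
#' @return `read_notes`: a data frame with columns `patient_id` (character),
#'   `date` (Date), `note_type` (one of pulmonary, radiology, cardiology)
#'   and `text`. `read_deaths`: a data frame with `patient_id` and
#'   `death_date` (Date).
#' @export
#' @examples
#' f <- tempfile(fileext = ".jsonl")
#' notes <- data.frame(patient_id = "P1", date = as.Date("2015-03-02"),
#'                     note_type = "pulmonary", text = "FEV1 reduced.")
#' write_notes(notes, f)
#' identical(read_notes(f), notes)
read_notes <- function(path) {
  if (!file.exists(path)) stop_cfg("no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_notes())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop_cfg(
                      "notes line %d: malformed JSON (%s)", i, conditionMessage(e)))
    for (f in c("patient_id", "date", "note_type", "text"))
      if (is.null(rec[[f]])) stop_cfg("notes line %d: missing field '%s'", i, f)
    if (!rec$note_type %in% NOTE_TYPES)
      stop_cfg("notes line %d: unknown note_type '%s' (expected %s)",
               i, rec$note_type, paste(NOTE_TYPES, collapse = "|"))
    if (!nzchar(rec$text)) stop_cfg("notes line %d: empty text", i)
    d <- as.Date(rec$date, format = "%Y-%m-%d")
    if (is.na(d)) stop_cfg("notes line %d: unparseable date '%s'", i, rec$date)
    recs[[i]] <- data.frame(patient_id = rec$patient_id, date = d,
                            note_type = rec$note_type, text = rec$text,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

empty_notes <- function() {
  data.frame(patient_id = character(), date = as.Date(character()),
             note_type = character(), text = character(),
             stringsAsFactors = FALSE)
}

#' @rdname read_notes
#' @param notes a data frame of notes as returned by `read_notes()` (a
#'   `synthetic_corpus$notes` component qualifies).
#' @export
write_notes <- function(notes, path) {
  stopifnot(is.data.frame(notes))
  lines <- vapply(seq_len(nrow(notes)), function(i) {
    jsonlite::toJSON(list(patient_id = notes$patient_id[i],
                          date = format(notes$date[i], "%Y-%m-%d"),
                          note_type = notes$note_type[i],
                          text = notes$text[i]), auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname read_notes
#' @export
read_deaths <- function(path) {
  if (!file.exists(path)) stop_cfg("no such file: %s", path)
  df <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("patient_id", "death_date") %in% names(df)))
    stop_cfg("deaths file must have header patient_id,death_date")
  if (anyDuplicated(df$patient_id)) {
    dup <- df$patient_id[duplicated(df$patient_id)][1]
    stop_cfg("duplicate patient_id '%s' in deaths file", dup)
  }
  d <- as.Date(df$death_date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))[1]
    stop_cfg("deaths row %d: unparseable date '%s'", bad, df$death_date[bad])
  }
  data.frame(patient_id = df$patient_id, death_date = d,
             stringsAsFactors = FALSE)
}

#' @rdname read_notes
#' @param deaths a data frame with `patient_id` and `death_date` (Date).
#' @export
write_deaths <- function(deaths, path) {
  stopifnot(is.data.frame(deaths))
  out <- data.frame(patient_id = deaths$patient_id,
                    death_date = format(deaths$death_date, "%Y-%m-%d"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("patient_id,death_date",
               if (nrow(out)) paste(out$patient_id, out$death_date, sep = ",")),
             con, useBytes = TRUE)
  invisible(path)
}

# Join-time consistency check: every note's patient must have a death record
# dated on or after the note. Returns days before death per note.
days_before_death <- function(notes, deaths) {
  idx <- match(notes$patient_id, deaths$patient_id)
  if (anyNA(idx)) {
    missing <- unique(notes$patient_id[is.na(idx)])[1]
    stop_cfg("no death record for patient '%s'", missing)
  }
  dd <- as.integer(deaths$death_date[idx] - notes$date)
  if (any(dd < 0)) {
    bad <- which(dd < 0)[1]
    stop_cfg("patient '%s' has a note dated after death (%s > %s)",
             notes$patient_id[bad], format(notes$date[bad]),
             format(deaths$death_date[idx[bad]]))
  }
  dd
}
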