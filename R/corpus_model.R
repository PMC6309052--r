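#' @keywords internal
"_PACKAGE"

## corpus_model: patient records, notes, sentence preprocessing ---------------

#' Normalize clinical text
#'
#' Lowercases, replaces every run of non-alphanumeric characters by a single
#' space, and trims. The output alphabet is `[a-z0-9 ]`; this is the
#' canonical form used by the tagger, the cue filter, and duplicate
#' detection.
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @export
normalize_text <- function(text) {
  out <- tolower(text)
  out <- gsub("[^a-z0-9]+", " ", out)
  trimws(out)
}

#' Default sentence-splitter abbreviation list
#'
#' Tokens (lowercase, trailing period stripped) after which a period is not
#' treated as a sentence boundary.
#'
#' @return character vector.
#' @export
default_abbreviations <- function() {
  c("dr", "mr", "mrs", "ms", "pt", "st", "vs", "no", "e.g", "i.e",
    "approx", "fig")
}

#' Split a note into normalized sentences
#'
#' Boundaries are placed at runs of `.`, `!` or `?` followed by whitespace
#' and an uppercase letter, or at end of text, except when the preceding word
#' is a configured abbreviation. Each sentence is then normalized with
#' [normalize_text()]; empty sentences are dropped.
#'
#' @param text a single string (may be empty).
#' @param abbreviations lowercase words that block a following period from
#'   ending a sentence.
#' @return character vector of normalized sentences (possibly empty).
#' @examples
#' preprocess_note("She denies pain. Recurrence noted.")
#' @export
preprocess_note <- function(text, abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  m <- gregexpr("[.!?]+(?=\\s+[A-Z])|[.!?]+\\s*$", text, perl = TRUE)[[1]]
  pieces <- character()
  if (m[1] == -1L) {
    pieces <- text
  } else {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    cut_at <- integer()
    for (i in seq_along(starts)) {
      before <- substr(text, 1L, starts[i] - 1L)
      prev <- regmatches(before, regexpr("[A-Za-z][A-Za-z./]*$", before))
      prev <- tolower(sub("\\.+$", "", prev))
      if (length(prev) == 1L && prev %in% abbreviations) next
      cut_at <- c(cut_at, starts[i] + lens[i] - 1L)
    }
    from <- c(1L, cut_at + 1L)
    to <- c(cut_at, nchar(text))
    keep <- from <= to
    pieces <- substring(text, from[keep], to[keep])
    if (length(pieces) == 0L) pieces <- text
  }
  out <- normalize_text(pieces)
  out[nzchar(out)]
}

parse_iso_date <- function(x, what, line = NULL) {
  where <- if (is.null(line)) "" else sprintf(" (line %d)", line)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("corpus schema error%s: %s must be an ISO-8601 date string",
                 where, what), call. = FALSE)
  }
  d <- as.Date(x, format = "%Y-%m-%d")
  if (is.na(d) || format(d, "%Y-%m-%d") != x) {
    stop(sprintf("corpus schema error%s: unparseable date '%s' for %s",
                 where, x, what), call. = FALSE)
  }
  d
}

require_field <- function(obj, field, line) {
  if (is.null(obj[[field]])) {
    stop(sprintf("corpus schema error (line %d): missing required field '%s'",
                 line, field), call. = FALSE)
  }
  obj[[field]]
}

#' Construct a patient record
#'
#' @param patient_id opaque identifier, unique within a corpus.
#' @param primary_diagnosis_date `Date` (or ISO-8601 string) of the first
#'   primary diagnosis.
#' @param notes data frame with columns `note_id`, `date` (`Date`), `text`.
#' @param pathology_report_dates `Date` vector (may be empty).
#' @param label optional binary outcome, 1 = local recurrence, `NA` if
#'   unlabeled.
#' @return an object of class `patient_record`.
#' @export
patient_record <- function(patient_id, primary_diagnosis_date,
                           notes = empty_notes(),
                           pathology_report_dates = as.Date(character()),
                           label = NA_integer_) {
  if (is.character(primary_diagnosis_date)) {
    primary_diagnosis_date <- parse_iso_date(primary_diagnosis_date,
                                             "primary_diagnosis_date")
  }
  stopifnot(is.data.frame(notes),
            all(c("note_id", "date", "text") %in% names(notes)))
  if (nrow(notes) > 0L && any(!nzchar(notes$text))) {
    stop("corpus schema error: note text must be non-empty", call. = FALSE)
  }
  structure(list(
    patient_id = as.character(patient_id),
    primary_diagnosis_date = primary_diagnosis_date,
    notes = notes,
    pathology_report_dates = as.Date(pathology_report_dates),
    label = if (is.null(label) || is.na(label)) NA_integer_ else as.integer(label)
  ), class = "patient_record")
}

empty_notes <- function() {
  data.frame(note_id = character(), date = as.Date(character()),
             text = character(), stringsAsFactors = FALSE)
}

#' Read a patient corpus from JSONL
#'
#' One JSON object per line:
#' `{"patient_id", "primary_diagnosis_date", "label", "notes":
#' [{"note_id","date","text"}], "pathology_report_dates": [...]}`.
#' Dates are ISO-8601 at day precision. Schema violations raise an error
#' naming the offending line.
#'
#' @param path path to a JSONL corpus file.
#' @return a named list of [patient_record()] objects, class
#'   `recurrex_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines_keep <- which(nzchar(trimws(lines)))
  records <- vector("list", length(lines_keep))
  ids <- character(length(lines_keep))
  for (k in seq_along(lines_keep)) {
    i <- lines_keep[k]
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) {
                      stop(sprintf("corpus schema error (line %d): invalid JSON: %s",
                                   i, conditionMessage(e)), call. = FALSE)
                    })
    pid <- require_field(obj, "patient_id", i)
    dx <- parse_iso_date(require_field(obj, "primary_diagnosis_date", i),
                         "primary_diagnosis_date", i)
    raw_notes <- if (is.null(obj$notes)) list() else obj$notes
    if (length(raw_notes) > 0L) {
      notes <- data.frame(
        note_id = vapply(raw_notes, function(n)
          as.character(require_field(n, "note_id", i)), character(1)),
        date = as.Date(vapply(raw_notes, function(n)
          format(parse_iso_date(require_field(n, "date", i), "note date", i)),
          character(1))),
        text = vapply(raw_notes, function(n)
          as.character(require_field(n, "text", i)), character(1)),
        stringsAsFactors = FALSE)
      if (any(!nzchar(notes$text))) {
        stop(sprintf("corpus schema error (line %d): empty note text", i),
             call. = FALSE)
      }
    } else notes <- empty_notes()
    pdates <- unlist(obj$pathology_report_dates, use.names = FALSE)
    pdates <- if (length(pdates)) {
      as.Date(vapply(pdates, function(d)
        format(parse_iso_date(d, "pathology_report_date", i)), character(1),
        USE.NAMES = FALSE))
    } else as.Date(character())
    label <- obj$label
    label <- if (is.null(label)) NA_integer_ else as.integer(label)
    if (!is.na(label) && !label %in% c(0L, 1L)) {
      stop(sprintf("corpus schema error (line %d): label must be 0, 1 or null", i),
           call. = FALSE)
    }
    records[[k]] <- patient_record(pid, dx, notes, pdates, label)
    ids[k] <- as.character(pid)
  }
  if (anyDuplicated(ids)) {
    stop("corpus schema error: duplicate patient_id '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  }
  names(records) <- ids
  structure(records, class = "recurrex_corpus")
}

#' Write a patient corpus to canonical JSONL
#'
#' Inverse of [read_corpus()]; reading then writing is byte-stable on a
#' canonicalized file.
#'
#' @param records `recurrex_corpus` or list of `patient_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path) {
  lines <- vapply(records, function(r) {
    notes <- if (nrow(r$notes) == 0L) list() else
      lapply(seq_len(nrow(r$notes)), function(j) list(
        note_id = r$notes$note_id[j],
        date = format(r$notes$date[j], "%Y-%m-%d"),
        text = r$notes$text[j]))
    obj <- list(
      patient_id = r$patient_id,
      primary_diagnosis_date = format(r$primary_diagnosis_date, "%Y-%m-%d"),
      label = if (is.na(r$label)) NULL else r$label,
      notes = notes,
      pathology_report_dates = as.list(format(r$pathology_report_dates,
                                              "%Y-%m-%d")))
    if (is.na(r$label)) obj["label"] <- list(NULL)
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                  digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Remove duplicate note copies within one patient
#'
#' Notes whose normalized full text is byte-identical are duplicates; only
#' the earliest-dated copy is retained (first occurrence on date ties),
#' other note order preserved. Idempotent.
#'
#' @param record a `patient_record`.
#' @return the record with duplicates removed.
#' @export
deduplicate_notes <- function(record) {
  notes <- record$notes
  if (nrow(notes) <= 1L) return(record)
  key <- normalize_text(notes$text)
  keep <- logical(nrow(notes))
  for (k in unique(key)) {
    idx <- which(key == k)
    keep[idx[which.min(notes$date[idx])]] <- TRUE
  }
  record$notes <- notes[keep, , drop = FALSE]
  rownames(record$notes) <- NULL
  record
}

#' Sentence table for a corpus
#'
#' Applies [preprocess_note()] to every note and returns one row per
#' normalized sentence with its 0-based index within the note.
#'
#' @param records `recurrex_corpus` or list of `patient_record`.
#' @param abbreviations passed to [preprocess_note()].
#' @return data frame with columns `patient_id`, `note_id`, `index`, `text`.
#' @export
corpus_sentences <- function(records, abbreviations = default_abbreviations()) {
  out <- list()
  for (r in records) {
    for (j in seq_len(nrow(r$notes))) {
      sents <- preprocess_note(r$notes$text[j], abbreviations)
      if (length(sents) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        patient_id = r$patient_id,
        note_id = r$notes$note_id[j],
        index = seq_along(sents) - 1L,
        text = sents,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(patient_id = character(), note_id = character(),
                      index = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Labels of a corpus
#' @param records `recurrex_corpus`.
#' @return named integer vector of labels (may contain `NA`).
#' @export
corpus_labels <- function(records) {
  vapply(records, function(r) r$label, integer(1))
}
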