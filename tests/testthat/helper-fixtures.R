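# shared builders for tiny in-code fixtures

make_note <- function(note_id, date, text) {
  data.frame(note_id = note_id, date = as.Date(date), text = text,
             stringsAsFactors = FALSE)
}

make_record <- function(patient_id = "p1", dx = "2010-01-01",
                        notes = empty_notes(), pdates = character(),
                        label = NA_integer_) {
  patient_record(patient_id, dx, notes, as.Date(pdates), label)
}

as_corpus <- function(...) {
  records <- list(...)
  names(records) <- vapply(records, function(r) r$patient_id, character(1))
  structure(records, class = "recurrex_corpus")
}

write_lexicon_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_lexicon <- function(rows) {
  # rows: list of c(cui, name, form, score)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(cui = r[1], preferred_name = r[2], surface_form = r[3],
               score = r[4], stringsAsFactors = FALSE)))
  load_lexicon(write_lexicon_tsv(df))
}

example_lexicon <- function() {
  load_lexicon(system.file("extdata", "example_lexicon.tsv",
                           package = "recurrex", mustWork = TRUE))
}

sentence_row <- function(text, patient_id = "p1", note_id = "n1",
                         index = 0L) {
  data.frame(patient_id = patient_id, note_id = note_id, index = index,
             text = text, stringsAsFactors = FALSE)
}

# brute-force enumeration of all non-empty subsets of size <= kmax
brute_subsets <- function(items, kmax = 3L) {
  items <- sort(unique(items))
  n <- length(items)
  out <- character()
  for (mask in seq_len(2^n - 1)) {
    sel <- items[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(sel) <= kmax) out <- c(out, paste(sel, collapse = "+"))
  }
  sort(out)
}

# brute-force AUC: pairwise comparison of every (positive, negative) pair
brute_auc <- function(labels, scores) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
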