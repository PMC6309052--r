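## concept_tagger: dictionary stand-in for a MetaMap-style concept mapper ----

CUI_PATTERN <- "^C[0-9]+$"

#' Load a concept lexicon
#'
#' TSV with header columns `cui`, `preferred_name`, `surface_form`, `score`
#' (one surface form per row). Surface forms are normalized with
#' [normalize_text()] on load; duplicate (cui, surface_form) rows collapse
#' keeping the maximum score.
#'
#' @param path path to the lexicon TSV.
#' @return data frame of class `recurrex_lexicon`.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("cui", "preferred_name", "surface_form", "score")
  if (!all(need %in% names(df))) {
    stop("lexicon schema error: columns must include ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("lexicon is empty", call. = FALSE)
  bad <- !grepl(CUI_PATTERN, df$cui)
  if (any(bad)) {
    stop("lexicon schema error: malformed CUI '", df$cui[bad][1], "'",
         call. = FALSE)
  }
  df$surface_form <- normalize_text(df$surface_form)
  if (any(!nzchar(df$surface_form))) {
    stop("lexicon schema error: empty surface form", call. = FALSE)
  }
  df$score <- as.numeric(df$score)
  if (anyNA(df$score)) stop("lexicon schema error: non-numeric score",
                            call. = FALSE)
  ## collapse duplicate (cui, form) keeping max score
  key <- paste(df$cui, df$surface_form, sep = "\r")
  df <- df[order(key, -df$score), , drop = FALSE]
  df <- df[!duplicated(paste(df$cui, df$surface_form, sep = "\r")), ,
           drop = FALSE]
  df <- df[order(df$cui, df$surface_form), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("recurrex_lexicon", "data.frame")
  df
}

#' The packaged synthetic lexicon
#'
#' A hand-built dictionary covering the vocabulary of the packaged template
#' pools and partial-sentence fixture. It is synthetic: reconstructed from
#' concept identifiers printed in the literature plus curated recurrence
#' vocabulary, not an excerpt of the UMLS Metathesaurus.
#'
#' @return a `recurrex_lexicon`.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "lexicon_synthetic.tsv",
                           package = "recurrex", mustWork = TRUE))
}

empty_mentions <- function() {
  data.frame(cui = character(), patient_id = character(),
             note_id = character(), index = integer(),
             start = integer(), end = integer(),
             matched_text = character(), score = numeric(),
             negated = logical(), stringsAsFactors = FALSE)
}

tokenize <- function(text) {
  if (!nzchar(text)) return(character())
  strsplit(text, " ", fixed = TRUE)[[1]]
}

## 1-based character start offsets of space-separated tokens
token_starts <- function(tokens) {
  if (length(tokens) == 0L) return(integer())
  cumsum(c(1L, utils::head(nchar(tokens), -1L) + 1L))
}

## same-span disambiguation (keep max score, ties -> smallest CUI) followed
## by duplicate-CUI collapse to the first occurrence; canonical ordering.
resolve_mentions <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$start, df$end, -df$score, df$cui), , drop = FALSE]
  span <- paste(df$start, df$end)
  df <- df[!duplicated(span), , drop = FALSE]
  df <- df[!duplicated(df$cui), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Tag one normalized sentence with lexicon concepts
#'
#' Every occurrence of every lexicon surface form present as a whole-word
#' (contiguous-token) phrase yields a mention; overlapping mentions from
#' different entries are all kept. When several CUIs claim the exact same
#' span, the maximum-score CUI wins (ties: lexicographically smallest CUI).
#' Duplicate CUIs within the sentence collapse to the first occurrence.
#' Spans are 0-based, half-open character offsets into the sentence.
#'
#' @param sentence either a normalized sentence string or a one-row sentence
#'   data frame (`patient_id`, `note_id`, `index`, `text`).
#' @param lexicon a `recurrex_lexicon`.
#' @param patient_id,note_id,index sentence identity when `sentence` is a
#'   plain string.
#' @return mention data frame (`cui`, sentence reference, `start`, `end`,
#'   `matched_text`, `score`, `negated` = `FALSE`).
#' @export
tag_sentence <- function(sentence, lexicon, patient_id = NA_character_,
                         note_id = NA_character_, index = NA_integer_) {
  if (is.data.frame(sentence)) {
    stopifnot(nrow(sentence) == 1L)
    patient_id <- sentence$patient_id
    note_id <- sentence$note_id
    index <- sentence$index
    sentence <- sentence$text
  }
  toks <- tokenize(sentence)
  n <- length(toks)
  if (n == 0L) return(empty_mentions())
  starts <- token_starts(toks)
  rows <- list()
  forms <- strsplit(lexicon$surface_form, " ", fixed = TRUE)
  for (r in seq_len(nrow(lexicon))) {
    ft <- forms[[r]]
    k <- length(ft)
    if (k > n) next
    for (i in seq_len(n - k + 1L)) {
      if (all(toks[i:(i + k - 1L)] == ft)) {
        s0 <- starts[i] - 1L
        e0 <- starts[i + k - 1L] - 1L + nchar(toks[i + k - 1L])
        rows[[length(rows) + 1L]] <- data.frame(
          cui = lexicon$cui[r], patient_id = patient_id, note_id = note_id,
          index = index, start = s0, end = e0,
          matched_text = substr(sentence, s0 + 1L, e0),
          score = lexicon$score[r], negated = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty_mentions())
  resolve_mentions(do.call(rbind, rows))
}

#' Tag every sentence of a corpus
#'
#' Vectorized over the whole sentence table; output equals mapping
#' [tag_sentence()] over the rows.
#'
#' @param sentences sentence data frame from [corpus_sentences()].
#' @param lexicon a `recurrex_lexicon`.
#' @return mention data frame over all sentences.
#' @export
tag_corpus <- function(sentences, lexicon) {
  if (nrow(sentences) == 0L) return(empty_mentions())
  tok_list <- strsplit(sentences$text, " ", fixed = TRUE)
  ntok <- lengths(tok_list)
  sid <- rep.int(seq_len(nrow(sentences)), ntok)
  toks <- unlist(tok_list, use.names = FALSE)
  pos <- sequence(ntok)                # token position within its sentence
  tstart <- unlist(lapply(tok_list, token_starts), use.names = FALSE)
  tlen <- nchar(toks)
  forms <- strsplit(lexicon$surface_form, " ", fixed = TRUE)
  N <- length(toks)
  hits <- list()
  for (r in seq_len(nrow(lexicon))) {
    ft <- forms[[r]]
    k <- length(ft)
    idx <- which(toks == ft[1])
    if (k > 1L && length(idx)) {
      for (j in 2L:k) {
        idx <- idx[idx + j - 1L <= N &
                     toks[pmin(idx + j - 1L, N)] == ft[j] &
                     sid[pmin(idx + j - 1L, N)] == sid[idx]]
        if (!length(idx)) break
      }
    }
    if (!length(idx)) next
    last <- idx + k - 1L
    hits[[length(hits) + 1L]] <- data.frame(
      sid = sid[idx],
      cui = lexicon$cui[r],
      start = tstart[idx] - 1L,
      end = tstart[last] - 1L + tlen[last],
      score = lexicon$score[r],
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty_mentions())
  h <- do.call(rbind, hits)
  ## per-sentence resolution, vectorized: order, drop same-span losers,
  ## collapse duplicate CUIs to first occurrence
  h <- h[order(h$sid, h$start, h$end, -h$score, h$cui), , drop = FALSE]
  h <- h[!duplicated(paste(h$sid, h$start, h$end)), , drop = FALSE]
  h <- h[!duplicated(paste(h$sid, h$cui, sep = "\r")), , drop = FALSE]
  out <- data.frame(
    cui = h$cui,
    patient_id = sentences$patient_id[h$sid],
    note_id = sentences$note_id[h$sid],
    index = sentences$index[h$sid],
    start = h$start, end = h$end,
    matched_text = substr(sentences$text[h$sid], h$start + 1L, h$end),
    score = h$score,
    negated = FALSE,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
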