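## feature_builder: power-set concept features + pathology-count feature -----

PATHOLOGY_KEY <- ".pathology_count"

feature_kind <- function(keys) {
  ifelse(keys == PATHOLOGY_KEY, "pathology_count",
         ifelse(startsWith(keys, "tok:"), "token", "cui_set"))
}

#' Power set of co-occurring sentence CUIs (sizes 1-3)
#'
#' All non-empty subsets of size at most three of the CUIs tagged in one
#' sentence, each encoded as a sorted `+`-joined key. The output size is
#' `C(n,1) + C(n,2) + C(n,3)`. Sentences with more than `cap` distinct CUIs
#' are truncated (with a warning) to the `cap` lexicographically smallest
#' before expansion, guarding against combinatorial blow-up on pathological
#' sentences.
#'
#' @param cuis character vector of CUIs (deduplicated internally).
#' @param cap maximum number of distinct CUIs expanded per sentence.
#' @return character vector of feature keys.
#' @examples
#' sentence_powerset(c("C1997028", "C1387407", "C2945760"))
#' @export
sentence_powerset <- function(cuis, cap = 10L) {
  cuis <- sort(unique(as.character(cuis)))
  n <- length(cuis)
  if (n == 0L) return(character())
  if (n > cap) {
    warning(sprintf("sentence has %d distinct CUIs; capping at %d", n, cap))
    cuis <- cuis[seq_len(cap)]
    n <- cap
  }
  out <- cuis
  for (m in 2:3) {
    if (n >= m) {
      cmb <- utils::combn(cuis, m)
      out <- c(out, apply(cmb, 2L, paste, collapse = "+"))
    }
  }
  out
}

#' Count pathology reports at least `min_days` after diagnosis
#'
#' Reports dated exactly `min_days` after the primary diagnosis qualify
#' (inclusive boundary); earlier or pre-diagnosis reports do not.
#'
#' @param record a `patient_record`.
#' @param min_days minimum offset in days (default 120).
#' @return non-negative integer.
#' @export
count_pathology_reports <- function(record, min_days = 120L) {
  if (length(record$pathology_report_dates) == 0L) return(0L)
  as.integer(sum(as.numeric(record$pathology_report_dates -
                              record$primary_diagnosis_date) >= min_days))
}

#' Build one patient's sparse feature vector
#'
#' Union over the patient's sentences of the power sets of CUIs retained in
#' that sentence, each key valued 1 (binary presence), plus the pathology
#' count feature when requested. Invariant to sentence and note order.
#'
#' @param record a `patient_record`.
#' @param mentions retained (context- and positive-filtered) mentions for
#'   this patient.
#' @param include_pathology include the pathology-count feature?
#' @param min_days,cap passed to [count_pathology_reports()] and
#'   [sentence_powerset()].
#' @return named numeric vector (feature key -> value).
#' @export
build_patient_vector <- function(record, mentions, include_pathology = TRUE,
                                 min_days = 120L, cap = 10L) {
  keys <- character()
  if (!is.null(mentions) && nrow(mentions) > 0L) {
    grp <- paste(mentions$note_id, mentions$index, sep = "\r")
    for (g in unique(grp)) {
      keys <- c(keys, sentence_powerset(mentions$cui[grp == g], cap = cap))
    }
    keys <- unique(keys)
  }
  v <- stats::setNames(rep(1, length(keys)), keys)
  if (include_pathology) {
    v[PATHOLOGY_KEY] <- count_pathology_reports(record, min_days)
  }
  v
}

tokenize_patient_doc <- function(record) {
  if (nrow(record$notes) == 0L) return(character())
  unlist(strsplit(normalize_text(record$notes$text), " ", fixed = TRUE),
         use.names = FALSE)
}

#' Assemble the patient-by-feature matrix for one feature mode
#'
#' Modes mirror the study design:
#' * `proposed`: positive-gated power-set keys plus the pathology count.
#' * `filtered_concepts`: the same minus the pathology count.
#' * `full_concepts`: singleton keys for all context-filtered CUIs (no
#'   positive-set gate, no power sets), binary.
#' * `bag_of_words`: TF-IDF token weights over whole-note text (smoothed
#'   IDF, L2-normalized rows); the vocabulary and document frequencies come
#'   from `idf_ids` (normally the training split), and unseen tokens in
#'   other documents are ignored.
#'
#' Columns are sorted by key for determinism.
#'
#' @param records `recurrex_corpus` (deduplicated).
#' @param prepared output of [prepare_corpus()] (ignored for
#'   `bag_of_words`).
#' @param mode feature mode.
#' @param idf_ids patient ids defining the TF-IDF fitting documents
#'   (default: all patients).
#' @param min_days,cap see [build_patient_vector()].
#' @return object of class `feature_matrix`: list with dense matrix `x`
#'   (patients by keys), `keys` data frame (`key`, `kind`), `patient_ids`,
#'   `labels`, `mode`.
#' @export
assemble_matrix <- function(records, prepared,
                            mode = c("proposed", "filtered_concepts",
                                     "full_concepts", "bag_of_words"),
                            idf_ids = NULL, min_days = 120L, cap = 10L) {
  mode <- match.arg(mode)
  ids <- vapply(records, function(r) r$patient_id, character(1))
  labels <- corpus_labels(records)
  if (mode == "bag_of_words") {
    docs <- lapply(records, tokenize_patient_doc)
    names(docs) <- ids
    if (is.null(idf_ids)) idf_ids <- ids
    fit_docs <- docs[idf_ids]
    vocab <- sort(unique(unlist(lapply(fit_docs, unique), use.names = FALSE)))
    nd <- length(fit_docs)
    df_count <- table(factor(unlist(lapply(fit_docs, unique),
                                    use.names = FALSE), levels = vocab))
    idf <- log((1 + nd) / (1 + as.numeric(df_count))) + 1
    x <- matrix(0, nrow = length(ids), ncol = length(vocab),
                dimnames = list(ids, paste0("tok:", vocab)))
    for (i in seq_along(ids)) {
      tf <- table(factor(docs[[i]][docs[[i]] %in% vocab], levels = vocab))
      row <- as.numeric(tf) * idf
      nrm <- sqrt(sum(row^2))
      if (nrm > 0) row <- row / nrm
      x[i, ] <- row
    }
    keys <- colnames(x)
  } else {
    mention_src <- if (mode == "full_concepts") prepared$mentions_context
                   else prepared$mentions_positive
    vecs <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      m <- mention_src[mention_src$patient_id == ids[i], , drop = FALSE]
      if (mode == "full_concepts") {
        keys_i <- unique(m$cui)
        v <- stats::setNames(rep(1, length(keys_i)), keys_i)
      } else {
        v <- build_patient_vector(records[[i]], m,
                                  include_pathology = (mode == "proposed"),
                                  min_days = min_days, cap = cap)
      }
      vecs[[i]] <- v
    }
    keys <- sort(unique(unlist(lapply(vecs, names), use.names = FALSE)))
    x <- matrix(0, nrow = length(ids), ncol = length(keys),
                dimnames = list(ids, keys))
    for (i in seq_along(ids)) {
      v <- vecs[[i]]
      if (length(v)) x[i, names(v)] <- v
    }
  }
  structure(list(
    x = x,
    keys = data.frame(key = keys, kind = feature_kind(keys),
                      stringsAsFactors = FALSE),
    patient_ids = unname(ids),
    labels = unname(labels),
    mode = mode), class = "feature_matrix")
}

#' Run the shared narrative preprocessing chain
#'
#' Deduplicates notes, splits sentences, tags concepts, applies the context
#' filters, and gates by the positive set. Stage counts (for the
#' conservation log `input = retained + dropped_by_cue + dropped_by_negex +
#' dropped_by_positive_gate`) are in `$counts`.
#'
#' @param records `recurrex_corpus`.
#' @param lexicon a `recurrex_lexicon`.
#' @param triggers a `trigger_lexicon`.
#' @param positive a `positive_concept_set`.
#' @param window NegEx window.
#' @return list with `records` (deduplicated), `sentences`,
#'   `mentions_tagged`, `mentions_context`, `mentions_positive`, `counts`.
#' @export
prepare_corpus <- function(records, lexicon = default_lexicon(),
                           triggers = default_triggers(),
                           positive = default_positive_set(),
                           window = 6L) {
  records <- structure(lapply(records, deduplicate_notes),
                       class = "recurrex_corpus")
  sentences <- corpus_sentences(records)
  mentions_tagged <- tag_corpus(sentences, lexicon)
  mentions_context <- apply_context_filters(sentences, mentions_tagged,
                                            triggers, window)
  cf <- attr(mentions_context, "counts")
  mentions_positive <- filter_to_positive(mentions_context, positive)
  counts <- list(
    mentions_in = nrow(mentions_tagged),
    dropped_by_cue = cf$dropped_by_cue,
    dropped_by_negex = cf$dropped_by_negex,
    dropped_by_positive_gate = nrow(mentions_context) -
      nrow(mentions_positive),
    mentions_retained = nrow(mentions_positive))
  stopifnot(counts$mentions_in == counts$mentions_retained +
              counts$dropped_by_cue + counts$dropped_by_negex +
              counts$dropped_by_positive_gate)
  list(records = records, sentences = sentences,
       mentions_tagged = mentions_tagged,
       mentions_context = mentions_context,
       mentions_positive = mentions_positive,
       counts = counts)
}

#' Write a feature matrix as keys TSV + MatrixMarket triplets
#'
#' @param fm a `feature_matrix`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_feature_matrix <- function(fm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keys <- fm$keys
  keys$index <- seq_len(nrow(keys)) - 1L
  utils::write.table(keys[, c("index", "kind", "key")],
                     file.path(dir, "keys.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(fm$patient_ids, file.path(dir, "patients.txt"))
  sm <- Matrix::Matrix(fm$x, sparse = TRUE)
  Matrix::writeMM(sm, file.path(dir, "values.mtx"))
  invisible(dir)
}
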