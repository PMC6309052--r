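## positive_set: curated whitelist of local-recurrence CUIs ------------------

#' Construct a positive concept set
#'
#' @param cuis character vector of CUIs (must be non-empty, well-formed,
#'   duplicates collapsed).
#' @param preferred_names optional named character vector (CUI -> name).
#' @param provenance free-text source description.
#' @return object of class `positive_concept_set`.
#' @export
positive_concept_set <- function(cuis, preferred_names = NULL,
                                 provenance = "") {
  cuis <- unique(as.character(cuis))
  if (length(cuis) == 0L) {
    stop("positive concept set must be non-empty", call. = FALSE)
  }
  bad <- !grepl(CUI_PATTERN, cuis)
  if (any(bad)) {
    stop("malformed CUI in positive set: '", cuis[bad][1], "'", call. = FALSE)
  }
  if (is.null(preferred_names)) {
    preferred_names <- stats::setNames(rep(NA_character_, length(cuis)), cuis)
  }
  structure(list(cuis = cuis,
                 preferred_names = preferred_names[cuis],
                 provenance = provenance),
            class = "positive_concept_set")
}

#' Load a positive concept set from TSV
#'
#' TSV with header columns `cui` and `preferred_name`; duplicate CUIs
#' collapse; an empty file is an error.
#'
#' @param path path to the TSV file.
#' @return a `positive_concept_set`.
#' @export
load_positive_set <- function(path) {
  if (!file.exists(path)) {
    stop("positive set file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("cui", "preferred_name") %in% names(df))) {
    stop("positive set schema error: columns must be cui, preferred_name",
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("positive set file has no rows", call. = FALSE)
  df <- df[!duplicated(df$cui), , drop = FALSE]
  positive_concept_set(df$cui,
                       stats::setNames(df$preferred_name, df$cui),
                       provenance = path)
}

#' The packaged synthetic positive concept set
#'
#' 48 CUIs describing breast cancer local recurrence. The fixture is
#' synthetic: it contains every recurrence-related CUI printed in the
#' literature body plus hand-curated recurrence vocabulary, reconstructed
#' because the original supplementary table cannot be redistributed.
#'
#' @return a `positive_concept_set`.
#' @export
default_positive_set <- function() {
  load_positive_set(system.file("extdata", "positive_cuis_synthetic.tsv",
                                package = "recurrex", mustWork = TRUE))
}

#' Load a partial-sentence corpus
#'
#' One text fragment per line, UTF-8; blank lines dropped; empty corpus is
#' an error.
#'
#' @param path path to the fixture.
#' @return character vector of fragments.
#' @export
load_partial_sentences <- function(path) {
  if (!file.exists(path)) {
    stop("partial sentence file not found: ", path, call. = FALSE)
  }
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- x[nzchar(trimws(x))]
  if (length(x) == 0L) stop("partial sentence corpus is empty", call. = FALSE)
  x
}

#' The packaged synthetic development partial sentences
#'
#' 93 fragments indicating local recurrence, mirroring the structure of a
#' development corpus of annotated progress-note excerpts (synthetic
#' reconstruction).
#'
#' @return character vector of 93 fragments.
#' @export
default_partial_sentences <- function() {
  load_partial_sentences(system.file("extdata",
                                     "partial_sentences_synthetic.txt",
                                     package = "recurrex", mustWork = TRUE))
}

#' Derive a positive concept set from partial sentences
#'
#' Each fragment is normalized and tagged with the lexicon; the union of
#' tagged CUIs minus the exclusion set (the manual relevance filter,
#' externalized as data) forms the set. Deterministic and invariant to
#' fragment order.
#'
#' @param partials character vector of fragments.
#' @param lexicon a `recurrex_lexicon`.
#' @param exclusion character vector of CUIs to remove.
#' @param provenance source description for the result.
#' @return a `positive_concept_set`.
#' @export
derive_positive_set <- function(partials, lexicon, exclusion = character(),
                                provenance = "derived from partial sentences") {
  if (length(partials) == 0L) {
    stop("partial sentence corpus is empty", call. = FALSE)
  }
  sentences <- data.frame(patient_id = "dev", note_id = "dev",
                          index = seq_along(partials) - 1L,
                          text = normalize_text(partials),
                          stringsAsFactors = FALSE)
  mentions <- tag_corpus(sentences, lexicon)
  cuis <- setdiff(sort(unique(mentions$cui)), exclusion)
  if (length(cuis) == 0L) {
    stop("positive concept set must be non-empty (no CUIs survived derivation)",
         call. = FALSE)
  }
  nm <- lexicon$preferred_name[match(cuis, lexicon$cui)]
  positive_concept_set(cuis, stats::setNames(nm, cuis), provenance)
}

#' Gate mentions by the positive concept set
#'
#' Keeps exactly the mentions whose CUI belongs to the set; order preserved.
#'
#' @param mentions mention data frame.
#' @param pos a `positive_concept_set`.
#' @return filtered mention data frame.
#' @export
filter_to_positive <- function(mentions, pos) {
  stopifnot(inherits(pos, "positive_concept_set"))
  out <- mentions[mentions$cui %in% pos$cuis, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load an exclusion CUI list (TSV with a `cui` column)
#' @param path path to the TSV.
#' @return character vector of CUIs.
#' @export
load_exclusion_set <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!"cui" %in% names(df)) {
    stop("exclusion set schema error: need a 'cui' column", call. = FALSE)
  }
  unique(df$cui)
}

#' The packaged exclusion list used by set derivation
#' @return character vector of CUIs (function-word and other off-target
#'   concepts removed during derivation).
#' @export
default_exclusion_set <- function() {
  load_exclusion_set(system.file("extdata", "excluded_cuis_synthetic.tsv",
                                 package = "recurrex", mustWork = TRUE))
}
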