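## context_filter: NegEx negation scoping + sentence-level contextual cues ---

SEEDED_NEGATION_CUES <- c("no", "rule out", "deny", "unremarkable")
SEEDED_UNCERTAINTY_CUES <- c("risk", "concern", "worry", "evaluation")

#' Construct a trigger lexicon
#'
#' Holds NegEx pre/post triggers and scope terminators plus the
#' sentence-level negation/uncertainty cue stems that drop whole sentences.
#' All entries are normalized to the lowercase alphabet of
#' [normalize_text()]. An empty lexicon is allowed (filters become no-ops).
#'
#' @param negex_pre phrases negating following concepts.
#' @param negex_post phrases negating preceding concepts.
#' @param scope_terminators phrases ending a negation scope.
#' @param sentence_negation_cues,sentence_uncertainty_cues word stems whose
#'   presence drops the sentence.
#' @return object of class `trigger_lexicon`.
#' @export
trigger_lexicon <- function(negex_pre = character(),
                            negex_post = character(),
                            scope_terminators = character(),
                            sentence_negation_cues = character(),
                            sentence_uncertainty_cues = character()) {
  norm <- function(x) {
    x <- normalize_text(as.character(x))
    unique(x[nzchar(x)])
  }
  structure(list(
    negex_pre = norm(negex_pre),
    negex_post = norm(negex_post),
    scope_terminators = norm(scope_terminators),
    sentence_negation_cues = norm(sentence_negation_cues),
    sentence_uncertainty_cues = norm(sentence_uncertainty_cues)
  ), class = "trigger_lexicon")
}

#' Default trigger lexicon
#'
#' Standard NegEx triggers plus the mandatory seeded sentence cues
#' (negation: no, rule out, deny, unremarkable; uncertainty: risk, concern,
#' worry, evaluation) and additional curated stems emulating a cue list
#' derived from a development corpus.
#'
#' @return a `trigger_lexicon`.
#' @export
default_triggers <- function() {
  trigger_lexicon(
    negex_pre = c("no", "not", "without", "denies", "denied", "deny",
                  "no evidence of", "no sign of", "negative for", "free of",
                  "rule out", "ruled out", "rules out", "ruling out",
                  "rather than", "absence of", "never developed",
                  "resolution of", "resolved"),
    negex_post = c("unlikely", "was ruled out", "is ruled out",
                   "has been ruled out", "free"),
    scope_terminators = c("but", "however", "although", "though", "except",
                          "aside from", "apart from", "yet", "still",
                          "which", "who", "since"),
    sentence_negation_cues = c(SEEDED_NEGATION_CUES, "without", "negative"),
    sentence_uncertainty_cues = c(SEEDED_UNCERTAINTY_CUES, "fear", "possib",
                                  "recommend", "prevent", "decreas",
                                  "chance", "anxious", "goal")
  )
}

#' Load a trigger lexicon from YAML
#'
#' Keys: `negex_pre`, `negex_post`, `scope_terminators`,
#' `sentence_negation_cues`, `sentence_uncertainty_cues`.
#'
#' @param path path to a YAML file.
#' @return a `trigger_lexicon`.
#' @export
load_triggers <- function(path) {
  if (!file.exists(path)) stop("trigger file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  trigger_lexicon(
    negex_pre = unlist(y$negex_pre),
    negex_post = unlist(y$negex_post),
    scope_terminators = unlist(y$scope_terminators),
    sentence_negation_cues = unlist(y$sentence_negation_cues),
    sentence_uncertainty_cues = unlist(y$sentence_uncertainty_cues))
}

## light suffix stemmer used only for cue matching
stem_token <- function(tokens) {
  out <- tokens
  out <- sub("(ies|ied)$", "y", out)
  i <- out == tokens
  out[i] <- sub("(ing|ed|es)$", "", out[i])
  i <- out == tokens
  out[i] <- sub("s$", "", out[i])
  out
}

## does each token match one cue word? token == cue, stem(token) == cue,
## or (nchar(cue) >= 4) cue is a prefix of token
token_matches_cueword <- function(tokens, stems, cueword) {
  hit <- tokens == cueword | stems == cueword
  if (nchar(cueword) >= 4L) {
    hit <- hit | startsWith(tokens, cueword)
  }
  hit
}

#' Test a sentence for sentence-level contextual cues
#'
#' True iff any token run matches a configured negation or uncertainty cue
#' at a word boundary. Matching is stem-aware ("concern" matches
#' "concerned", "deny" matches "denies"); multi-word cues ("rule out")
#' match contiguous token runs word-by-word under the same rule.
#'
#' @param sentence normalized sentence string (or one-row sentence frame).
#' @param triggers a `trigger_lexicon`.
#' @return list with `has` (logical), `cue` (first matched cue or `NA`) and
#'   `type` ("negation", "uncertainty" or `NA`).
#' @export
has_contextual_cue <- function(sentence, triggers) {
  if (is.data.frame(sentence)) sentence <- sentence$text
  toks <- tokenize(sentence)
  if (length(toks) == 0L) {
    return(list(has = FALSE, cue = NA_character_, type = NA_character_))
  }
  stems <- stem_token(toks)
  cues <- c(triggers$sentence_negation_cues, triggers$sentence_uncertainty_cues)
  types <- c(rep("negation", length(triggers$sentence_negation_cues)),
             rep("uncertainty", length(triggers$sentence_uncertainty_cues)))
  best_pos <- Inf; best <- NA_character_; best_type <- NA_character_
  for (ci in seq_along(cues)) {
    cw <- strsplit(cues[ci], " ", fixed = TRUE)[[1]]
    k <- length(cw)
    if (k > length(toks)) next
    ok <- token_matches_cueword(toks, stems, cw[1])
    if (k > 1L) {
      for (j in 2L:k) {
        nxt <- c(token_matches_cueword(toks, stems, cw[j])[-seq_len(j - 1L)],
                 rep(FALSE, j - 1L))
        ok <- ok & nxt
      }
    }
    pos <- which(ok)
    if (length(pos) && pos[1] < best_pos) {
      best_pos <- pos[1]; best <- cues[ci]; best_type <- types[ci]
    }
  }
  list(has = is.finite(best_pos), cue = best, type = best_type)
}

## vectorized cue test over many sentences; returns logical vector
sentences_have_cue <- function(texts, triggers) {
  cues <- c(triggers$sentence_negation_cues, triggers$sentence_uncertainty_cues)
  if (length(cues) == 0L || length(texts) == 0L) {
    return(rep(FALSE, length(texts)))
  }
  tok_list <- strsplit(texts, " ", fixed = TRUE)
  ntok <- lengths(tok_list)
  sid <- rep.int(seq_along(texts), ntok)
  toks <- unlist(tok_list, use.names = FALSE)
  stems <- stem_token(toks)
  N <- length(toks)
  out <- rep(FALSE, length(texts))
  for (cue in cues) {
    cw <- strsplit(cue, " ", fixed = TRUE)[[1]]
    k <- length(cw)
    idx <- which(token_matches_cueword(toks, stems, cw[1]))
    if (k > 1L && length(idx)) {
      for (j in 2L:k) {
        pos <- pmin(idx + j - 1L, N)
        idx <- idx[idx + j - 1L <= N &
                     token_matches_cueword(toks[pos], stems[pos], cw[j]) &
                     sid[pos] == sid[idx]]
        if (!length(idx)) break
      }
    }
    if (length(idx)) out[unique(sid[idx])] <- TRUE
  }
  out
}

## locate exact-token phrase occurrences; returns data.frame(first, last)
find_phrases <- function(toks, phrases) {
  out <- list()
  n <- length(toks)
  for (p in phrases) {
    pw <- strsplit(p, " ", fixed = TRUE)[[1]]
    k <- length(pw)
    if (k > n) next
    for (i in seq_len(n - k + 1L)) {
      if (all(toks[i:(i + k - 1L)] == pw)) {
        out[[length(out) + 1L]] <- c(first = i, last = i + k - 1L)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(first = integer(), last = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

#' Flag negated concept mentions with a NegEx-style scope rule
#'
#' A pre-trigger negates mentions starting within `window` tokens after it;
#' a post-trigger negates mentions ending within `window` tokens before it.
#' A scope terminator cuts the scope. Mentions are otherwise untouched.
#'
#' @param sentence normalized sentence string (or one-row sentence frame).
#' @param mentions mention data frame for this sentence.
#' @param triggers a `trigger_lexicon`.
#' @param window scope size in tokens (default 6, the published NegEx
#'   window).
#' @return `mentions` with the `negated` flag set.
#' @export
detect_negated <- function(sentence, mentions, triggers, window = 6L) {
  if (is.data.frame(sentence)) sentence <- sentence$text
  if (nrow(mentions) == 0L) return(mentions)
  toks <- tokenize(sentence)
  starts <- token_starts(toks)
  ## token index of each mention's first and last token
  m_first <- findInterval(mentions$start + 1L, starts)
  m_last <- findInterval(mentions$end, starts)
  pre <- find_phrases(toks, triggers$negex_pre)
  post <- find_phrases(toks, triggers$negex_post)
  term <- find_phrases(toks, triggers$scope_terminators)
  negated <- rep(FALSE, nrow(mentions))
  if (nrow(pre)) {
    for (i in seq_len(nrow(pre))) {
      lo <- pre$last[i] + 1L
      hi <- min(pre$last[i] + window, length(toks))
      if (nrow(term)) {
        cut <- term$first[term$first >= lo & term$first <= hi]
        if (length(cut)) hi <- min(cut) - 1L
      }
      if (lo <= hi) negated <- negated | (m_first >= lo & m_first <= hi)
    }
  }
  if (nrow(post)) {
    for (i in seq_len(nrow(post))) {
      hi <- post$first[i] - 1L
      lo <- max(post$first[i] - window, 1L)
      if (nrow(term)) {
        cut <- term$last[term$last >= lo & term$last <= hi]
        if (length(cut)) lo <- max(cut) + 1L
      }
      if (lo <= hi) negated <- negated | (m_last >= lo & m_last <= hi)
    }
  }
  mentions$negated <- negated
  mentions
}

#' Apply sentence-cue and negation filters to tagged mentions
#'
#' Sentences carrying a contextual cue lose all their mentions; among the
#' surviving sentences, NegEx-negated mentions are dropped. The retained set
#' is always a subset of the input. Drop counts are attached as the
#' `"counts"` attribute (`input`, `dropped_by_cue`, `dropped_by_negex`,
#' `retained`).
#'
#' @param sentences sentence data frame ([corpus_sentences()]).
#' @param mentions mention data frame ([tag_corpus()]).
#' @param triggers a `trigger_lexicon`.
#' @param window NegEx scope window in tokens.
#' @return retained mention data frame (all `negated` flags `FALSE`).
#' @export
apply_context_filters <- function(sentences, mentions, triggers,
                                  window = 6L) {
  counts <- list(input = nrow(mentions), dropped_by_cue = 0L,
                 dropped_by_negex = 0L, retained = nrow(mentions))
  if (nrow(mentions) == 0L) {
    attr(mentions, "counts") <- counts
    return(mentions)
  }
  skey <- paste(sentences$patient_id, sentences$note_id, sentences$index,
                sep = "\r")
  cue <- sentences_have_cue(sentences$text, triggers)
  mkey <- paste(mentions$patient_id, mentions$note_id, mentions$index,
                sep = "\r")
  cue_sent <- skey[cue]
  drop_cue <- mkey %in% cue_sent
  counts$dropped_by_cue <- sum(drop_cue)
  kept <- mentions[!drop_cue, , drop = FALSE]
  mkey <- mkey[!drop_cue]
  if (nrow(kept) > 0L) {
    text_by_key <- stats::setNames(sentences$text, skey)
    out <- vector("list", 0L)
    for (k in unique(mkey)) {
      sub <- kept[mkey == k, , drop = FALSE]
      sub <- detect_negated(text_by_key[[k]], sub, triggers, window)
      out[[length(out) + 1L]] <- sub
    }
    kept <- do.call(rbind, out)
    counts$dropped_by_negex <- sum(kept$negated)
    kept <- kept[!kept$negated, , drop = FALSE]
    rownames(kept) <- NULL
  }
  counts$retained <- nrow(kept)
  attr(kept, "counts") <- counts
  kept
}
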