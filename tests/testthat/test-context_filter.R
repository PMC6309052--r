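simple_lex <- function() {
  tiny_lexicon(list(c("C0000001", "recurrence", "recurrence", "1"),
                    c("C0000002", "pain", "pain", "1")))
}

test_that("NegEx flags mentions inside a pre-trigger scope", {
  trg <- default_triggers()
  lex <- simple_lex()
  s <- "no evidence of recurrence"
  m <- detect_negated(s, tag_sentence(s, lex), trg)
  expect_true(m$negated[m$cui == "C0000001"])
  s2 <- "recurrence noted today"
  m2 <- detect_negated(s2, tag_sentence(s2, lex), trg)
  expect_false(any(m2$negated))
})

test_that("a scope terminator cuts the negation window", {
  trg <- default_triggers()
  lex <- simple_lex()
  s <- "denies pain but reports recurrence"
  m <- detect_negated(s, tag_sentence(s, lex), trg)
  expect_true(m$negated[m$cui == "C0000002"])    # pain
  expect_false(m$negated[m$cui == "C0000001"])   # recurrence, after "but"
})

test_that("post-triggers negate preceding mentions within the window", {
  trg <- trigger_lexicon(negex_post = "unlikely")
  lex <- simple_lex()
  s <- "recurrence unlikely at this time"
  m <- detect_negated(s, tag_sentence(s, lex), trg)
  expect_true(m$negated[1])
})

test_that("sentence cues match by stem at word boundaries", {
  trg <- default_triggers()
  pos_ex <- "she was found to have an ipsilateral breast tumor recurrence"
  neg_ex <- paste("pt very concerned and anxious as some of her friends have",
                  "been diagnosed with recurrent breast cancer")
  expect_false(has_contextual_cue(pos_ex, trg)$has)
  got <- has_contextual_cue(neg_ex, trg)
  expect_true(got$has)
  expect_equal(got$cue, "concern")
  expect_true(has_contextual_cue("no residual disease", trg)$has)
  # stemmed matches: "denies" <- "deny", "worried" <- "worry"
  expect_true(has_contextual_cue("she denies any masses", trg)$has)
  expect_true(has_contextual_cue("she is worried today", trg)$has)
  # short stems do not swallow longer words: "now" is not "no"
  expect_false(has_contextual_cue("now with newly diagnosed dcis recurrence",
                                  trg)$has)
  # multi-word cue with inflection
  expect_true(has_contextual_cue("imaging ruled out disease", trg)$has)
})

test_that("context filters drop cue sentences then negated mentions", {
  trg <- default_triggers()
  lex <- simple_lex()
  sents <- rbind(
    sentence_row("worried about recurrence and pain", index = 0L),
    sentence_row("it is not pain but is recurrence", index = 1L),
    sentence_row("recurrence confirmed on biopsy", index = 2L))
  mentions <- tag_corpus(sents, lex)
  kept <- apply_context_filters(sents, mentions, trg)
  counts <- attr(kept, "counts")
  # sentence 0 dropped whole (cue "worry"), sentence 1 loses "pain" to NegEx
  expect_equal(counts$dropped_by_cue, 2L)
  expect_equal(counts$dropped_by_negex, 1L)
  expect_equal(kept$index, c(1L, 2L))
  expect_equal(kept$cui, c("C0000001", "C0000001"))
  expect_equal(counts$input,
               counts$retained + counts$dropped_by_cue + counts$dropped_by_negex)
})

test_that("filter output is a subset and shrinks monotonically with cues", {
  lex <- default_lexicon()
  set.seed(21)
  pool <- c("biopsy confirmed recurrence in the left breast",
            "no evidence of recurrence today",
            "worried about a possible recurrence",
            "recurrent breast cancer treated with chemotherapy",
            "she denies pain and fevers",
            "follow up in three months")
  for (rep in 1:5) {
    texts <- sample(pool, 4, replace = TRUE)
    sents <- do.call(rbind, lapply(seq_along(texts), function(i)
      sentence_row(texts[i], note_id = "n1", index = i - 1L)))
    mentions <- tag_corpus(sents, lex)
    base_trg <- default_triggers()
    kept <- apply_context_filters(sents, mentions, base_trg)
    key <- function(df) paste(df$index, df$cui, df$start)
    expect_true(all(key(kept) %in% key(mentions)))
    wider <- trigger_lexicon(
      negex_pre = base_trg$negex_pre, negex_post = base_trg$negex_post,
      scope_terminators = base_trg$scope_terminators,
      sentence_negation_cues = base_trg$sentence_negation_cues,
      sentence_uncertainty_cues = c(base_trg$sentence_uncertainty_cues,
                                    "biopsy", "follow"))
    kept2 <- apply_context_filters(sents, mentions, wider)
    expect_true(all(key(kept2) %in% key(kept)))
  }
})

test_that("an empty trigger lexicon passes everything through unflagged", {
  lex <- simple_lex()
  sents <- sentence_row("no pain and no recurrence")
  mentions <- tag_corpus(sents, lex)
  kept <- apply_context_filters(sents, mentions, trigger_lexicon())
  expect_equal(nrow(kept), nrow(mentions))
  expect_false(any(kept$negated))
})
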