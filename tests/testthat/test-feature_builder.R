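test_that("sentence power sets equal brute-force subset enumeration", {
  cuis <- sprintf("C%07d", 1:8)
  for (n in 1:8) {
    got <- sort(sentence_powerset(cuis[seq_len(n)]))
    expect_identical(got, brute_subsets(cuis[seq_len(n)]))
    expect_length(got, choose(n, 1) + choose(n, 2) + choose(n, 3))
  }
})

test_that("the three-concept example expands to exactly seven features", {
  keys <- sentence_powerset(c("C1997028", "C1387407", "C2945760"))
  expect_setequal(keys, c(
    "C1387407", "C1997028", "C2945760",
    "C1387407+C1997028", "C1997028+C2945760", "C1387407+C2945760",
    "C1387407+C1997028+C2945760"))
})

test_that("oversized sentences are capped with a warning", {
  cuis <- sprintf("C%07d", 1:12)
  expect_warning(keys <- sentence_powerset(cuis, cap = 10L), "capping")
  expect_length(keys, 10 + choose(10, 2) + choose(10, 3))
})

test_that("pathology report counting is inclusive at the 120-day boundary", {
  r <- make_record(dx = "2010-01-01",
                   pdates = as.Date("2010-01-01") + c(30, 120, 400))
  expect_equal(count_pathology_reports(r), 2L)
  expect_equal(count_pathology_reports(make_record()), 0L)
  r2 <- make_record(dx = "2010-06-01", pdates = c("2010-01-10", "2010-05-01"))
  expect_equal(count_pathology_reports(r2), 0L)
})

test_that("patient vectors compose power sets with the pathology count", {
  r <- make_record(dx = "2010-01-01",
                   pdates = as.Date("2010-01-01") + c(150, 500))
  m <- data.frame(cui = c("C1997028", "C1387407", "C2945760"),
                  patient_id = "p1", note_id = "n1", index = 0L,
                  start = 0L, end = 1L, matched_text = "x", score = 1,
                  negated = FALSE, stringsAsFactors = FALSE)
  v <- build_patient_vector(r, m)
  expect_length(v, 8L)  # 7 power-set keys + pathology count
  expect_equal(unname(v[".pathology_count"]), 2)
  expect_true(all(v[names(v) != ".pathology_count"] == 1))
  # no mentions: only the pathology key
  v0 <- build_patient_vector(r, m[0, ])
  expect_equal(names(v0), ".pathology_count")
  # repeated co-occurrence still yields binary presence
  m2 <- rbind(m, transform(m, index = 1L))
  expect_identical(build_patient_vector(r, m2), v)
  # sentence order does not matter
  expect_identical(build_patient_vector(r, m2[rev(seq_len(nrow(m2))), ]), v)
})

make_prepared <- function() {
  lex <- default_lexicon()
  r1 <- make_record("p1", "2010-01-01", make_note(
    "n1", "2010-07-01",
    "Now with newly diagnosed DCIS recurrence. Follow up in clinic."),
    pdates = as.Date("2010-01-01") + c(130, 300), label = 1L)
  r2 <- make_record("p2", "2011-01-01", make_note(
    "n2", "2011-05-01", "Her pain is well controlled. She returns to clinic."),
    label = 0L)
  corpus <- as_corpus(r1, r2)
  list(corpus = corpus, prepared = prepare_corpus(corpus, lexicon = lex))
}

test_that("feature modes differ exactly as designed", {
  mp <- make_prepared()
  fm_prop <- assemble_matrix(mp$corpus, mp$prepared, "proposed")
  fm_filt <- assemble_matrix(mp$corpus, mp$prepared, "filtered_concepts")
  fm_full <- assemble_matrix(mp$corpus, mp$prepared, "full_concepts")
  expect_equal(ncol(fm_prop$x), ncol(fm_filt$x) + 1L)
  expect_setequal(setdiff(fm_prop$keys$key, fm_filt$keys$key),
                  ".pathology_count")
  # full-concept baseline: singletons only, no positive gate, binary
  expect_false(any(grepl("[+]", fm_full$keys$key)))
  expect_true(all(fm_full$x %in% c(0, 1)))
  expect_true(any(!fm_full$keys$key %in% default_positive_set()$cuis))
  # binary everywhere except the pathology column
  bincols <- fm_prop$keys$key != ".pathology_count"
  expect_true(all(fm_prop$x[, bincols] %in% c(0, 1)))
  expect_equal(unname(fm_prop$x["p1", ".pathology_count"]), 2)
  expect_error(assemble_matrix(mp$corpus, mp$prepared, "nope"))
})

test_that("TF-IDF bag of words follows the smoothed, L2-normalized form", {
  r1 <- make_record("p1", "2010-01-01",
                    make_note("n1", "2010-02-01", "recurrence"), label = 1L)
  r2 <- make_record("p2", "2010-01-01",
                    make_note("n2", "2010-02-01", "recurrence"), label = 0L)
  fm <- assemble_matrix(as_corpus(r1, r2), NULL, "bag_of_words")
  expect_equal(fm$keys$key, "tok:recurrence")
  expect_equal(unname(fm$x[, 1]), c(1, 1))  # identical docs, unit L2 rows
  # hand-computed two-token case: tf * (log((1+n)/(1+df)) + 1), L2 rows
  r3 <- make_record("p3", "2010-01-01",
                    make_note("n3", "2010-02-01", "recurrence stable stable"),
                    label = 0L)
  fm2 <- assemble_matrix(as_corpus(r1, r3), NULL, "bag_of_words")
  idf_rec <- log(3 / 3) + 1
  idf_sta <- log(3 / 2) + 1
  raw <- c(1 * idf_rec, 2 * idf_sta)
  expect_equal(unname(fm2$x["p3", c("tok:recurrence", "tok:stable")]),
               raw / sqrt(sum(raw^2)), tolerance = 1e-12)
})

test_that("preprocessing stage counts reconcile exactly", {
  mp <- make_prepared()
  cts <- mp$prepared$counts
  expect_equal(cts$mentions_in,
               cts$mentions_retained + cts$dropped_by_cue +
                 cts$dropped_by_negex + cts$dropped_by_positive_gate)
  expect_gt(cts$mentions_retained, 0L)
})
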