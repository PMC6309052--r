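test_that("the 7:3 split is disjoint, exhaustive, sized like the study", {
  ids <- sprintf("p%03d", 1:701)
  sp <- split_train_test(ids, 0.7, seed = 1L)
  expect_length(sp$train, 490L)
  expect_length(sp$test, 211L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(split_train_test(ids, 0.7, seed = 1L), sp)
  sp2 <- split_train_test(ids, 0.7, seed = 2L)
  expect_false(identical(sp2$train, sp$train))
  expect_length(sp2$train, 490L)
  expect_error(split_train_test("p1", 0.7, 1L), "at least 2")
})

test_that("metrics from the reported confusion counts reproduce the arithmetic", {
  tp <- 152L; fp <- 32L; fn <- 41L; tn <- 476L
  labels <- rep(c(1, 1, 0, 0), c(tp, fn, fp, tn))
  scores <- rep(c(0.9, 0.1, 0.9, 0.1), c(tp, fn, fp, tn))
  m <- compute_metrics(labels, scores, cutoff = 0.5)
  expect_equal(m$tp, tp); expect_equal(m$fp, fp)
  expect_equal(m$fn, fn); expect_equal(m$tn, tn)
  expect_equal(m$precision, 152 / 184, tolerance = 1e-12)
  expect_equal(m$recall, 152 / 193, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (152 / 184) * (152 / 193) / (152 / 184 + 152 / 193),
               tolerance = 1e-12)
})

test_that("rank-based AUC matches brute-force pair counting", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(6:14, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 1)  # coarse grid forces ties
    m <- suppressWarnings(compute_metrics(labels, scores))
    expect_equal(m$auc, brute_auc(labels, scores), tolerance = 1e-12)
  }
  expect_equal(compute_metrics(c(0, 0, 1, 1), c(.1, .2, .8, .9))$auc, 1.0)
  expect_equal(compute_metrics(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)
  expect_warning(m1 <- compute_metrics(c(1, 1), c(.2, .9)), "single-class")
  expect_true(is.na(m1$auc))
})

test_that("metrics are invariant to patient ordering", {
  set.seed(23)
  labels <- rbinom(30, 1, 0.4); scores <- runif(30)
  a <- compute_metrics(labels, scores)
  perm <- sample.int(30)
  b <- compute_metrics(labels[perm], scores[perm])
  expect_equal(a, b)
})

test_that("Cohen's kappa matches its closed form", {
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1.0)
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1.0)
  ann1 <- rep(c(1, 1, 0, 0), c(40, 5, 5, 50))
  ann2 <- rep(c(1, 0, 1, 0), c(40, 5, 5, 50))
  expect_equal(cohen_kappa(ann1, ann2), 79 / 99, tolerance = 1e-12)
  expect_equal(cohen_kappa(rep(1, 5), rep(1, 5)), 1.0)
})

small_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_patients = 80L, prevalence = 0.3,
                              notes_per_patient = 2, sentences_per_note = 3,
                              miss_rate = 0, confound_rate = 0)
      cache <<- generate_corpus(cfg, seed = 11L)$records
    }
    cache
  }
})

small_experiment <- function(seed = 5L) {
  run_experiment(small_corpus(), modes = c("proposed", "filtered_concepts"),
                 grid = list(kernels = "rbf", C = 11, gamma = 0.0091),
                 folds = 3L, seed = seed)
}

test_that("the experiment harness reports both phases for every mode", {
  rep1 <- small_experiment()
  expect_setequal(names(rep1$modes), c("proposed", "filtered_concepts"))
  npos_test <- sum(corpus_labels(small_corpus())[rep1$split$test])
  for (m in rep1$modes) {
    expect_equal(nrow(m$cv_table), 3L)
    expect_s3_class(m$heldout, "metrics_report")
    expect_true(all(c("precision", "recall", "f1", "auc") %in% names(m$cv)))
    # totals reconcile on the held-out phase: TP + FN = positives
    expect_equal(m$heldout$tp + m$heldout$fn, npos_test)
  }
  expect_equal(rep1$modes$proposed$n_features,
               rep1$modes$filtered_concepts$n_features + 1L)
  expect_named(rep1$comparisons, "filtered_concepts")
  p <- rep1$comparisons$filtered_concepts$auc$p_value
  expect_true(is.na(p) || (p >= 0 && p <= 1))
})

test_that("experiments are reproducible bit for bit given the seed", {
  a <- report_to_list(small_experiment())
  b <- report_to_list(small_experiment())
  expect_identical(a, b)
  j1 <- jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA)
  j2 <- jsonlite::toJSON(b, auto_unbox = TRUE, digits = NA)
  expect_identical(as.character(j1), as.character(j2))
})

test_that("error analysis summarizes misclassified patients", {
  r1 <- make_record("p1", "2010-01-01", pdates = as.Date("2010-06-01") + 0:2,
                    label = 1L)
  r2 <- make_record("p2", "2010-01-01", label = 0L)
  r3 <- make_record("p3", "2010-01-01", pdates = "2010-08-01", label = 1L)
  recs <- as_corpus(r1, r2, r3)
  scores <- data.frame(patient_id = c("p1", "p2", "p3"),
                       score = c(0.9, 0.1, 0.2),
                       label = c(1L, 0L, 0L), stringsAsFactors = FALSE)
  ea <- error_analysis(recs, scores)
  expect_equal(ea$listing$patient_id, "p3")
  expect_equal(ea$listing$group, "FN")
  expect_equal(unname(ea$group_means["FN"]), 1)
  expect_equal(unname(ea$group_means["TP"]), 3)
  # no misclassifications: empty listing
  scores2 <- transform(scores, score = c(0.9, 0.1, 0.8))
  ea2 <- error_analysis(recs, scores2)
  expect_equal(nrow(ea2$listing), 0L)
})
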