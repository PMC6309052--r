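random_binary_fm <- function(n = 20L, p = 8L) {
  x <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, sprintf("C%07d", seq_len(p))))
  structure(list(x = x,
                 keys = data.frame(key = colnames(x), kind = "cui_set",
                                   stringsAsFactors = FALSE)),
            class = "feature_matrix")
}

test_that("chi-square scores agree with the reference 2x2 computation", {
  set.seed(101)
  for (rep in 1:20) {
    fm <- random_binary_fm()
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    for (k in colnames(fm$x)) {
      xk <- fm$x[, k]
      expected <- if (length(unique(xk)) < 2) 0 else
        suppressWarnings(unname(
          stats::chisq.test(table(factor(xk, levels = 0:1),
                                  factor(y, levels = 0:1)),
                            correct = FALSE)$statistic))
      expect_equal(chi2_stat(xk, y), expected, tolerance = 1e-10)
    }
  }
})

test_that("selection keeps the top fraction plus the exempt pathology count", {
  set.seed(7)
  fm <- random_binary_fm(30, 10)
  y <- fm$x[, 1]  # column 1 identical to the label: must rank first
  sel <- chi_square_select(fm, y, 0.5)
  expect_length(sel$retained, 5L)
  expect_equal(sel$retained[1], colnames(fm$x)[1])
  # with a pathology column present it is always retained, unranked
  x2 <- cbind(fm$x, .pathology_count = rpois(30, 2))
  fm2 <- structure(list(x = x2, keys = data.frame(
    key = colnames(x2),
    kind = c(rep("cui_set", 10), "pathology_count"),
    stringsAsFactors = FALSE)), class = "feature_matrix")
  sel2 <- chi_square_select(fm2, y, 0.5)
  expect_length(sel2$retained, 6L)
  expect_true(".pathology_count" %in% sel2$retained)
  expect_false(".pathology_count" %in% names(sel2$scores))
  # full retention and errors
  expect_length(chi_square_select(fm, y, 1.0)$retained, 10L)
  expect_error(chi_square_select(fm, rep(1L, 30), 0.5), "both classes")
  expect_error(chi_square_select(fm, y, 0), "fraction")
})

test_that("hyperparameter grids follow the stated arithmetic reading", {
  g <- default_grid()
  expect_equal(g$C, c(1, 11, 21, 31, 41, 51, 61, 71, 81, 91))
  expect_equal(g$gamma, seq(0.0001, 0.0091, by = 0.001))
  expect_length(g$gamma, 10L)
  expect_equal(g$kernels, c("rbf", "linear", "poly", "sigmoid"))
})

separable_toy <- function(n = 40L) {
  set.seed(13)
  x <- rbind(matrix(rnorm(n, 0, 0.3), n / 2, 2),
             matrix(rnorm(n, 4, 0.3), n / 2, 2))
  colnames(x) <- c("C0000001", "C0000002")
  list(x = x, y = rep(c(0L, 1L), each = n / 2))
}

test_that("grid search finds a perfect configuration on separable data", {
  toy <- separable_toy()
  gs <- grid_search_svm(toy$x, toy$y,
                        grid = list(kernels = c("rbf", "linear"),
                                    C = c(1, 11), gamma = c(0.01, 0.1)),
                        folds = 5L, seed = 3L)
  expect_equal(max(gs$table$cv_micro_f1), 1.0)
  # ties resolve to smallest C, then gamma, then kernel order
  best <- gs$best
  perfect <- gs$table[gs$table$cv_micro_f1 == 1, ]
  expect_equal(best$C, min(perfect$C))
  # duplicated configurations cannot change the winner
  gs2 <- grid_search_svm(toy$x, toy$y,
                         grid = list(kernels = c("rbf", "rbf", "linear"),
                                     C = c(1, 1, 11), gamma = c(0.01, 0.01, 0.1)),
                         folds = 5L, seed = 3L)
  expect_equal(gs2$best$kernel, best$kernel)
  expect_equal(gs2$best$C, best$C)
  expect_equal(gs2$best$gamma, best$gamma)
})

test_that("grid search is deterministic and order-invariant on clear data", {
  toy <- separable_toy()
  g <- list(kernels = c("rbf", "linear"), C = c(1, 41), gamma = c(0.01))
  a <- grid_search_svm(toy$x, toy$y, g, seed = 5L)
  b <- grid_search_svm(toy$x, toy$y, g, seed = 5L)
  expect_identical(a$table, b$table)
  set.seed(9); perm <- sample.int(nrow(toy$x))
  c_ <- grid_search_svm(toy$x[perm, ], toy$y[perm], g, seed = 5L)
  expect_equal(c_$best$kernel, a$best$kernel)
  expect_equal(c_$best$C, a$best$C)
  expect_error(grid_search_svm(toy$x, rep(0:1, c(38, 2)), g, folds = 5L),
               "folds|class")
})

test_that("training yields zero error, reproducible serialized models", {
  toy <- separable_toy()
  spec <- model_spec("rbf", C = 11, gamma = 0.01, seed = 2L)
  m <- train(toy$x, toy$y, spec)
  pr <- predict(m, toy$x)
  expect_equal(pr$label, toy$y)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict(m2, toy$x)$score, pr$score)
  # refit with same seed reproduces predictions exactly
  m3 <- train(toy$x, toy$y, spec)
  expect_identical(predict(m3, toy$x)$score, pr$score)
  expect_error(train(toy$x[0, , drop = FALSE], integer(), spec), "empty")
})

test_that("probabilities live in [0,1], honor the >= cutoff, and align columns", {
  toy <- separable_toy()
  m <- train(toy$x, toy$y, model_spec("linear", C = 1, seed = 0L))
  # missing columns are zero-filled; extra columns ignored
  probe <- matrix(0, 1, 1, dimnames = list("q", "C0000001"))
  pr <- predict(m, probe)
  expect_true(pr$score >= 0 && pr$score <= 1)
  expect_equal(pr$label, as.integer(pr$score >= 0.5))
  # cutoff 0 labels everything positive (>= convention)
  expect_true(all(predict(m, toy$x, cutoff = 0)$label == 1L))
})

test_that("a one-feature linear model scores monotonically in the feature", {
  set.seed(4)
  x <- matrix(c(rnorm(20, 0), rnorm(20, 3)), ncol = 1,
              dimnames = list(NULL, "C0000001"))
  y <- rep(c(0L, 1L), each = 20)
  m <- train(x, y, model_spec("linear", C = 1, seed = 1L))
  probe <- matrix(seq(-2, 5, length.out = 30), ncol = 1,
                  dimnames = list(NULL, "C0000001"))
  s <- predict(m, probe)$score
  expect_true(all(diff(s) >= -1e-12))
})

test_that("linear-kernel weights orient toward the recurrence class", {
  toy <- separable_toy()
  m <- train(toy$x, toy$y, model_spec("linear", C = 1, seed = 0L))
  w <- svm_coefficients(m)
  expect_named(w, c("C0000001", "C0000002"))
  expect_true(all(w > 0))  # both features increase with class 1
  m_rbf <- train(toy$x, toy$y, model_spec("rbf", C = 1, gamma = 0.01))
  expect_error(svm_coefficients(m_rbf), "linear")
})

test_that("micro-averaged F1 equals pooled-count accuracy in binary tasks", {
  set.seed(31)
  for (rep in 1:10) {
    truth <- rbinom(25, 1, 0.4); pred <- rbinom(25, 1, 0.5)
    expect_equal(micro_f1(pred, truth), mean(pred == truth))
  }
})
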