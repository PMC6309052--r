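## evaluation: splitting, metrics, experiment harness, error analysis --------

#' Random train/test split of patient ids
#'
#' Simple (non-stratified) seeded random split; the training set receives
#' `floor(ratio * n)` patients, matching a 7:3 split of 701 patients into
#' 490 and 211.
#'
#' @param records a `recurrex_corpus` (or a character vector of ids).
#' @param ratio training fraction (default 0.7).
#' @param seed RNG seed.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_train_test <- function(records, ratio = 0.7, seed = 0L) {
  ids <- if (is.character(records)) records
         else vapply(records, function(r) r$patient_id, character(1))
  n <- length(ids)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  stopifnot(ratio > 0, ratio < 1)
  set.seed(seed)
  perm <- ids[sample.int(n)]
  n_train <- floor(ratio * n)
  list(train = perm[seq_len(n_train)], test = perm[(n_train + 1L):n])
}

#' Classification metrics at a probability cutoff
#'
#' Confusion counts at `cutoff` (>= is positive), precision, recall, F1,
#' and AUC via the rank (Mann-Whitney) statistic with midranks for ties.
#' With a single-class label vector the AUC is undefined and reported as
#' `NA` with a warning.
#'
#' @param labels binary labels.
#' @param scores probabilities in `[0, 1]`.
#' @param cutoff decision cutoff (default 0.5).
#' @return object of class `metrics_report`.
#' @export
compute_metrics <- function(labels, scores, cutoff = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores))
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L) {
    warning("AUC undefined for single-class labels; reported as NA")
    auc <- NA_real_
  } else {
    r <- rank(scores)  # midranks for ties
    auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  structure(list(precision = precision, recall = recall, f1 = f1, auc = auc,
                 tp = tp, fp = fp, fn = fn, tn = tn,
                 n = length(labels), cutoff = cutoff),
            class = "metrics_report")
}

#' Cohen's kappa for two binary annotations
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product chance agreement. Perfect chance agreement (`p_e` = 1)
#' is defined as 1 when observed agreement is perfect and is an error
#' otherwise.
#'
#' @param ann1,ann2 equal-length binary vectors.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(ann1, ann2) {
  ann1 <- as.integer(ann1); ann2 <- as.integer(ann2)
  stopifnot(length(ann1) == length(ann2), length(ann1) > 0)
  n <- length(ann1)
  po <- mean(ann1 == ann2)
  p1a <- mean(ann1 == 1); p1b <- mean(ann2 == 1)
  pe <- p1a * p1b + (1 - p1a) * (1 - p1b)
  if (pe >= 1) {
    if (po == 1) return(1)
    stop("kappa undefined: chance agreement is 1 but observed is not",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

fold_metric_table <- function(per_fold) {
  do.call(rbind, lapply(seq_along(per_fold), function(f) {
    m <- per_fold[[f]]
    data.frame(fold = f, precision = m$precision, recall = m$recall,
               f1 = m$f1, auc = m$auc)
  }))
}

metric_mean_sd <- function(tab) {
  metrics <- c("precision", "recall", "f1", "auc")
  out <- lapply(metrics, function(m) {
    v <- tab[[m]]
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v))
  })
  stats::setNames(out, metrics)
}

#' Run the full comparison experiment
#'
#' Mirrors the study design: one shared 7:3 split, shared stratified CV
#' folds on the training set, chi-square selection per feature mode
#' (computed on the training split before cross-validation), a grid search
#' selecting the best kernel/C/gamma by CV micro-F1, fold-wise
#' precision/recall/F1/AUC with the selected configuration, a held-out
#' evaluation, and paired t-tests across folds between the proposed mode
#' and each baseline.
#'
#' @param corpus labeled `recurrex_corpus`.
#' @param modes feature modes to run (the proposed model plus up to three
#'   baselines).
#' @param lexicon,triggers,positive pipeline resources.
#' @param ratio train fraction; `folds` CV folds; `fraction` chi-square
#'   retention; `grid` hyperparameter grid; `cutoff` probability cutoff;
#'   `seed` master seed; `cap`/`min_days` feature-builder knobs.
#' @return object of class `experiment_report`.
#' @export
run_experiment <- function(corpus,
                           modes = c("proposed", "full_concepts",
                                     "filtered_concepts", "bag_of_words"),
                           lexicon = default_lexicon(),
                           triggers = default_triggers(),
                           positive = default_positive_set(),
                           ratio = 0.7, folds = 5L, fraction = 0.5,
                           grid = default_grid(), cutoff = 0.5,
                           seed = 1L, cap = 10L, min_days = 120L) {
  labels_all <- corpus_labels(corpus)
  if (anyNA(labels_all)) stop("experiment requires a fully labeled corpus",
                              call. = FALSE)
  prepared <- prepare_corpus(corpus, lexicon, triggers, positive)
  records <- prepared$records
  ids <- vapply(records, function(r) r$patient_id, character(1))
  split <- split_train_test(records, ratio, seed)
  tr_idx <- match(split$train, ids)
  te_idx <- match(split$test, ids)
  y_tr <- labels_all[tr_idx]
  fold_ids <- stratified_folds(y_tr, folds, seed + 1L)
  res <- list()
  for (mode in modes) {
    fm <- assemble_matrix(records, prepared, mode, idf_ids = split$train,
                          min_days = min_days, cap = cap)
    sel <- chi_square_select(
      structure(list(x = fm$x[tr_idx, , drop = FALSE], keys = fm$keys),
                class = "feature_matrix"),
      y_tr, fraction)
    x_tr <- fm$x[tr_idx, sel$retained, drop = FALSE]
    gs <- grid_search_svm(x_tr, y_tr, grid, folds, seed, fold_ids = fold_ids)
    spec <- gs$best
    spec$seed <- seed
    per_fold <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- fold_ids != f
      m <- train(x_tr[tr, , drop = FALSE], y_tr[tr], spec)
      pr <- predict(m, x_tr[!tr, , drop = FALSE], cutoff = cutoff)
      per_fold[[f]] <- compute_metrics(y_tr[!tr], pr$score, cutoff)
    }
    cv_tab <- fold_metric_table(per_fold)
    model <- train(x_tr, y_tr, spec)
    pr_te <- predict(model, fm$x[te_idx, , drop = FALSE], cutoff = cutoff)
    held <- compute_metrics(labels_all[te_idx], pr_te$score, cutoff)
    res[[mode]] <- list(mode = mode,
                        n_features = ncol(fm$x),
                        n_selected = length(sel$retained),
                        best_spec = spec,
                        cv_table = cv_tab,
                        cv = metric_mean_sd(cv_tab),
                        heldout = held,
                        heldout_scores = pr_te,
                        model = model,
                        grid_table = gs$table)
  }
  comparisons <- list()
  if ("proposed" %in% modes) {
    for (mode in setdiff(modes, "proposed")) {
      comparisons[[mode]] <- lapply(
        c("precision", "recall", "f1", "auc"), function(m) {
          a <- res[["proposed"]]$cv_table[[m]]
          b <- res[[mode]]$cv_table[[m]]
          if (stats::sd(a - b) == 0) {
            list(metric = m, p_value = if (all(a == b)) 1 else 0)
          } else {
            list(metric = m,
                 p_value = stats::t.test(a, b, paired = TRUE)$p.value)
          }
        })
      names(comparisons[[mode]]) <- c("precision", "recall", "f1", "auc")
    }
  }
  structure(list(modes = res, comparisons = comparisons,
                 split = split, counts = prepared$counts,
                 config = list(ratio = ratio, folds = folds,
                               fraction = fraction, grid = grid,
                               cutoff = cutoff, seed = seed, cap = cap,
                               min_days = min_days)),
            class = "experiment_report")
}

#' Serialize an experiment report to plain lists (JSON-ready)
#'
#' Strips model handles so the result is a pure data structure; two runs
#' with identical seeds serialize identically.
#'
#' @param report an `experiment_report`.
#' @return a nested list.
#' @export
report_to_list <- function(report) {
  modes <- lapply(report$modes, function(m) {
    list(mode = m$mode,
         n_features = m$n_features,
         n_selected = m$n_selected,
         best_spec = list(kernel = m$best_spec$kernel, C = m$best_spec$C,
                          gamma = m$best_spec$gamma),
         cv = lapply(m$cv, function(v) list(mean = unname(v["mean"]),
                                            sd = unname(v["sd"]))),
         cv_table = m$cv_table,
         heldout = unclass(m$heldout))
  })
  comparisons <- lapply(report$comparisons, function(cmp)
    lapply(cmp, function(x) x$p_value))
  list(modes = modes, comparisons = comparisons,
       counts = report$counts, config = report$config,
       split = report$split)
}

#' Render an experiment report as a Markdown table
#'
#' One table for the cross-validation phase (mean (SD)) and one for the
#' held-out phase.
#'
#' @param report an `experiment_report`.
#' @return character vector of Markdown lines.
#' @export
render_report_markdown <- function(report) {
  fmt2 <- function(x) sprintf("%.2f", x)
  lines <- c("## Cross-validation results", "",
             "| Method (features) | P (SD) | R (SD) | F (SD) | AUC (SD) |",
             "|---|---|---|---|---|")
  for (m in report$modes) {
    cv <- m$cv
    cell <- function(s) sprintf("%s (%s)", fmt2(cv[[s]]["mean"]),
                                fmt2(cv[[s]]["sd"]))
    lines <- c(lines, sprintf("| %s (%d) | %s | %s | %s | %s |",
                              m$mode, m$n_features, cell("precision"),
                              cell("recall"), cell("f1"), cell("auc")))
  }
  lines <- c(lines, "", "## Held-out test results", "",
             "| Method (features) | P | R | F | AUC |", "|---|---|---|---|---|")
  for (m in report$modes) {
    h <- m$heldout
    lines <- c(lines, sprintf("| %s (%d) | %s | %s | %s | %s |",
                              m$mode, m$n_features, fmt2(h$precision),
                              fmt2(h$recall), fmt2(h$f1), fmt2(h$auc)))
  }
  lines
}

#' Error analysis of a scored corpus
#'
#' Lists every misclassified patient with its score, qualifying pathology
#' report count and retained positive-concept sentences, reports group mean
#' pathology counts for TP/FP/FN/TN, and the Pearson correlation between
#' pathology count and score within the false negatives.
#'
#' @param records labeled `recurrex_corpus`.
#' @param scores data frame from [predict.recurrex_model()] (`patient_id`,
#'   `score`, `label`).
#' @param prepared output of [prepare_corpus()] (for sentence evidence).
#' @param cutoff probability cutoff.
#' @param min_days pathology-count window.
#' @return list with `listing` (data frame over misclassified patients),
#'   `group_means`, `fn_count_score_correlation`.
#' @export
error_analysis <- function(records, scores, prepared = NULL, cutoff = 0.5,
                           min_days = 120L) {
  ids <- scores$patient_id
  labels <- vapply(ids, function(i) records[[i]]$label, integer(1))
  pred <- as.integer(scores$score >= cutoff)
  pcount <- vapply(ids, function(i)
    count_pathology_reports(records[[i]], min_days), integer(1))
  group <- ifelse(pred == 1 & labels == 1, "TP",
           ifelse(pred == 1 & labels == 0, "FP",
           ifelse(pred == 0 & labels == 1, "FN", "TN")))
  evidence <- function(id) {
    if (is.null(prepared)) return(NA_character_)
    m <- prepared$mentions_positive
    m <- m[m$patient_id == id, , drop = FALSE]
    if (nrow(m) == 0L) return("")
    s <- prepared$sentences
    key <- paste(s$patient_id, s$note_id, s$index)
    mk <- unique(paste(m$patient_id, m$note_id, m$index))
    paste(s$text[key %in% mk], collapse = " | ")
  }
  mis <- which(pred != labels)
  listing <- data.frame(
    patient_id = ids[mis],
    group = group[mis],
    score = scores$score[mis],
    pathology_count = pcount[mis],
    evidence = vapply(ids[mis], evidence, character(1)),
    stringsAsFactors = FALSE)
  group_means <- vapply(c("TP", "FP", "FN", "TN"), function(g) {
    if (any(group == g)) mean(pcount[group == g]) else NA_real_
  }, numeric(1))
  fn <- group == "FN"
  fn_cor <- if (sum(fn) >= 2 && stats::sd(pcount[fn]) > 0 &&
                stats::sd(scores$score[fn]) > 0) {
    stats::cor(pcount[fn], scores$score[fn])
  } else NA_real_
  list(listing = listing, group_means = group_means,
       fn_count_score_correlation = fn_cor)
}
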