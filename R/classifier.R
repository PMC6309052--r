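## classifier: chi-square feature selection + SVM with grid search -----------

#' Chi-square statistic of a binary feature against a binary label
#'
#' Pearson chi-square (no continuity correction) on the 2x2 contingency of
#' presence vs label. Degenerate tables (a zero margin) score 0.
#'
#' @param x numeric/logical vector; nonzero = present.
#' @param y binary labels.
#' @return the chi-square statistic.
#' @export
chi2_stat <- function(x, y) {
  x <- as.integer(x != 0)
  y <- as.integer(y)
  n <- length(x)
  n1x <- sum(x); n1y <- sum(y)
  o11 <- sum(x == 1 & y == 1)
  obs <- c(o11, n1x - o11, n1y - o11, n - n1x - n1y + o11)
  rx <- c(n1x, n1x, n - n1x, n - n1x)
  ry <- c(n1y, n - n1y, n1y, n - n1y)
  e <- rx * ry / n
  if (any(e == 0)) return(0)
  sum((obs - e)^2 / e)
}

#' Select the top fraction of features by chi-square score
#'
#' Binary candidate columns are ranked by [chi2_stat()] against the label
#' (descending, ties broken by key order) and the top `ceil(fraction * N)`
#' retained. The pathology-count column is exempt from ranking and always
#' retained when present: the statistic assumes categorical presence data,
#' and the count is the single continuous feature.
#'
#' @param fm a `feature_matrix`.
#' @param labels binary labels aligned with `fm$patient_ids`.
#' @param fraction retained proportion, in (0, 1].
#' @return object of class `selection_result`: `retained` (ordered keys),
#'   `scores` (named vector over candidates), `fraction`.
#' @export
chi_square_select <- function(fm, labels, fraction = 0.5) {
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  candidates <- fm$keys$key[fm$keys$kind != "pathology_count"]
  scores <- vapply(candidates,
                   function(k) chi2_stat(fm$x[, k], labels), numeric(1))
  ord <- order(-scores)              # stable: ties keep key (column) order
  k <- ceiling(fraction * length(candidates))
  retained <- candidates[ord][seq_len(min(k, length(candidates)))]
  if (PATHOLOGY_KEY %in% fm$keys$key) {
    retained <- c(retained, PATHOLOGY_KEY)
  }
  structure(list(retained = retained,
                 scores = stats::setNames(scores, candidates),
                 fraction = fraction),
            class = "selection_result")
}

#' The study's SVM hyperparameter grid
#'
#' Four kernels; C from 1 to 100 in steps of 10 (1, 11, ..., 91); gamma
#' from 0.0001 to 0.01 in steps of 0.001 (0.0001, 0.0011, ..., 0.0091).
#' Endpoints beyond the last full step are not added; the reading is
#' recorded here so it can be overridden.
#'
#' @return list with `kernels`, `C`, `gamma`.
#' @export
default_grid <- function() {
  list(kernels = c("rbf", "linear", "poly", "sigmoid"),
       C = seq(1, 91, by = 10),
       gamma = seq(0.0001, 0.0091, by = 0.001))
}

#' A reduced grid for quick experiments
#'
#' Two kernels by three C by three gamma values, all drawn from the full
#' grid.
#'
#' @return list with `kernels`, `C`, `gamma`.
#' @export
reduced_grid <- function() {
  list(kernels = c("rbf", "linear"),
       C = c(1, 41, 91),
       gamma = c(0.0001, 0.0041, 0.0091))
}

#' Construct a model specification
#' @param kernel one of `"rbf"`, `"linear"`, `"poly"`, `"sigmoid"`.
#' @param C positive cost parameter.
#' @param gamma positive kernel width (ignored by the linear kernel).
#' @param seed integer seed used by calibration fold assignment.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(kernel, C, gamma = 0.0001, seed = 0L) {
  kernel <- match.arg(kernel, c("rbf", "linear", "poly", "sigmoid"))
  stopifnot(C > 0, gamma > 0)
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 seed = as.integer(seed)), class = "model_spec")
}

KERNEL_ORDER <- c(rbf = 1L, linear = 2L, poly = 3L, sigmoid = 4L)

e1071_kernel <- function(kernel) {
  c(rbf = "radial", linear = "linear", poly = "polynomial",
    sigmoid = "sigmoid")[[kernel]]
}

#' Micro-averaged F1 score
#'
#' Pooled over both classes of a binary single-label task; numerically
#' equal to accuracy in that setting, implemented literally from the pooled
#' confusion counts.
#'
#' @param pred,truth binary vectors.
#' @return micro-averaged F1 in `[0, 1]`.
#' @export
micro_f1 <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  tp_pooled <- sum(pred == truth)               # per-class TPs summed
  fp_pooled <- sum(pred != truth)               # each error is FP + FN once
  fn_pooled <- fp_pooled
  p <- tp_pooled / (tp_pooled + fp_pooled)
  r <- tp_pooled / (tp_pooled + fn_pooled)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Stratified cross-validation fold assignment
#'
#' @param labels binary labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold ids in `1..k`, one per sample.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 0L) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  set.seed(seed)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

scale_pathology <- function(x, center, scale) {
  if (PATHOLOGY_KEY %in% colnames(x)) {
    x[, PATHOLOGY_KEY] <- (x[, PATHOLOGY_KEY] - center) / scale
  }
  x
}

pathology_scaling <- function(x) {
  if (!(PATHOLOGY_KEY %in% colnames(x))) {
    return(list(center = 0, scale = 1))
  }
  v <- x[, PATHOLOGY_KEY]
  s <- stats::sd(v)
  list(center = mean(v), scale = if (is.na(s) || s == 0) 1 else s)
}

fit_raw_svm <- function(x, y, spec) {
  e1071::svm(x = x, y = factor(y, levels = c(0L, 1L)),
             kernel = e1071_kernel(spec$kernel),
             cost = spec$C, gamma = spec$gamma, scale = FALSE)
}

decision_values <- function(fit, x) {
  p <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")[, 1]
  ## orient so larger = class "1"
  if (colnames(attr(p, "decision.values"))[1] == "0/1") dv <- -dv
  unname(dv)
}

## Platt sigmoid fit: p(y=1|d) = 1/(1+exp(A*d+B)), Platt-smoothed targets,
## cross-entropy minimized with optim (deterministic).
platt_fit <- function(d, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    z <- par[1] * d + par[2]
    ## stable log(1+exp(z)) and cross-entropy
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(t * lse + (1 - t) * (lse - z))
  }
  fit <- stats::optim(c(A = -1, B = 0), nll, method = "BFGS",
                      control = list(maxit = 200))
  fit$par
}

platt_prob <- function(par, d) {
  1 / (1 + exp(par[1] * d + par[2]))
}

#' Grid-search SVM hyperparameters by cross-validated micro-F1
#'
#' Stratified k-fold cross-validation over the full Cartesian grid (gamma
#' collapsed for the linear kernel). The best mean micro-averaged F1 wins;
#' ties prefer smaller C, then smaller gamma, then kernel order rbf <
#' linear < poly < sigmoid. Deterministic given the seed (or a supplied
#' fold assignment).
#'
#' @param x numeric feature matrix (selection already applied).
#' @param labels binary labels.
#' @param grid list with `kernels`, `C`, `gamma`.
#' @param folds number of CV folds.
#' @param seed RNG seed for fold assignment.
#' @param fold_ids optional precomputed fold assignment (overrides
#'   `folds`/`seed`).
#' @return list with `best` (a [model_spec()]) and `table` (per-config mean
#'   CV micro-F1).
#' @export
grid_search_svm <- function(x, labels, grid = default_grid(), folds = 5L,
                            seed = 0L, fold_ids = NULL) {
  labels <- as.integer(labels)
  if (min(table(labels)) < folds) {
    stop("need at least `folds` samples per class", call. = FALSE)
  }
  if (is.null(fold_ids)) fold_ids <- stratified_folds(labels, folds, seed)
  k <- max(fold_ids)
  for (f in seq_len(k)) {
    if (length(unique(labels[fold_ids != f])) < 2L) {
      stop("degenerate training data in fold ", f, call. = FALSE)
    }
  }
  configs <- list()
  for (kern in grid$kernels) {
    gs <- if (kern == "linear") grid$gamma[1] else grid$gamma
    for (C in grid$C) for (g in gs) {
      configs[[length(configs) + 1L]] <- model_spec(kern, C, g, seed)
    }
  }
  scores <- numeric(length(configs))
  for (ci in seq_along(configs)) {
    spec <- configs[[ci]]
    f1 <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold_ids != f
      fit <- fit_raw_svm(x[tr, , drop = FALSE], labels[tr], spec)
      pred <- as.integer(as.character(
        stats::predict(fit, x[!tr, , drop = FALSE])))
      f1[f] <- micro_f1(pred, labels[!tr])
    }
    scores[ci] <- mean(f1)
  }
  tab <- data.frame(
    kernel = vapply(configs, `[[`, character(1), "kernel"),
    C = vapply(configs, `[[`, numeric(1), "C"),
    gamma = vapply(configs, `[[`, numeric(1), "gamma"),
    cv_micro_f1 = scores, stringsAsFactors = FALSE)
  ord <- order(-tab$cv_micro_f1, tab$C, tab$gamma, KERNEL_ORDER[tab$kernel])
  best <- configs[[ord[1]]]
  list(best = best, table = tab)
}

#' Train a calibrated SVM classifier
#'
#' Applies the feature selection, standardizes the pathology-count column
#' (training mean/SD), fits the SVM, and fits a Platt sigmoid on
#' out-of-fold decision values from an internal stratified CV so predicted
#' probabilities are calibrated within training folds. Deterministic given
#' the seed.
#'
#' @param fm a `feature_matrix` (or plain matrix with column names).
#' @param labels binary labels.
#' @param spec a [model_spec()].
#' @param selection optional `selection_result`; when supplied only its
#'   retained keys are used.
#' @param calibration_folds folds for the Platt fit (default 5).
#' @return object of class `recurrex_model`.
#' @export
train <- function(fm, labels, spec, selection = NULL,
                  calibration_folds = 5L) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else fm
  if (nrow(x) == 0L || ncol(x) == 0L) {
    stop("empty feature matrix", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  keys <- colnames(x)
  if (!is.null(selection)) {
    keys <- selection$retained
    x <- x[, keys, drop = FALSE]
  }
  scaling <- pathology_scaling(x)
  xs <- scale_pathology(x, scaling$center, scaling$scale)
  fit <- fit_raw_svm(xs, labels, spec)
  cal_k <- min(calibration_folds, min(table(labels)))
  d_oof <- numeric(length(labels))
  if (cal_k >= 2L) {
    cf <- stratified_folds(labels, cal_k, spec$seed + 1L)
    for (f in seq_len(cal_k)) {
      tr <- cf != f
      ffit <- fit_raw_svm(xs[tr, , drop = FALSE], labels[tr], spec)
      d_oof[!tr] <- decision_values(ffit, xs[!tr, , drop = FALSE])
    }
  } else {
    d_oof <- decision_values(fit, xs)
  }
  platt <- platt_fit(d_oof, labels)
  structure(list(spec = spec, keys = keys, selection = selection,
                 scaling = scaling, svm = fit, platt = platt),
            class = "recurrex_model")
}

align_features <- function(x, keys) {
  out <- matrix(0, nrow = nrow(x), ncol = length(keys),
                dimnames = list(rownames(x), keys))
  common <- intersect(colnames(x), keys)
  out[, common] <- x[, common, drop = FALSE]
  out
}

#' Predict recurrence probabilities and labels
#'
#' Missing feature columns in the new data are treated as 0. The label is
#' positive when the calibrated probability is at least `cutoff` (>=
#' convention, so a score of exactly 0.5 is positive at the default).
#'
#' @param object a `recurrex_model`.
#' @param newdata a `feature_matrix` or plain matrix with column names.
#' @param cutoff probability cutoff (default 0.5).
#' @param ... unused.
#' @return data frame with `patient_id`, `score`, `label`.
#' @export
predict.recurrex_model <- function(object, newdata, cutoff = 0.5, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else newdata
  ids <- if (inherits(newdata, "feature_matrix")) newdata$patient_ids
         else rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  x <- align_features(x, object$keys)
  x <- scale_pathology(x, object$scaling$center, object$scaling$scale)
  d <- decision_values(object$svm, x)
  p <- platt_prob(object$platt, d)
  data.frame(patient_id = ids, score = unname(p),
             label = as.integer(p >= cutoff), stringsAsFactors = FALSE)
}

#' Per-feature weights of a linear-kernel model
#'
#' Primal weight vector `w = sum_i alpha_i y_i x_i`, oriented so positive
#' weights indicate the recurrence class; used for the feature study.
#'
#' @param model a `recurrex_model` with `kernel == "linear"`.
#' @return named numeric vector over the model's feature keys.
#' @export
svm_coefficients <- function(model) {
  if (model$spec$kernel != "linear") {
    stop("coefficients are defined for the linear kernel", call. = FALSE)
  }
  w <- drop(crossprod(model$svm$coefs, model$svm$SV))
  ## libsvm orients decision values toward its first internal class
  first_class <- model$svm$levels[model$svm$labels[1]]
  if (first_class == "0") w <- -w
  stats::setNames(as.numeric(w), model$keys)
}

#' Save / load a fitted model bundle
#' @param model a `recurrex_model`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "recurrex_model"))
  m
}
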