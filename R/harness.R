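#' Leave-one-out cross-validation fold plan
#'
#' One fold per subject: fold `i` trains on the other `n - 1` subjects and
#' tests on subject `i` alone, so the test sets partition the cohort.
#'
#' @param subject_ids vector of unique subject identifiers (length >= 2).
#' @return List of `n` folds, each `list(fold, test_index, train_index,
#'   test_id)`.
#' @export
make_loocv_folds <- function(subject_ids) {
  n <- length(subject_ids)
  if (n < 2L) stop("leave-one-out needs at least 2 subjects", call. = FALSE)
  if (anyDuplicated(subject_ids)) {
    stop("subject ids must be unique", call. = FALSE)
  }
  lapply(seq_len(n), function(i) {
    list(fold = i, test_index = i, train_index = setdiff(seq_len(n), i),
         test_id = subject_ids[i])
  })
}

#' Map cohort group labels to a classification task
#'
#' `diagnosis` is control vs glaucoma (any glaucoma group counts as
#' glaucoma; the positive class), `type` is NTG vs POAG (positive POAG),
#' `severity` is the four ordered levels control / mild / moderate / severe.
#'
#' @param table cohort feature table with a `group` (or `label`) column.
#' @param task `"diagnosis"`, `"type"` or `"severity"`.
#' @return Factor of task labels, positive / reference coding documented
#'   above.
#' @export
task_labels <- function(table, task = c("diagnosis", "type", "severity")) {
  task <- match.arg(task)
  g <- as.character(table$group %||% table$label)
  switch(task,
    diagnosis = factor(ifelse(g == "control", "control", "glaucoma"),
                       levels = c("control", "glaucoma")),
    type = {
      if (!all(g %in% c("POAG", "NTG"))) {
        stop("`type` task requires POAG / NTG group labels", call. = FALSE)
      }
      factor(g, levels = c("NTG", "POAG"))
    },
    severity = {
      if (!all(g %in% c("control", "mild", "moderate", "severe"))) {
        stop("`severity` task requires control/mild/moderate/severe groups",
             call. = FALSE)
      }
      factor(g, levels = c("control", "mild", "moderate", "severe"))
    })
}

#' Univariate feature ranking by p-value
#'
#' Each feature is tested against the class labels — Mann-Whitney for binary
#' tasks, Kruskal-Wallis for multiclass — and features are ranked by
#' ascending p-value. Ties (including constant features, which get p = 1 by
#' convention) are broken by the fixed canonical feature order (layer-major,
#' sector-minor), so the ranking is deterministic. Top-k selection is simply
#' the first k rows.
#'
#' @param table data.frame holding the feature columns.
#' @param labels factor of class labels (2 or more levels).
#' @param features character vector of feature column names to rank;
#'   defaults to the 42 canonical VIM columns present in `table`.
#' @return data.frame `(feature, p_value, rank)` sorted by rank.
#' @export
rank_features_univariate <- function(table, labels,
                                     features = intersect(feature_columns(),
                                                          names(table))) {
  stopifnot(length(features) > 0)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L || min(table(labels)) < 2L) {
    stop("need >= 2 samples in each of >= 2 classes", call. = FALSE)
  }
  p <- vapply(features, function(f) {
    x <- table[[f]]
    if (length(unique(x)) == 1L) return(1)
    if (nlevels(labels) == 2L) {
      mann_whitney(x[labels == levels(labels)[1]],
                   x[labels == levels(labels)[2]])$p_value
    } else {
      kruskal_wallis(split(x, labels))$p_value
    }
  }, numeric(1))
  ord <- order(p)  # stable: ties keep canonical feature order
  data.frame(feature = features[ord], p_value = unname(p[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

# Stratified k-fold assignment. Degrades to the largest feasible fold count
# (>= 2) with a warning when the rarest class is smaller than k.
stratified_fold_ids <- function(y, k = 5L, seed = 1L) {
  with_seed(seed, {
    counts <- table(y)
    k_eff <- min(k, max(2L, min(counts)))
    if (min(counts) < 2L) {
      warning("a class has < 2 members; falling back to unstratified 2-fold",
              call. = FALSE)
      return(list(ids = sample(rep_len(1:2, length(y))), k = 2L))
    }
    if (k_eff < k) {
      warning("rarest class smaller than ", k, " members; using ", k_eff,
              "-fold stratified CV", call. = FALSE)
    }
    ids <- integer(length(y))
    for (lv in levels(y)) {
      w <- which(y == lv)
      ids[w] <- sample(rep_len(seq_len(k_eff), length(w)))
    }
    list(ids = ids, k = k_eff)
  })
}

#' Inner grid-search hyperparameter tuning
#'
#' Exhaustive search over a hyperparameter grid, scored by stratified 5-fold
#' cross-validated accuracy on the training split, followed by a refit of
#' the winning configuration on the full training split. Ties keep the first
#' grid row, so the choice is deterministic for a fixed seed.
#'
#' @param X numeric matrix of training features (top-k selection, if any,
#'   must already be applied).
#' @param y factor of training labels (multiclass handled one-versus-all).
#' @param model `"svm"`, `"rf"` or `"xgb"`.
#' @param grid data.frame of configurations; defaults to the full reference grid of
#'   [default_grid()].
#' @param n_folds inner fold count (default 5).
#' @param seed integer seed driving fold assignment and stochastic fits.
#' @return `list(fit, best_params, inner_accuracy, cv_accuracy)`.
#' @export
tune_hyperparameters <- function(X, y, model = c("svm", "rf", "xgb"),
                                 grid = NULL, n_folds = 5L, seed = 1L) {
  model <- match.arg(model)
  grid <- grid %||% default_grid(model)
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  fold <- stratified_fold_ids(y, n_folds, derive_seed(seed, "innerfolds"))
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    hits <- 0L
    for (f in seq_len(fold$k)) {
      tr <- fold$ids != f
      fit <- fit_any(model, X[tr, , drop = FALSE], y[tr], params,
                     seed = derive_seed(seed, paste0("cfg", gi, "f", f)))
      pred <- predict_any(fit, X[!tr, , drop = FALSE])
      hits <- hits + sum(pred == y[!tr])
    }
    acc[gi] <- hits / length(y)
  }
  best <- which.max(acc)  # first grid row on ties
  params <- as.list(grid[best, , drop = FALSE])
  fit <- fit_any(model, X, y, params, seed = derive_seed(seed, "refit"))
  list(fit = fit, best_params = params, inner_accuracy = acc[best],
       cv_accuracy = acc)
}

#' Nested leave-one-out evaluation of one classification task
#'
#' Outer leave-one-out cross-validation around inner stratified 5-fold grid
#' search. With `feature_set = "selected"`, features are ranked on each
#' outer training split by univariate p-value and an accuracy-versus-k curve
#' is computed over the outer folds for every candidate k; the reported k is
#' the (smallest) argmax of that curve, exactly the protocol of the source
#' method — note this k choice uses the outer test predictions and is
#' therefore optimistically biased, which is flagged in the result. With
#' `feature_set = "all"` the full 42-feature set is used; a single feature
#' name (aliases `"S-IT"` for `superficial_IT` and `"RNFL"` for `rnfl_um`)
#' gives the single-feature reference models. Multiclass tasks are handled
#' one-versus-all. All stochastic components derive their streams from one
#' master seed.
#'
#' @param table cohort feature table ([generate_cohort_feature_table()]
#'   schema).
#' @param task `"diagnosis"`, `"type"` or `"severity"`.
#' @param model `"svm"`, `"rf"` or `"xgb"`.
#' @param grid hyperparameter grid (defaults to the full reference grid — reduce it
#'   for desk-scale runs).
#' @param feature_set `"all"`, `"selected"`, or one feature name.
#' @param k_grid candidate numbers of selected features (default 1..42).
#' @param inner_folds inner CV fold count.
#' @param seed master seed.
#' @return A `nested_cv_result`: truth/prediction/score per subject, the
#'   accuracy-versus-k curve and chosen k (selected mode), per-fold selected
#'   features and winning hyperparameters.
#' @export
run_nested_evaluation <- function(table,
                                  task = c("diagnosis", "type", "severity"),
                                  model = c("svm", "rf", "xgb"),
                                  grid = NULL, feature_set = "all",
                                  k_grid = NULL, inner_folds = 5L,
                                  seed = 1L) {
  task <- match.arg(task)
  model <- match.arg(model)
  grid <- grid %||% default_grid(model)
  y <- task_labels(table, task)
  feats_all <- intersect(feature_columns(), names(table))
  alias <- c("S-IT" = "superficial_IT", "RNFL" = "rnfl_um")
  if (feature_set %in% names(alias)) feature_set <- alias[[feature_set]]
  single <- !feature_set %in% c("all", "selected")
  if (single && !feature_set %in% names(table)) {
    stop("unknown feature: ", feature_set, call. = FALSE)
  }
  n <- nrow(table)
  folds <- make_loocv_folds(table$subject_id %||% seq_len(n))
  lev <- levels(y)
  multi <- length(lev) > 2L

  preds <- rep(NA_character_, n)
  scores <- if (multi) {
    matrix(NA_real_, n, length(lev), dimnames = list(NULL, lev))
  } else {
    rep(NA_real_, n)
  }
  per_fold <- vector("list", n)
  by_k <- NULL
  chosen_k <- NA_integer_

  if (feature_set == "selected") {
    k_grid <- k_grid %||% seq_along(feats_all)
    pred_k <- array(NA_character_, c(n, length(k_grid)))
    fold_store <- vector("list", n)
    for (fd in folds) {
      i <- fd$fold
      tr <- fd$train_index
      fseed <- derive_seed(seed, paste0("fold", i))
      ranking <- rank_features_univariate(table[tr, , drop = FALSE], y[tr],
                                          features = feats_all)
      store <- list(ranking = ranking, tunes = vector("list", length(k_grid)))
      for (ki in seq_along(k_grid)) {
        top <- ranking$feature[seq_len(k_grid[ki])]
        tune <- tune_hyperparameters(table[tr, top, drop = FALSE], y[tr],
                                     model, grid, inner_folds,
                                     seed = derive_seed(fseed, paste0("k", ki)))
        Xte <- as.matrix(table[fd$test_index, top, drop = FALSE])
        pred_k[i, ki] <- as.character(predict_any(tune$fit, Xte))
        store$tunes[[ki]] <- tune
      }
      fold_store[[i]] <- store
    }
    acc_k <- colMeans(pred_k == as.character(y))
    by_k <- data.frame(k = k_grid, accuracy = acc_k)
    chosen_k <- k_grid[which.max(acc_k)]  # smallest k on ties
    ki <- match(chosen_k, k_grid)
    for (fd in folds) {
      i <- fd$fold
      store <- fold_store[[i]]
      top <- store$ranking$feature[seq_len(chosen_k)]
      tune <- store$tunes[[ki]]
      Xte <- as.matrix(table[fd$test_index, top, drop = FALSE])
      preds[i] <- as.character(predict_any(tune$fit, Xte))
      if (multi) scores[i, ] <- ova_scores(tune$fit, Xte)
      else scores[i] <- predict_score(tune$fit, Xte)
      per_fold[[i]] <- list(features = top, params = tune$best_params,
                            inner_accuracy = tune$inner_accuracy)
    }
  } else {
    feats <- if (single) feature_set else feats_all
    for (fd in folds) {
      i <- fd$fold
      tr <- fd$train_index
      tune <- tune_hyperparameters(table[tr, feats, drop = FALSE], y[tr],
                                   model, grid, inner_folds,
                                   seed = derive_seed(seed, paste0("fold", i)))
      Xte <- as.matrix(table[fd$test_index, feats, drop = FALSE])
      preds[i] <- as.character(predict_any(tune$fit, Xte))
      if (multi) scores[i, ] <- ova_scores(tune$fit, Xte)
      else scores[i] <- predict_score(tune$fit, Xte)
      per_fold[[i]] <- list(features = feats, params = tune$best_params,
                            inner_accuracy = tune$inner_accuracy)
    }
  }

  structure(list(task = task, model = model, feature_set = feature_set,
                 truth = y, predictions = factor(preds, levels = lev),
                 scores = scores, accuracy_by_k = by_k, chosen_k = chosen_k,
                 per_fold = per_fold, n_folds = n, seed = seed,
                 k_bias_note = paste("k chosen on the outer test curve;",
                                     "accuracy at the chosen k is",
                                     "optimistically biased")),
            class = "nested_cv_result")
}

#' Binary classification metrics with stratified bootstrap CIs
#'
#' AUROC (over decision scores), accuracy, sensitivity (recall of the
#' positive class — the second factor level) and specificity, each with a
#' 95 percent stratified-bootstrap percentile interval.
#'
#' @param result a binary `nested_cv_result`, or omit and pass `truth`,
#'   `pred`, `score` directly.
#' @param truth,pred factors; `score` numeric decision scores.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return A `metrics_report` data.frame: metric, point estimate, CI bounds.
#' @export
score_binary <- function(result = NULL, truth = result$truth,
                         pred = result$predictions, score = result$scores,
                         n_boot = 1000L, seed = 1L) {
  truth <- droplevels(as.factor(truth))
  stopifnot(nlevels(truth) == 2L)
  pos <- levels(truth)[2]
  pred <- factor(as.character(pred), levels = levels(truth))
  point <- c(auroc = auroc(score, truth == pos),
             accuracy = mean(pred == truth),
             sensitivity = mean(pred[truth == pos] == pos),
             specificity = mean(pred[truth != pos] != pos))
  ci <- rbind(
    stratified_bootstrap_ci(function(l, s) auroc(s, l == pos), truth, score,
                            n_boot, derive_seed(seed, "auroc")),
    stratified_bootstrap_ci(function(l, p) mean(p == l), truth, pred,
                            n_boot, derive_seed(seed, "acc")),
    stratified_bootstrap_ci(function(l, p) mean(p[l == pos] == pos), truth,
                            pred, n_boot, derive_seed(seed, "sens")),
    stratified_bootstrap_ci(function(l, p) mean(p[l != pos] != pos), truth,
                            pred, n_boot, derive_seed(seed, "spec")))
  structure(data.frame(metric = names(point), estimate = unname(point),
                       ci_low = ci[, 1], ci_high = ci[, 2],
                       row.names = NULL),
            class = c("metrics_report", "data.frame"),
            n = length(truth), positive = pos)
}

#' Multiclass (micro-averaged) metrics with stratified bootstrap CIs
#'
#' Micro-averaged AUROC pools the one-versus-all binarized (label, score)
#' pairs of every class into a single ROC; micro-averaged sensitivity equals
#' overall accuracy (each subject contributes exactly one true-positive
#' opportunity — an algebraic identity, reported as such); micro-averaged
#' specificity pools the per-class true negatives. The confusion matrix has
#' one row per true class.
#'
#' @param result a multiclass `nested_cv_result`, or pass `truth`, `pred`,
#'   `scores` (score matrix, one column per class) directly.
#' @inheritParams score_binary
#' @param scores numeric matrix of per-class scores.
#' @return A `metrics_report` with the confusion matrix attached as
#'   attribute `confusion`.
#' @export
score_multiclass <- function(result = NULL, truth = result$truth,
                             pred = result$predictions,
                             scores = result$scores, n_boot = 1000L,
                             seed = 1L) {
  truth <- as.factor(truth)
  lev <- levels(truth)
  pred <- factor(as.character(pred), levels = lev)
  if (!all(lev %in% unique(as.character(pred)))) {
    warning("some classes never predicted; metrics still computed",
            call. = FALSE)
  }
  micro_auroc <- function(l, s) {
    lab <- as.vector(vapply(lev, function(cl) l == cl, logical(length(l))))
    auroc(as.vector(s[, lev]), lab)
  }
  micro_spec <- function(l, p) {
    tn <- fp <- 0
    for (cl in lev) {
      tn <- tn + sum(p != cl & l != cl)
      fp <- fp + sum(p == cl & l != cl)
    }
    tn / (tn + fp)
  }
  acc <- mean(pred == truth)
  point <- c(auroc = if (is.null(scores)) NA_real_ else micro_auroc(truth, scores),
             accuracy = acc,
             sensitivity = acc,  # micro-averaged identity
             specificity = micro_spec(truth, pred))
  ci_auroc <- if (is.null(scores)) c(NA_real_, NA_real_) else {
    stratified_bootstrap_ci(micro_auroc, truth, scores, n_boot,
                            derive_seed(seed, "auroc"))
  }
  ci_acc <- stratified_bootstrap_ci(function(l, p) mean(p == l), truth, pred,
                                    n_boot, derive_seed(seed, "acc"))
  ci_spec <- stratified_bootstrap_ci(micro_spec, truth, pred, n_boot,
                                     derive_seed(seed, "spec"))
  cm <- table(truth = truth, predicted = pred)
  structure(data.frame(metric = names(point), estimate = unname(point),
                       ci_low = c(ci_auroc[1], ci_acc[1], ci_acc[1],
                                  ci_spec[1]),
                       ci_high = c(ci_auroc[2], ci_acc[2], ci_acc[2],
                                   ci_spec[2]),
                       row.names = NULL),
            class = c("metrics_report", "data.frame"),
            n = length(truth), confusion = cm)
}
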