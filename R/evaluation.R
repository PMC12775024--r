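#' Train/test split
#'
#' Seeded shuffle with `floor(train_fraction * n)` training samples and the
#' remainder held out. The stratified variant applies the floor rule within
#' each class, preserving the class ratio.
#'
#' @param labels Integer 0/1 label vector (or a list of pairs, from which
#'   labels are taken).
#' @param train_fraction Fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @param stratified Preserve class proportions in both splits.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering all samples).
#' @export
split_train_test <- function(labels, train_fraction = 0.8, seed = 1L,
                             stratified = FALSE) {
  if (is.list(labels))
    labels <- vapply(labels, function(p) p$label, integer(1L))
  n <- length(labels)
  if (n < 2L) stop_input("input error: need at least 2 samples")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_input("configuration error: train_fraction must lie in (0,1)")
  with_seed(seed, {
    if (stratified) {
      train <- integer(0)
      for (cl in sort(unique(labels))) {
        idx <- sample(which(labels == cl))
        train <- c(train, idx[seq_len(floor(train_fraction * length(idx)))])
      }
      train <- sort(train)
    } else {
      perm <- sample.int(n)
      train <- sort(perm[seq_len(floor(train_fraction * n))])
    }
    list(train = train, test = sort(setdiff(seq_len(n), train)))
  })
}

#' Binary confusion matrix
#'
#' Counts with the FAW class (label 0) as the positive/detection target by
#' default.
#'
#' @param y_true,y_pred Equal-length 0/1 label vectors.
#' @param positive_class The label counted as positive (0 = FAW).
#' @return A `confusion_matrix` list with `TP`, `FP`, `FN`, `TN`,
#'   `positive_class`; the four counts sum to `length(y_true)`.
#' @export
confusion <- function(y_true, y_pred, positive_class = 0L) {
  if (length(y_true) != length(y_pred))
    stop_input("input error: label vectors must have equal length")
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L)))
    stop_input("input error: labels must be 0 or 1")
  pos_t <- y_true == positive_class
  pos_p <- y_pred == positive_class
  structure(list(TP = sum(pos_t & pos_p), FP = sum(!pos_t & pos_p),
                 FN = sum(pos_t & !pos_p), TN = sum(!pos_t & !pos_p),
                 positive_class = as.integer(positive_class)),
            class = "confusion_matrix")
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' `accuracy = (TP + TN) / total`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`,
#' `f1 = 2 * precision * recall / (precision + recall)`.
#' Zero denominators yield 0.0 with a warning (common tooling convention).
#'
#' @param cm A [confusion()] result.
#' @return Named list `accuracy`, `precision`, `recall`, `f1`.
#' @export
metrics_from_confusion <- function(cm) {
  total <- cm$TP + cm$FP + cm$FN + cm$TN
  if (total == 0L) stop_input("input error: empty confusion matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0",
              call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- safe_div(cm$TP, cm$TP + cm$FP, "precision")
  recall <- safe_div(cm$TP, cm$TP + cm$FN, "recall")
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(accuracy = (cm$TP + cm$TN) / total,
       precision = precision, recall = recall, f1 = f1)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores (plus infinite sentinels),
#' predicting positive when `score >= threshold`; tied scores move
#' simultaneously (standard staircase), so the trapezoidal AUC equals the
#' normalized Mann-Whitney rank statistic.
#'
#' @param y_true 0/1 labels (both classes required).
#' @param scores Finite numeric scores; larger means more
#'   positive-class-like (for this package, the FAW-class probability).
#' @param positive_class Label counted as positive (0 = FAW).
#' @return List with `roc` — a data frame `threshold,fpr,tpr` ordered by
#'   increasing FPR from (0,0) to (1,1) — and `auc`.
#' @export
roc_auc <- function(y_true, scores, positive_class = 0L) {
  if (length(y_true) != length(scores))
    stop_input("input error: labels and scores must have equal length")
  if (!all(is.finite(scores)))
    stop_input("input error: scores must be finite")
  pos <- y_true == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop_input("undefined-AUC error: both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred_pos <- scores >= thr[i]
    tpr[i] <- sum(pred_pos & pos) / n_pos
    fpr[i] <- sum(pred_pos & !pos) / n_neg
  }
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve
#'
#' One point per unique-score threshold (`score >= threshold` predicts
#' positive), descending thresholds; recall is non-decreasing along the
#' returned curve (equivalently non-increasing as the threshold rises).
#' At the lowest threshold everything is predicted positive, so recall is 1
#' and precision equals the prevalence.
#'
#' @inheritParams roc_auc
#' @return Data frame `threshold,recall,precision`.
#' @export
pr_curve <- function(y_true, scores, positive_class = 0L) {
  if (length(y_true) != length(scores))
    stop_input("input error: labels and scores must have equal length")
  pos <- y_true == positive_class
  if (sum(pos) == 0L || sum(!pos) == 0L)
    stop_input("undefined-AUC error: both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  recall <- precision <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred_pos <- scores >= thr[i]
    tp <- sum(pred_pos & pos)
    recall[i] <- tp / sum(pos)
    precision[i] <- if (sum(pred_pos) > 0) tp / sum(pred_pos) else 1
  }
  data.frame(threshold = thr, recall = recall, precision = precision)
}

#' Full evaluation report
#'
#' Confusion matrix, accuracy/precision/recall/F1 for the positive (FAW)
#' class, macro-averaged precision/recall/F1 over both classes, ROC/AUC and
#' PR curve.
#'
#' @param y_true 0/1 labels.
#' @param y_pred 0/1 predictions.
#' @param scores Optional positive-class scores for the curves (required
#'   for ROC/PR/AUC).
#' @param positive_class Label counted as positive (0 = FAW).
#' @return A `metric_report` list.
#' @export
evaluate_predictions <- function(y_true, y_pred, scores = NULL,
                                 positive_class = 0L) {
  cm <- confusion(y_true, y_pred, positive_class)
  m <- metrics_from_confusion(cm)
  other <- confusion(y_true, y_pred, 1L - positive_class)
  mo <- suppressWarnings(metrics_from_confusion(other))
  rep_ <- list(confusion = cm, accuracy = m$accuracy,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               macro_precision = (m$precision + mo$precision) / 2,
               macro_recall = (m$recall + mo$recall) / 2,
               macro_f1 = (m$f1 + mo$f1) / 2,
               auc = NA_real_, roc = NULL, pr = NULL,
               positive_class = as.integer(positive_class))
  if (!is.null(scores) && length(unique(y_true)) == 2L) {
    ra <- roc_auc(y_true, scores, positive_class)
    rep_$auc <- ra$auc
    rep_$roc <- ra$roc
    rep_$pr <- pr_curve(y_true, scores, positive_class)
  }
  structure(rep_, class = "metric_report")
}

#' Stratified K-fold plan
#'
#' Shuffles each class independently (seeded) and deals its members
#' round-robin across folds, so every sample lands in exactly one test fold
#' and per-fold class counts differ from perfect proportionality by at most
#' one sample per class.
#'
#' @param labels 0/1 labels (or list of pairs).
#' @param k Number of folds (>= 2; every class must have >= k members).
#' @param seed Integer seed.
#' @return List with `k`, `assignments` (fold index per sample) and `folds`
#'   (list of test-index vectors).
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  if (is.list(labels))
    labels <- vapply(labels, function(p) p$label, integer(1L))
  k <- as.integer(k)
  if (k < 2L) stop_input("configuration error: k must be >= 2")
  for (cl in unique(labels))
    if (sum(labels == cl) < k)
      stop_input("configuration error: class ", cl, " has fewer than k = ",
                 k, " members")
  assignments <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      assignments[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds <- lapply(seq_len(k), function(f) which(assignments == f))
  structure(list(k = k, assignments = assignments, folds = folds),
            class = "kfold_plan")
}

#' Stratified K-fold cross-validated training and evaluation
#'
#' Runs `train_fn` on each training fold, predicts the held-out fold with
#' `predict_fn`, computes a [evaluate_predictions()] report per fold, and
#' averages the scalar metrics across folds.
#'
#' @param pairs List of `preprocessed_pair` objects.
#' @param k Number of folds.
#' @param seed Seed for the fold plan (per-fold training seeds derive from
#'   it).
#' @param train_fn `function(train_pairs, fold_seed)` returning a model.
#' @param predict_fn `function(model, test_pairs)` returning a list with
#'   `label` and `score`.
#' @return A `cv_result` list: `k`, `plan`, `per_fold` (metric reports),
#'   `averaged` (mean scalar metrics).
#' @export
cross_validate <- function(pairs, k = 5L, seed = 1L, train_fn, predict_fn) {
  labels <- vapply(pairs, function(p) p$label, integer(1L))
  plan <- stratified_kfold(labels, k, seed)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- plan$folds[[f]]
    train_idx <- setdiff(seq_along(pairs), test_idx)
    model <- train_fn(pairs[train_idx], derive_seed(seed, f))
    pred <- predict_fn(model, pairs[test_idx])
    per_fold[[f]] <- evaluate_predictions(labels[test_idx], pred$label,
                                          pred$score)
  }
  scalar <- c("accuracy", "precision", "recall", "f1", "auc")
  averaged <- lapply(setNames(scalar, scalar), function(m)
    mean(vapply(per_fold, function(r) r[[m]], numeric(1L))))
  structure(list(k = k, plan = plan, per_fold = per_fold,
                 averaged = averaged), class = "cv_result")
}

#' Write an evaluation report to disk
#'
#' JSON scalar metrics (with config echo), CSV curve tables
#' (`threshold,fpr,tpr` and `threshold,recall,precision`) and a labelled
#' 2x2 confusion-matrix CSV.
#'
#' @param report A `metric_report`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, prefix = "eval") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  scal <- report[c("accuracy", "precision", "recall", "f1",
                   "macro_precision", "macro_recall", "macro_f1", "auc",
                   "positive_class")]
  scal$confusion <- report$confusion[c("TP", "FP", "FN", "TN")]
  p <- file.path(dir, paste0(prefix, "_metrics.json"))
  jsonlite::write_json(scal, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  cm <- report$confusion
  cmt <- data.frame(row.names = c("actual_positive", "actual_negative"),
                    predicted_positive = c(cm$TP, cm$FP),
                    predicted_negative = c(cm$FN, cm$TN))
  p <- file.path(dir, paste0(prefix, "_confusion.csv"))
  utils::write.csv(cmt, p)
  paths <- c(paths, p)
  if (!is.null(report$roc)) {
    p <- file.path(dir, paste0(prefix, "_roc.csv"))
    utils::write.csv(report$roc, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$pr)) {
    p <- file.path(dir, paste0(prefix, "_pr.csv"))
    utils::write.csv(report$pr, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
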