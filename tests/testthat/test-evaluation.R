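test_that("train/test split follows the floor rule and is seed-stable", {
  s <- split_train_test(rep(c(0L, 1L), 50L), 0.8, seed = 4L)
  expect_length(s$train, 80L)
  expect_length(s$test, 20L)
  expect_length(intersect(s$train, s$test), 0L)
  expect_setequal(c(s$train, s$test), 1:100)
  # floor on awkward sizes
  s5 <- split_train_test(c(0L, 1L, 0L, 1L, 0L), 0.8, seed = 1L)
  expect_length(s5$train, 4L)
  expect_length(s5$test, 1L)
  # determinism
  expect_identical(split_train_test(rep(0:1, 20L), seed = 9L),
                   split_train_test(rep(0:1, 20L), seed = 9L))
  # stratified variant preserves the class ratio exactly here
  y <- c(rep(0L, 60L), rep(1L, 40L))
  st <- split_train_test(y, 0.8, seed = 2L, stratified = TRUE)
  expect_equal(sum(y[st$train] == 0L), 48L)
  expect_equal(sum(y[st$train] == 1L), 32L)
  expect_error(split_train_test(y, 1.2), "train_fraction")
})

test_that("confusion counts match the hand-enumerated 2x2 table", {
  cm <- confusion(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 0L), positive_class = 0L)
  expect_equal(cm[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  perfect <- confusion(c(0L, 1L, 0L), c(0L, 1L, 0L))
  expect_equal(perfect$FP + perfect$FN, 0L)
  allpos <- confusion(c(0L, 1L, 1L), c(0L, 0L, 0L))
  expect_equal(allpos$TN + allpos$FN, 0L)
  expect_error(confusion(c(0L, 1L), c(0L)), "equal length")
  expect_error(confusion(c(0L, 2L), c(0L, 1L)), "labels")
})

test_that("metrics from counts follow the closed forms with safe conventions", {
  m <- metrics_from_confusion(list(TP = 3L, FP = 1L, FN = 0L, TN = 4L))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 1.0)
  expect_equal(m$accuracy, 0.875)
  expect_equal(m$f1, 6 / 7)
  expect_warning(z <- metrics_from_confusion(list(TP = 0L, FP = 0L, FN = 2L,
                                                  TN = 3L)), "precision")
  expect_equal(z$precision, 0)
  expect_warning(z2 <- metrics_from_confusion(list(TP = 0L, FP = 1L,
                                                   FN = 0L, TN = 3L)),
                 "recall")
  expect_equal(z2$recall, 0)
})

test_that("metrics agree exactly with a brute-force recount on 1000 random sets", {
  withr::with_seed(123L, {
    for (rep in 1:1000) {
      n <- sample(2:40, 1L)
      y <- sample(0:1, n, replace = TRUE)
      p <- sample(0:1, n, replace = TRUE)
      cm <- confusion(y, p)
      got <- suppressWarnings(metrics_from_confusion(cm))
      want <- oracle_metrics(y, p)
      expect_identical(cm$TP, want$TP)
      expect_identical(cm$FP, want$FP)
      expect_identical(cm$FN, want$FN)
      expect_identical(cm$TN, want$TN)
      expect_identical(got$accuracy, want$accuracy)
      expect_identical(got$precision, want$precision)
      expect_identical(got$recall, want$recall)
      expect_identical(got$f1, want$f1)
    }
  })
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic", {
  # perfect, reversed, and random rankings
  y <- c(0L, 0L, 1L, 1L)
  expect_equal(roc_auc(y, c(0.9, 0.8, 0.1, 0.2))$auc, 1.0)
  expect_equal(roc_auc(y, c(0.1, 0.2, 0.9, 0.8))$auc, 0.0)
  # all-distinct scores: equality to the rank statistic within 1e-9
  withr::with_seed(7L, {
    for (rep in 1:50) {
      n <- sample(5:30, 1L)
      y <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
      s <- sample(seq_len(200L), n) / 200
      expect_lt(abs(roc_auc(y, s)$auc - oracle_auc(y, s)), 1e-9)
    }
    # tied scores: simultaneous staircase moves still match Mann-Whitney
    for (rep in 1:20) {
      n <- sample(6:30, 1L)
      y <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
      s <- sample(seq_len(5L), n, replace = TRUE) / 5
      expect_lt(abs(roc_auc(y, s)$auc - oracle_auc(y, s)), 1e-9)
    }
  })
  # independent implementation cross-check (pROC)
  skip_if_not_installed("pROC")
  withr::with_seed(15L, {
    y <- sample(0:1, 100L, replace = TRUE)
    s <- runif(100L)
  })
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = y, predictor = s, levels = c(1, 0), direction = "<")))
  expect_equal(roc_auc(y, s)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("label-independent scores give chance-level AUC on 2000 samples", {
  withr::with_seed(2000L, {
    y <- sample(0:1, 2000L, replace = TRUE)
    s <- runif(2000L)
  })
  auc <- roc_auc(y, s)$auc
  expect_gt(auc, 0.47)
  expect_lt(auc, 0.53)
})

test_that("ROC curve runs from (0,0) to (1,1) with non-decreasing FPR", {
  withr::with_seed(5L, {
    y <- sample(0:1, 50L, replace = TRUE)
    s <- runif(50L)
  })
  roc <- roc_auc(y, s)$roc
  expect_equal(roc$fpr[1L], 0)
  expect_equal(roc$tpr[1L], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_error(roc_auc(rep(0L, 5L), runif(5L)), "undefined-AUC")
})

test_that("PR curve is monotone in recall with the prevalence endpoint", {
  y <- c(0L, 0L, 1L, 1L)
  pr <- pr_curve(y, c(0.9, 0.8, 0.1, 0.2))
  expect_true(any(pr$recall == 1 & pr$precision == 1)) # perfect ranking
  # at the lowest threshold everything is positive
  withr::with_seed(6L, {
    for (rep in 1:20) {
      n <- sample(6:40, 1L)
      y <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
      s <- runif(n)
      pr <- pr_curve(y, s)
      expect_true(all(diff(pr$recall) >= 0)) # descending thresholds
      last <- pr[nrow(pr), ]
      expect_equal(last$recall, 1)
      expect_equal(last$precision, mean(y == 0L))
    }
  })
})

test_that("stratified K-fold balances classes and partitions the data", {
  y <- c(rep(0L, 50L), rep(1L, 50L))
  plan <- stratified_kfold(y, k = 5L, seed = 3L)
  for (f in plan$folds) {
    expect_length(f, 20L)
    expect_equal(sum(y[f] == 0L), 10L)
  }
  expect_setequal(unlist(plan$folds), seq_along(y))
  expect_equal(sum(lengths(plan$folds)), 100L) # no duplicates

  # 52 + 48 with k = 5: per-fold class counts within 1 of proportional
  y2 <- c(rep(0L, 52L), rep(1L, 48L))
  plan2 <- stratified_kfold(y2, k = 5L, seed = 3L)
  for (f in plan2$folds) {
    expect_lte(abs(sum(y2[f] == 0L) - 52 / 5), 1)
    expect_lte(abs(sum(y2[f] == 1L) - 48 / 5), 1)
  }
  expect_error(stratified_kfold(c(0L, 0L, 1L), k = 2L), "fewer than k")
})

test_that("cross-validation averages equal the mean of per-fold metrics", {
  # trivial threshold classifier on mean intensity; the harness is what is
  # under test, not the model
  pairs <- separable_pairs(n = 30L, size = 32L)
  cv <- cross_validate(
    pairs, k = 3L, seed = 8L,
    train_fn = function(train_pairs, fold_seed) {
      mu <- vapply(train_pairs, function(p) mean(p$rgb), numeric(1L))
      y <- vapply(train_pairs, function(p) p$label, integer(1L))
      list(cut = mean(tapply(mu, y, mean)))
    },
    predict_fn = function(model, test_pairs) {
      mu <- vapply(test_pairs, function(p) mean(p$rgb), numeric(1L))
      list(label = as.integer(mu < model$cut), score = mu)
    })
  expect_equal(cv$k, 3L)
  expect_length(cv$per_fold, 3L)
  accs <- vapply(cv$per_fold, `[[`, numeric(1L), "accuracy")
  expect_identical(cv$averaged$accuracy, mean(accs))
  f1s <- vapply(cv$per_fold, `[[`, numeric(1L), "f1")
  expect_identical(cv$averaged$f1, mean(f1s))
})

test_that("evaluation reports write curve tables and a labelled confusion matrix", {
  withr::with_seed(10L, {
    y <- sample(0:1, 40L, replace = TRUE)
    s <- runif(40L)
  })
  rep_ <- evaluate_predictions(y, as.integer(s < 0.5), s)
  d <- tempfile("report_")
  paths <- write_report(rep_, d)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(file.path(d, "eval_metrics.json"))
  expect_equal(js$accuracy, rep_$accuracy)
  cmcsv <- utils::read.csv(file.path(d, "eval_confusion.csv"),
                           row.names = 1L)
  expect_equal(cmcsv["actual_positive", "predicted_positive"],
               rep_$confusion$TP)
})
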