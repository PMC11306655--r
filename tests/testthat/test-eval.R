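test_that("1-NN predictions match an exhaustive distance-scan oracle", {
  set.seed(1)
  train_X <- matrix(rnorm(30 * 4), 30, 4)
  train_y <- sample(c(0L, 1L), 30, replace = TRUE)
  test_X <- matrix(rnorm(12 * 4), 12, 4)
  expect_identical(knn_predict(train_X, train_y, test_X, k = 1L),
                   brute_1nn(train_X, train_y, test_X))
  # coincident test point takes the training point's label
  expect_identical(knn_predict(train_X, train_y, train_X[7, , drop = FALSE]),
                   train_y[7])
  # 1-D textbook case: nearest by |x|
  expect_identical(knn_predict(matrix(c(0, 10)), c(0L, 1L), matrix(c(4, 6))),
                   c(0L, 1L))
})

test_that("kNN tie-breaks are deterministic", {
  # two training points equidistant from the test point, different labels:
  # lower training index wins
  tr <- matrix(c(-1, 1), 2, 1)
  expect_identical(knn_predict(tr, c(1L, 0L), matrix(0)), 1L)
  expect_identical(knn_predict(tr[2:1, , drop = FALSE], c(0L, 1L), matrix(0)),
                   0L)
  # even k with a split vote: nearest neighbor's label wins
  tr2 <- matrix(c(1, -2), 2, 1)
  expect_identical(knn_predict(tr2, c(1L, 0L), matrix(0), k = 2L), 1L)
  expect_error(knn_predict(tr2, c(1L, 0L), matrix(0), k = 3L),
               class = "pdfe_validation_error")
  expect_error(knn_predict(tr2[0, , drop = FALSE], integer(0), matrix(0)),
               class = "pdfe_validation_error")
})

test_that("metric formulas reproduce hand-computed confusions", {
  m <- compute_metrics(confusion_matrix(TP = 159, TN = 165, FP = 0, FN = 0))
  expect_equal(unlist(m), c(accuracy = 100, recall = 100, precision = 100,
                            f1 = 100))
  m2 <- compute_metrics(confusion_matrix(TP = 1, TN = 0, FP = 0, FN = 1))
  expect_equal(m2$recall, 50)
  expect_equal(m2$precision, 100)
  expect_equal(m2$f1, 200 / 3, tolerance = 1e-12)  # 66.67
  expect_equal(m2$accuracy, 50)
})

test_that("undefined ratios come back as NA with a warning, never silent 0", {
  w <- capture_warnings(m <- compute_metrics(confusion_matrix(0, 5, 0, 0)))
  expect_setequal(w, c("recall is undefined (zero denominator)",
                       "precision is undefined (zero denominator)",
                       "f1 is undefined (zero denominator)"))
  expect_true(is.na(m$precision) && is.na(m$recall) && is.na(m$f1))
  expect_equal(m$accuracy, 100)
  expect_warning(m2 <- compute_metrics(confusion_matrix(0, 5, 1, 0)),
                 "recall")
  expect_true(is.na(m2$recall))
  expect_equal(m2$precision, 0)
  expect_error(compute_metrics(confusion_matrix(0, 0, 0, 0)),
               class = "pdfe_validation_error")
  expect_error(confusion_matrix(-1, 0, 0, 2), class = "pdfe_validation_error")
})

test_that("pooled confusion of a constant classifier is forced by the design", {
  always0 <- list(name = "always0",
                  fit = function(X, y) NULL,
                  predict = function(m, X) rep(0L, nrow(X)))
  toy <- toy_classes(n_per = 20L, p = 3L, seed = 4L)
  rep0 <- cross_validate(always0, toy$X, toy$y, folds = 10L, seed = 2L)
  expect_equal(rep0$accuracy, 50)
  expect_equal(rep0$recall, 100)   # positive class = 0 = large occlusion
  expect_equal(rep0$precision, 50)
  expect_equal(rep0$confusion$TP, 20L)
  expect_equal(rep0$confusion$FP, 20L)
})

test_that("a leaked-label feature yields a perfect pooled report", {
  y <- rep(c(0L, 1L), each = 15L)
  X <- matrix(as.numeric(y), ncol = 1)
  rep1 <- cross_validate("kNN", X, y, folds = 5L, seed = 3L)
  expect_equal(rep1$confusion$TP, 15L)
  expect_equal(rep1$confusion$TN, 15L)
  expect_equal(rep1$confusion$FP + rep1$confusion$FN, 0L)
  expect_equal(c(rep1$accuracy, rep1$recall, rep1$precision, rep1$f1),
               rep(100, 4))
})

test_that("cross-validation is deterministic and pools per-fold confusions", {
  toy <- toy_classes(n_per = 20L, p = 5L, d_info = 1L, delta = 2, seed = 6L)
  r1 <- cross_validate("kNN", toy$X, toy$y, folds = 10L, seed = 9L)
  r2 <- cross_validate("kNN", toy$X, toy$y, folds = 10L, seed = 9L)
  expect_identical(r1, r2)
  pooled <- Reduce(function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE),
                   lapply(r1$per_fold_confusion, unclass))
  expect_equal(pooled, unclass(r1$confusion), ignore_attr = TRUE)
  total <- with(r1$confusion, TP + TN + FP + FN)
  expect_equal(total, length(toy$y))
  expect_error(cross_validate("kNN", toy$X, toy$y, folds = 25L),
               class = "pdfe_validation_error")
})

test_that("f1 is the harmonic mean of precision and recall when defined", {
  set.seed(12)
  for (i in 1:20) {
    cm <- confusion_matrix(sample(1:30, 1), sample(1:30, 1),
                           sample(0:10, 1), sample(0:10, 1))
    m <- compute_metrics(cm)
    if (!is.na(m$precision) && !is.na(m$recall) && (m$precision + m$recall) > 0) {
      hm <- 2 * m$precision * m$recall / (m$precision + m$recall)
      expect_equal(m$f1, hm, tolerance = 1e-9)
    }
  }
})

test_that("1-NN resubstitution is perfect without duplicate conflicts", {
  set.seed(13)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- sample(c(0L, 1L), 40, replace = TRUE)
  expect_identical(knn_predict(X, y, X, k = 1L), y)
})

test_that("macro averaging symmetrizes recall and precision", {
  always0 <- list(name = "always0", fit = function(X, y) NULL,
                  predict = function(m, X) rep(0L, nrow(X)))
  toy <- toy_classes(n_per = 15L, p = 3L, seed = 14L)
  suppressWarnings(
    repm <- cross_validate(always0, toy$X, toy$y, folds = 5L, seed = 2L,
                           average = "macro"))
  expect_equal(repm$accuracy, 50)
  # macro recall = mean(100, 0)
  expect_equal(repm$recall, 50)
})
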