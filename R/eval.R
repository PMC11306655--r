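#' Construct a confusion matrix
#'
#' Counts with the large-occlusion class (label 0) as positive by
#' convention; see [cross_validate()] for how predictions are pooled.
#'
#' @param TP,TN,FP,FN Nonnegative counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop_validation("confusion counts must be nonnegative integers")
  structure(as.list(setNames(as.integer(v), names(v))),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, recall, precision and F1 in percent:
#' `accuracy = 100 (TP+TN)/(TP+TN+FP+FN)`, `recall = 100 TP/(TP+FN)`,
#' `precision = 100 TP/(TP+FP)`, `f1 = 100 * 2TP/(2TP+FN+FP)`.
#' A metric with a zero denominator is reported as `NA` with a warning,
#' never silently as 0.
#'
#' @param confusion A `confusion_matrix` (or list with TP, TN, FP, FN).
#' @return Named list `accuracy`, `recall`, `precision`, `f1` (percent).
#' @export
compute_metrics <- function(confusion) {
  cm <- confusion
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  total <- tp + tn + fp + fn
  if (is.null(total) || !is.finite(total) || total <= 0)
    stop_validation("confusion matrix has zero total count")
  ratio <- function(num, den, name) {
    if (den == 0) {
      warning(sprintf("%s is undefined (zero denominator)", name),
              call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  list(accuracy = 100 * (tp + tn) / total,
       recall = ratio(tp, tp + fn, "recall"),
       precision = ratio(tp, tp + fp, "precision"),
       f1 = ratio(2 * tp, 2 * tp + fn + fp, "f1"))
}

pool_confusion <- function(pred, truth, positive = 0L) {
  confusion_matrix(TP = sum(pred == positive & truth == positive),
                   TN = sum(pred != positive & truth != positive),
                   FP = sum(pred == positive & truth != positive),
                   FN = sum(pred != positive & truth == positive))
}

#' Stratified cross-validated evaluation of a classifier
#'
#' Runs stratified `folds`-fold cross-validation with folds fixed by `seed`,
#' pools the per-fold predictions into a single confusion matrix (positive
#' class = large occlusion, label 0) and computes the four metrics from the
#' pooled counts. Feature standardization, when enabled, is fitted on the
#' training folds only.
#'
#' @param classifier_spec A classifier name (one of `"kNN"`, `"DT"`, `"RF"`,
#'   `"LD"`, `"QD"`, `"LR"`, `"NB"`, `"SVM"`, `"MLP"`) or a list with fields
#'   `name`, `fit(X, y)` and `predict(model, X)`.
#' @param X Numeric matrix (n_samples x p) or `feature_matrix`.
#' @param y Binary labels (0/1).
#' @param folds Number of folds (default 10); every class must have at least
#'   `folds` samples.
#' @param seed Integer seed fixing the folds and any stochastic fit.
#' @param standardize Fit per-fold column standardization on the training
#'   folds (default TRUE).
#' @param positive Positive-class label for recall/precision/F1 (default 0,
#'   large occlusion).
#' @param average `"positive"` (default) scores the positive class;
#'   `"macro"` averages recall/precision/F1 over both class orientations.
#' @return An `evaluation_report`: classifier name, folds, seed, pooled
#'   `confusion`, `accuracy`/`recall`/`precision`/`f1` (percent),
#'   `per_fold_accuracy`, `per_fold_confusion`, `settings`.
#' @export
cross_validate <- function(classifier_spec, X, y = NULL, folds = 10L,
                           seed = 1L, standardize = TRUE, positive = 0L,
                           average = c("positive", "macro")) {
  average <- match.arg(average)
  if (inherits(X, "feature_matrix")) {
    y <- y %||% X$labels
    X <- X$values
  }
  X <- as.matrix(X)
  y <- as.integer(y)
  spec <- resolve_classifier(classifier_spec, seed)
  fold_id <- stratified_folds(y, folds, seed)
  pred_all <- integer(length(y))
  per_fold_conf <- vector("list", folds)
  per_fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    if (standardize) {
      fit <- standardize_fit(X, tr)
      Xtr <- standardize_apply(Xtr, fit)
      Xte <- standardize_apply(Xte, fit)
    }
    model <- with_seed(seed + f, spec$fit(Xtr, y[tr]))
    p <- as.integer(spec$predict(model, Xte))
    pred_all[te] <- p
    per_fold_conf[[f]] <- pool_confusion(p, y[te], positive)
    per_fold_acc[f] <- mean(p == y[te])
  }
  conf <- pool_confusion(pred_all, y, positive)
  metrics <- if (average == "positive") {
    compute_metrics(conf)
  } else {
    a <- compute_metrics(conf)
    other <- setdiff(unique(y), positive)[1]
    b <- compute_metrics(pool_confusion(pred_all, y, other))
    list(accuracy = a$accuracy,
         recall = mean(c(a$recall, b$recall)),
         precision = mean(c(a$precision, b$precision)),
         f1 = mean(c(a$f1, b$f1)))
  }
  structure(list(classifier_name = spec$name, folds = as.integer(folds),
                 seed = as.integer(seed), confusion = conf,
                 accuracy = metrics$accuracy, recall = metrics$recall,
                 precision = metrics$precision, f1 = metrics$f1,
                 per_fold_accuracy = per_fold_acc,
                 per_fold_confusion = per_fold_conf,
                 settings = c(spec$settings,
                              list(standardize = standardize,
                                   positive = positive, average = average))),
            class = "evaluation_report")
}

#' Nine-classifier benchmark under identical folds
#'
#' Evaluates the pipeline's 1-NN classifier alongside eight off-the-shelf
#' comparison classifiers (decision tree, random forest, linear and quadratic
#' discriminant, logistic regression, naive Bayes, SVM, multi-layer
#' perceptron) with [cross_validate()] under identical stratified folds. The
#' comparison classifiers run in their standard default configurations,
#' recorded in each report's `settings`. A classifier whose fit fails on this
#' data (for example a singular class covariance for the quadratic
#' discriminant) is reported with `NA` metrics and the failure message.
#'
#' @inheritParams cross_validate
#' @return Named list of nine `evaluation_report`s, in the order
#'   kNN, DT, RF, LD, QD, LR, NB, SVM, MLP.
#' @export
benchmark_classifiers <- function(X, y = NULL, folds = 10L, seed = 1L,
                                  standardize = TRUE) {
  names9 <- c("kNN", "DT", "RF", "LD", "QD", "LR", "NB", "SVM", "MLP")
  reports <- setNames(vector("list", length(names9)), names9)
  for (nm in names9) {
    reports[[nm]] <- tryCatch(
      cross_validate(nm, X, y, folds = folds, seed = seed,
                     standardize = standardize),
      error = function(e) {
        structure(list(classifier_name = nm, folds = as.integer(folds),
                       seed = as.integer(seed), confusion = NULL,
                       accuracy = NA_real_, recall = NA_real_,
                       precision = NA_real_, f1 = NA_real_,
                       per_fold_accuracy = rep(NA_real_, folds),
                       per_fold_confusion = NULL,
                       settings = list(error = conditionMessage(e))),
                  class = "evaluation_report")
      })
  }
  reports
}

#' Summarize evaluation reports as a table
#'
#' @param reports A single `evaluation_report` or a list of them.
#' @return A data.frame with one row per classifier: name, accuracy, recall,
#'   precision, f1 (percent).
#' @export
report_table <- function(reports) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    data.frame(classifier = r$classifier_name, accuracy = r$accuracy,
               recall = r$recall, precision = r$precision, f1 = r$f1,
               stringsAsFactors = FALSE)
  }))
}

#' Serialize evaluation reports
#'
#' Writes the full reports as JSON and the summary metric table as CSV.
#'
#' @param reports A list of `evaluation_report`s (or one report).
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the summary table.
#' @export
write_reports <- function(reports, json_path = NULL, csv_path = NULL) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  tab <- report_table(reports)
  if (!is.null(json_path)) {
    payload <- lapply(reports, function(r) {
      r <- unclass(r)
      r$confusion <- if (is.null(r$confusion)) NULL else unclass(r$confusion)
      r$per_fold_confusion <- NULL
      r
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  invisible(tab)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (%d-fold CV, seed %d)\n",
              x$classifier_name, x$folds, x$seed))
  if (!is.null(x$confusion))
    cat(sprintf("  confusion: TP=%d TN=%d FP=%d FN=%d\n", x$confusion$TP,
                x$confusion$TN, x$confusion$FP, x$confusion$FN))
  cat(sprintf("  accuracy %.2f%%  recall %.2f%%  precision %.2f%%  f1 %.2f%%\n",
              x$accuracy, x$recall, x$precision, x$f1))
  invisible(x)
}
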