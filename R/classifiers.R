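# Registry of the benchmark classifiers. The 1-NN classifier is the
# pipeline's own; the other eight are off-the-shelf comparisons in their
# standard default configurations (recorded in `settings`). Each entry
# provides fit(X, y) -> model and predict(model, X) -> integer labels; labels
# are handled as a factor with levels "0" < "1" throughout.

resolve_classifier <- function(spec, seed = 1L) {
  if (is.list(spec) && !is.null(spec$fit) && !is.null(spec$predict)) {
    spec$name <- spec$name %||% "custom"
    spec$settings <- spec$settings %||% list()
    return(spec)
  }
  if (!is.character(spec) || length(spec) != 1L)
    stop_validation("classifier_spec must be a name or a fit/predict list")
  yfac <- function(y) factor(y, levels = c(0L, 1L))
  as_df <- function(X) {
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(ncol(df)))
    df
  }
  switch(spec,
    kNN = list(
      name = "kNN",
      settings = list(k = 1, distance = "Euclidean", voting = "none"),
      fit = function(X, y) list(X = X, y = y),
      predict = function(m, X) knn_predict(m$X, m$y, X, k = 1L)),
    DT = list(
      name = "DT", settings = list(engine = "rpart", defaults = TRUE),
      fit = function(X, y) {
        d <- as_df(X); d$.y <- yfac(y)
        rpart::rpart(.y ~ ., data = d, method = "class")
      },
      predict = function(m, X)
        as.integer(as.character(predict(m, as_df(X), type = "class")))),
    RF = list(
      name = "RF", settings = list(engine = "randomForest", ntree = 500),
      fit = function(X, y) randomForest::randomForest(X, yfac(y)),
      predict = function(m, X) as.integer(as.character(predict(m, X)))),
    LD = list(
      name = "LD", settings = list(engine = "MASS::lda", defaults = TRUE),
      fit = function(X, y) suppressWarnings(MASS::lda(X, grouping = yfac(y))),
      predict = function(m, X)
        as.integer(as.character(predict(m, X)$class))),
    QD = list(
      name = "QD", settings = list(engine = "MASS::qda", defaults = TRUE),
      fit = function(X, y) MASS::qda(X, grouping = yfac(y)),
      predict = function(m, X)
        as.integer(as.character(predict(m, X)$class))),
    LR = list(
      name = "LR",
      settings = list(engine = "stats::glm", family = "binomial",
                      threshold = 0.5),
      fit = function(X, y) {
        d <- as_df(X); d$.y <- y
        suppressWarnings(glm(.y ~ ., data = d, family = binomial()))
      },
      predict = function(m, X) {
        p <- suppressWarnings(predict(m, as_df(X), type = "response"))
        as.integer(p >= 0.5)
      }),
    NB = list(
      name = "NB", settings = list(engine = "e1071::naiveBayes",
                                   model = "gaussian"),
      fit = function(X, y) e1071::naiveBayes(X, yfac(y)),
      predict = function(m, X) as.integer(as.character(predict(m, X)))),
    SVM = list(
      name = "SVM",
      settings = list(engine = "e1071::svm", kernel = "radial", cost = 1,
                      scale = FALSE),
      # scale = FALSE: the CV harness already standardizes on training folds
      fit = function(X, y) e1071::svm(X, yfac(y), scale = FALSE),
      predict = function(m, X) as.integer(as.character(predict(m, X)))),
    MLP = list(
      name = "MLP",
      settings = list(engine = "nnet", size = 8, decay = 1e-4, maxit = 200),
      fit = function(X, y) {
        nw <- (ncol(X) + 1L) * 8L + 9L
        m <- nnet::nnet(X, as.numeric(y), size = 8, decay = 1e-4, maxit = 200,
                        trace = FALSE, MaxNWts = nw + 10L)
        m
      },
      predict = function(m, X) as.integer(predict(m, X) >= 0.5)),
    stop_validation("unknown classifier '%s'", spec)
  )
}
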