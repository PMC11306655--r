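#' k-nearest-neighbor prediction (Euclidean, deterministic tie-breaks)
#'
#' Labels each test point by majority vote among its `k` Euclidean nearest
#' training points. Ties are resolved deterministically: equal distances are
#' broken toward the lower training index, and vote ties (possible for even
#' `k`) toward the label of the single nearest neighbor. With the default
#' `k = 1` the vote is vacuous and each test point takes its nearest
#' neighbor's label ("voting: none").
#'
#' @param train_X Numeric training matrix (n_train x p).
#' @param train_y Training labels.
#' @param test_X Numeric test matrix (n_test x p).
#' @param k Number of neighbors (default 1); must not exceed n_train.
#' @return Integer vector of predicted labels.
#' @export
knn_predict <- function(train_X, train_y, test_X, k = 1L) {
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X)
  if (nrow(train_X) == 0L) stop_validation("training set is empty")
  if (!is_count(k, 1L) || k > nrow(train_X))
    stop_validation("k must satisfy 1 <= k <= n_train (k=%s, n_train=%d)",
                    k, nrow(train_X))
  if (ncol(train_X) != ncol(test_X))
    stop_validation("train and test have different feature counts (%d vs %d)",
                    ncol(train_X), ncol(test_X))
  train_y <- as.integer(train_y)
  # squared Euclidean distances via the expanded quadratic form
  D2 <- outer(rowSums(test_X^2), rowSums(train_X^2), "+") -
    2 * tcrossprod(test_X, train_X)
  pred <- integer(nrow(test_X))
  for (i in seq_len(nrow(test_X))) {
    ord <- order(D2[i, ])         # stable: equal distances -> lower index
    nn <- ord[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1L) as.integer(top) else train_y[ord[1L]]
  }
  pred
}
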