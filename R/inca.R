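#' Iterative NCA feature selection (top-k prefix scan)
#'
#' Sorts features by NCA weight (descending; ties broken toward the lower
#' column index) and, for every subset size `k` in the loop range, scores the
#' top-k prefix by the stratified cross-validated misclassification rate of a
#' 1-NN Euclidean classifier. The folds are fixed once from `seed` and reused
#' for every `k`, so losses are comparable across subset sizes; the chosen
#' `k` is the loss minimizer, with ties broken toward the smallest `k`.
#' Column standardization inside the loss evaluation is fitted on the
#' training folds only.
#'
#' @param X Numeric matrix (n_samples x n_features) or a `feature_matrix`.
#' @param y Binary labels (taken from `X` when it is a `feature_matrix`).
#' @param weights An `nca_weights` object or a numeric weight vector.
#' @param k_min,k_max Loop range of subset sizes (defaults 1 and 500);
#'   `k_max` is capped at the number of features.
#' @param loss_folds Number of stratified CV folds for the loss (default 10).
#' @param seed Integer seed fixing the folds.
#' @return A `selection_result`: `ranked_indices` (all features, weight
#'   order), `loop_range`, `losses` (named by k), `chosen_k`,
#'   `selected_indices`, `folds_seed`.
#' @export
inca_select <- function(X, y = NULL, weights, k_min = 1L, k_max = 500L,
                        loss_folds = 10L, seed = 1L) {
  if (inherits(X, "feature_matrix")) {
    y <- y %||% X$labels
    X <- X$values
  }
  if (!is.matrix(X)) stop_validation("X must be a numeric matrix")
  w <- if (inherits(weights, "nca_weights")) weights$weights else as.numeric(weights)
  if (length(w) != ncol(X))
    stop_validation("weights length %d != n_features %d", length(w), ncol(X))
  if (!is_count(k_min, 1L) || !is_count(k_max, 1L) || k_max < k_min)
    stop_validation("need k_max >= k_min >= 1 (got %s, %s)", k_min, k_max)
  y <- as.integer(y)
  n <- nrow(X)
  if (n < loss_folds)
    stop_validation("n_samples %d < loss_folds %d; use fewer folds", n,
                    loss_folds)

  ranked <- order(-w)  # stable: equal weights keep ascending column index
  K <- min(as.integer(k_max), ncol(X))
  k_min <- as.integer(k_min)
  fold_id <- stratified_folds(y, loss_folds, seed)
  ks <- k_min:K
  miss <- numeric(length(ks))

  cols <- ranked[seq_len(K)]
  Xr <- X[, cols, drop = FALSE]
  for (f in sort(unique(fold_id))) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    A <- Xr[tr, , drop = FALSE]
    m <- colMeans(A)
    s <- sqrt(pmax(colSums(A^2) - length(tr) * m^2, 0) / (length(tr) - 1L))
    ok <- s > 0
    Str <- sweep(A, 2L, m, "-")
    Ste <- sweep(Xr[te, , drop = FALSE], 2L, m, "-")
    if (any(ok)) {
      Str[, ok] <- sweep(Str[, ok, drop = FALSE], 2L, s[ok], "/")
      Ste[, ok] <- sweep(Ste[, ok, drop = FALSE], 2L, s[ok], "/")
    }
    if (any(!ok)) { Str[, !ok] <- 0; Ste[, !ok] <- 0 }
    D2 <- matrix(0, length(te), length(tr))
    for (k in seq_len(K)) {
      D2 <- D2 + outer(Ste[, k], Str[, k], "-")^2
      if (k >= k_min) {
        nn <- max.col(-D2, ties.method = "first")  # lowest train index on ties
        miss[k - k_min + 1L] <- miss[k - k_min + 1L] + sum(y[tr][nn] != y[te])
      }
    }
  }
  losses <- miss / n
  names(losses) <- ks
  chosen_k <- ks[which.min(losses)]  # which.min: first minimum -> smallest k
  structure(list(ranked_indices = ranked,
                 loop_range = c(k_min, as.integer(k_max)),
                 losses = losses, chosen_k = chosen_k,
                 selected_indices = ranked[seq_len(chosen_k)],
                 loss_folds = as.integer(loss_folds),
                 folds_seed = as.integer(seed)),
            class = "selection_result")
}

#' Serialize a selection result to JSON
#'
#' Writes the loss curve, loop range, chosen subset and the ranked indices
#' (truncated to the loop upper bound) to a JSON file.
#'
#' @param sr A `selection_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(sr, path) {
  stopifnot(inherits(sr, "selection_result"))
  K <- min(sr$loop_range[2], length(sr$ranked_indices))
  jsonlite::write_json(
    list(loop_range = sr$loop_range,
         ranked_indices = sr$ranked_indices[seq_len(K)],
         losses = as.numeric(sr$losses), loss_k = as.integer(names(sr$losses)),
         chosen_k = sr$chosen_k, selected_indices = sr$selected_indices,
         loss_folds = sr$loss_folds, folds_seed = sr$folds_seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
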