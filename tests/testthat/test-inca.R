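# Brute-force prefix oracle: recomputes the per-k CV loss independently
# (explicit per-fold standardization and loop-based 1-NN), sharing only the
# fold assignment, which is part of the contract under a fixed seed.
inca_oracle <- function(X, y, w, k_max, folds, seed) {
  ranked <- order(-w)
  fold_id <- pdfe:::stratified_folds(y, folds, seed)
  K <- min(k_max, ncol(X))
  losses <- numeric(K)
  for (k in seq_len(K)) {
    cols <- ranked[seq_len(k)]
    miss <- 0L
    for (f in sort(unique(fold_id))) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      A <- X[tr, cols, drop = FALSE]
      m <- apply(A, 2, mean); s <- apply(A, 2, sd)
      sc <- function(M) {
        out <- sweep(M, 2, m, "-")
        for (j in seq_along(s)) out[, j] <- if (s[j] > 0) out[, j] / s[j] else 0
        out
      }
      pred <- brute_1nn(sc(A), y[tr], sc(X[te, cols, drop = FALSE]))
      miss <- miss + sum(pred != y[te])
    }
    losses[k] <- miss / length(y)
  }
  losses
}

test_that("per-k loss curve equals an independent brute-force recomputation", {
  for (s in 1:3) {
    set.seed(s)
    n <- 30L
    y <- rep(c(0L, 1L), each = 15L)
    X <- matrix(rnorm(n * 12), n, 12)
    X[, 3] <- X[, 3] + ifelse(y == 1L, 1.5, 0)
    w <- runif(12)
    sel <- inca_select(X, y, w, k_min = 1L, k_max = 12L, loss_folds = 5L,
                       seed = s)
    oracle <- inca_oracle(X, y, w, 12L, 5L, s)
    expect_equal(unname(sel$losses), oracle)
    expect_equal(sel$chosen_k, which.min(oracle))  # smallest-k tie-break
    expect_equal(sel$selected_indices,
                 order(-w)[seq_len(sel$chosen_k)])
  }
})

test_that("a single perfectly separating feature gives chosen_k = 1, loss 0", {
  toy <- toy_classes(n_per = 15L, p = 8L, d_info = 1L, delta = 6, sd = 0.2,
                     seed = 2L)
  fit <- nca_weights(toy$X, toy$y, nca_config())
  expect_equal(which.max(fit$weights), 1L)
  sel <- inca_select(toy$X, toy$y, fit, k_max = 8L, loss_folds = 5L, seed = 1L)
  expect_equal(sel$chosen_k, 1L)
  expect_equal(unname(sel$losses[1]), 0)
  expect_identical(sel$selected_indices, 1L)
})

test_that("loop bounds default to [1, 500] and cap at the feature count", {
  toy <- toy_classes(n_per = 10L, p = 6L, seed = 5L)
  sel <- inca_select(toy$X, toy$y, runif(6), loss_folds = 5L, seed = 1L)
  expect_identical(sel$loop_range, c(1L, 500L))
  expect_length(sel$losses, 6L)           # capped at n_features
  expect_true(sel$chosen_k >= 1L && sel$chosen_k <= 6L)
  expect_false(anyDuplicated(sel$selected_indices) > 0)
})

test_that("equal weights rank by ascending column index and runs repeat", {
  toy <- toy_classes(n_per = 10L, p = 5L, seed = 7L)
  w <- c(0.5, 0.7, 0.5, 0.9, 0.5)
  s1 <- inca_select(toy$X, toy$y, w, k_max = 5L, loss_folds = 5L, seed = 3L)
  expect_identical(s1$ranked_indices, c(4L, 2L, 1L, 3L, 5L))
  s2 <- inca_select(toy$X, toy$y, w, k_max = 5L, loss_folds = 5L, seed = 3L)
  expect_identical(s1, s2)
  expect_error(inca_select(toy$X, toy$y, w, k_max = 0L),
               class = "pdfe_validation_error")
  expect_error(inca_select(toy$X, toy$y, w[-1]),
               class = "pdfe_validation_error")
  expect_error(inca_select(toy$X, toy$y, w, loss_folds = 50L),
               class = "pdfe_validation_error")
})

test_that("selection results serialize to JSON", {
  toy <- toy_classes(n_per = 10L, p = 5L, seed = 9L)
  sel <- inca_select(toy$X, toy$y, runif(5), k_max = 5L, loss_folds = 5L,
                     seed = 1L)
  path <- file.path(tempdir(), "sel.json")
  write_selection_result(sel, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$chosen_k, sel$chosen_k)
  expect_equal(back$losses, unname(sel$losses))
})
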