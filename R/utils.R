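# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's random stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Stratified fold assignment: within each class, samples are shuffled by the
# seeded RNG and dealt round-robin into `folds` folds, so fold sizes per class
# differ by at most one. Returns an integer vector of fold ids in 1..folds.
stratified_folds <- function(y, folds, seed) {
  y <- as.integer(y)
  if (folds < 2L) stop_validation("folds must be >= 2, got %d", folds)
  counts <- table(y)
  if (any(counts < folds)) {
    stop_validation(
      "each class needs at least %d samples for %d-fold CV (counts: %s); use fewer folds",
      folds, folds, paste(counts, collapse = "/"))
  }
  assign_ids <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      assign_ids[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign_ids
}

# Column standardization fitted on `fit_rows`: returns centered/scaled copy of
# X. Zero-variance columns (on the fit rows) are mapped to exactly zero for
# all rows, so they contribute nothing to any distance.
standardize_fit <- function(X, fit_rows = seq_len(nrow(X))) {
  m <- colMeans(X[fit_rows, , drop = FALSE])
  s <- apply(X[fit_rows, , drop = FALSE], 2L, sd)
  list(center = m, scale = s)
}

standardize_apply <- function(X, fit) {
  Z <- sweep(X, 2L, fit$center, "-")
  ok <- fit$scale > 0
  if (any(ok)) Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2L, fit$scale[ok], "/")
  if (any(!ok)) Z[, !ok] <- 0
  Z
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

`%||%` <- function(a, b) if (is.null(a)) b else a
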