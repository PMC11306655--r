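#' Configuration for NCA feature weighting
#'
#' Hyperparameters of the neighborhood component analysis weighting stage.
#' The distance model is the weighted L1 metric
#' `d_w(x_i, x_j) = sum_r w_r^2 |x_ir - x_jr|`; soft nearest-neighbor
#' reference probabilities `p_ij` are proportional to `exp(-d_w / sigma)`,
#' and the objective maximized by gradient ascent from the all-ones weight
#' vector is the expected leave-one-out same-class mass minus an l2 weight
#' penalty: `xi(w) = sum_i p_i - lambda_reg * sum_r w_r^2`.
#'
#' @param sigma Kernel width. The default `"auto"` sets sigma to the mean
#'   initial (all-ones-weight) pairwise distance, which keeps the softmax in
#'   its informative regime at any feature-space width; a fixed positive
#'   number may be supplied instead.
#' @param lambda_reg Regularization coefficient; `NULL` (default) resolves to
#'   `1 / n_samples` at fit time.
#' @param max_iters Maximum accepted gradient-ascent iterations (default 100).
#' @param learning_rate Initial step size (default 0.01), halved until a step
#'   does not decrease the objective and grown mildly after accepted steps.
#' @param tol Relative objective improvement below which the ascent is
#'   declared converged (default 1e-6).
#' @param standardize Center/scale columns before weighting (default TRUE);
#'   zero-variance columns are mapped to zero.
#' @param seed Integer seed, kept for contract symmetry with the other
#'   stages; the ascent itself is deterministic (full-batch, fixed
#'   initialization) and does not consume randomness.
#' @return An object of class `nca_config`.
#' @export
nca_config <- function(sigma = "auto", lambda_reg = NULL, max_iters = 100L,
                       learning_rate = 0.01, tol = 1e-6, standardize = TRUE,
                       seed = 1L) {
  if (is.character(sigma)) {
    if (!identical(sigma, "auto"))
      stop_validation("sigma must be 'auto' or a positive number")
  } else if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_validation("sigma must be 'auto' or a positive number, got %s", sigma)
  }
  if (!is.null(lambda_reg) && (!is.numeric(lambda_reg) || lambda_reg < 0))
    stop_validation("lambda_reg must be >= 0 or NULL")
  if (!is_count(max_iters, 1L))
    stop_validation("max_iters must be a count >= 1")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_validation("learning_rate must be positive")
  structure(list(sigma = sigma, lambda_reg = lambda_reg,
                 max_iters = as.integer(max_iters),
                 learning_rate = learning_rate, tol = tol,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "nca_config")
}

#' Fit NCA feature weights
#'
#' Runs regularized NCA gradient ascent (see [nca_config()] for the model)
#' and returns one nonnegative relevance weight per feature together with the
#' per-iteration objective trace. Accepted steps never decrease the
#' objective; the final weights are reported as magnitudes (the objective
#' depends on the weights only through their squares).
#'
#' @param X Numeric matrix (n_samples x n_features) or a `feature_matrix`.
#' @param y Binary label vector (0/1), both classes present.
#' @param config An [nca_config()].
#' @return An `nca_weights` object: `weights` (nonnegative, one per feature),
#'   `objective_trace`, `converged`, `iterations`, `sigma` (the resolved
#'   kernel width), `lambda_reg`.
#' @export
nca_weights <- function(X, y = NULL, config = nca_config()) {
  if (inherits(X, "feature_matrix")) {
    y <- y %||% X$labels
    X <- X$values
  }
  if (!is.matrix(X)) stop_validation("X must be a numeric matrix")
  n <- nrow(X)
  if (n < 2L) stop_validation("need at least 2 samples, got %d", n)
  y <- as.integer(y)
  if (length(y) != n) stop_validation("labels length %d != n_samples %d",
                                      length(y), n)
  if (length(unique(y)) < 2L)
    stop_validation("NCA weighting requires both classes to be present")
  lambda <- config$lambda_reg %||% (1 / n)
  sigma <- if (identical(config$sigma, "auto")) -1 else config$sigma
  fit <- tryCatch(
    nca_fit_cpp(X, y, sigma, lambda, config$learning_rate, config$max_iters,
                config$tol, config$standardize),
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("non-finite", msg)) stop_numerical("%s", msg) else stop(e)
    })
  structure(list(weights = as.numeric(fit$weights),
                 objective_trace = as.numeric(fit$objective_trace),
                 converged = isTRUE(fit$converged),
                 iterations = fit$iterations,
                 sigma = fit$sigma_used, lambda_reg = lambda,
                 config = config),
            class = "nca_weights")
}

#' NCA objective and analytic gradient at a weight vector
#'
#' Evaluates the regularized NCA objective and its analytic gradient at an
#' arbitrary weight vector, without fitting. Intended for diagnostics and for
#' verifying the gradient against finite differences.
#'
#' @param X Numeric matrix (n_samples x n_features).
#' @param y Binary labels.
#' @param w Weight vector, one entry per feature.
#' @param sigma Positive kernel width, or `"auto"` to use the mean pairwise
#'   distance at the supplied weights.
#' @param lambda_reg Regularization coefficient.
#' @param standardize Center/scale columns first (default FALSE).
#' @return List with `objective`, `gradient`, `sigma_used`.
#' @export
nca_objective <- function(X, y, w, sigma = 1, lambda_reg = 0,
                          standardize = FALSE) {
  if (!is.matrix(X)) stop_validation("X must be a numeric matrix")
  if (length(w) != ncol(X))
    stop_validation("w length %d != n_features %d", length(w), ncol(X))
  s <- if (identical(sigma, "auto")) -1 else sigma
  out <- nca_grad_cpp(X, as.integer(y), as.numeric(w), s, lambda_reg,
                      standardize)
  list(objective = out$objective, gradient = as.numeric(out$gradient),
       sigma_used = out$sigma_used)
}
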