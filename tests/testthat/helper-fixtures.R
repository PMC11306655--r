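# Shared fixtures, built in code at test time.

# Small phantom configuration: fast to render, same structure as the default.
small_synth <- function(n0 = 4L, n1 = 4L, effect = 1, seed = 1L,
                        noise = 0.05) {
  synth_config(n_class0 = n0, n_class1 = n1, image_size = 48L,
               lesion_radius_class0 = 10, lesion_radius_class1 = 3,
               lesion_contrast = 0.15, noise_sd = noise,
               effect_size = effect, seed = seed)
}

# Two well-separated Gaussian classes in `p` dimensions, first `d_info`
# columns carrying the class shift.
toy_classes <- function(n_per = 20L, p = 10L, d_info = 1L, delta = 4,
                        sd = 0.3, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n_per)
  X <- matrix(rnorm(2 * n_per * p, sd = 1), 2 * n_per, p)
  for (j in seq_len(d_info))
    X[, j] <- ifelse(y == 0L, -delta / 2, delta / 2) + rnorm(2 * n_per, sd = sd)
  list(X = X, y = y)
}

# Independent brute-force 1-NN (used as an oracle against knn_predict and the
# INCA loss curve): plain loops, no shared code with the implementation.
brute_1nn <- function(train_X, train_y, test_X) {
  pred <- integer(nrow(test_X))
  for (i in seq_len(nrow(test_X))) {
    best <- Inf; best_j <- NA_integer_
    for (j in seq_len(nrow(train_X))) {
      d <- sqrt(sum((test_X[i, ] - train_X[j, ])^2))
      if (d < best) { best <- d; best_j <- j }
    }
    pred[i] <- train_y[best_j]
  }
  pred
}

# Independent NCA objective (weighted-L1 distances, softmax reference
# probabilities, l2 penalty) for finite-difference gradient checks.
nca_obj_ref <- function(X, y, w, sigma, lambda) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sum(w^2 * abs(X[i, ] - X[j, ]))
  total <- 0
  for (i in seq_len(n)) {
    k <- exp(-D[i, -i] / sigma)
    p <- k / sum(k)
    same <- y[-i] == y[i]
    total <- total + sum(p[same])
  }
  total - lambda * sum(w^2)
}
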