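# Feature extractor backends. Both satisfy the same contract: an extractor
# object with fields name, output_dim, input_side, deterministic and layers
# (named activation blocks with their widths), consumed by
# extract_input_features(). Extraction is deterministic: frozen weights, no
# dropout, no RNG at inference.

resize_matrix <- function(m, side) {
  if (nrow(m) == side && ncol(m) == side) return(m)
  out <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(m)),
                                              w = side, h = side,
                                              filter = "bilinear")))
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Seeded random-projection feature extractor
#'
#' A deterministic, training-free extractor with the same contract and
#' default width as the AlexNet fc6+fc7 backend: the input is bilinearly
#' resized to `input_side` x `input_side`, flattened, passed through a fixed
#' seeded random linear projection (Gaussian weights, scaled by the inverse
#' square root of the input dimension) and rectified. It needs no downloaded
#' weights and is the recommended backend for reproducible CPU-only runs.
#'
#' @param seed Integer seed fixing the projection weights.
#' @param output_dim Number of output features (default 8192, matching
#'   fc6 + fc7).
#' @param input_side Side in pixels to which inputs are resized (default 32).
#' @return A `pdfe_extractor` of subclass `fallback_extractor`.
#' @export
fallback_extractor <- function(seed = 1L, output_dim = 8192L, input_side = 32L) {
  if (!is_count(output_dim, 1L))
    stop_validation("output_dim must be a positive integer, got %s", output_dim)
  if (!is_count(input_side, 4L))
    stop_validation("input_side must be an integer >= 4, got %s", input_side)
  d_in <- as.integer(input_side)^2
  W <- with_seed(seed, matrix(rnorm(d_in * output_dim, sd = 1 / sqrt(d_in)),
                              nrow = d_in, ncol = as.integer(output_dim)))
  structure(list(name = sprintf("fallback(seed=%d)", as.integer(seed)),
                 output_dim = as.integer(output_dim),
                 input_side = as.integer(input_side),
                 deterministic = TRUE,
                 layers = list(list(name = "proj",
                                    dim = as.integer(output_dim))),
                 W = W),
            class = c("fallback_extractor", "pdfe_extractor"))
}

#' AlexNet-architecture deep feature extractor (fc6 + fc7)
#'
#' Builds the canonical AlexNet convolutional architecture (five convolution
#' layers with ReLU and max pooling, then fully connected fc6 and fc7 of
#' 4096 units each) with frozen weights, and exposes the concatenated
#' fc6 + fc7 activations (8192 values) as the feature vector. Grayscale
#' inputs are resized to `input_side`, replicated to three channels and
#' normalized by the ImageNet channel statistics before the forward pass.
#'
#' Weights are seeded He-normal random draws by default: the architecture —
#' and hence the feature geometry and the 4096 + 4096 output layout — is
#' exact, while pretrained ImageNet weights can be supplied through `weights`
#' as a named list of arrays matching the layer shapes.
#'
#' @param seed Integer seed for the random weight initialization.
#' @param input_side Input side in pixels; 227 is the canonical AlexNet grid.
#' @param activation `"post"` (default) returns fc6/fc7 after the rectifier,
#'   `"pre"` before it.
#' @param weights Optional named list (`conv1` ... `conv5`, `fc6`, `fc7`,
#'   each a list with `W` and `b`) overriding the random initialization.
#' @return A `pdfe_extractor` of subclass `alexnet_extractor` with
#'   `output_dim = 8192`.
#' @export
alexnet_extractor <- function(seed = 1L, input_side = 227L,
                              activation = c("post", "pre"), weights = NULL) {
  activation <- match.arg(activation)
  if (!is_count(input_side, 63L))
    stop_validation("input_side must be an integer >= 63, got %s", input_side)
  input_side <- as.integer(input_side)
  arch <- list(
    conv1 = list(k = 11L, stride = 4L, pad = 0L, in_ch = 3L,   out_ch = 96L,  pool = TRUE),
    conv2 = list(k = 5L,  stride = 1L, pad = 2L, in_ch = 96L,  out_ch = 256L, pool = TRUE),
    conv3 = list(k = 3L,  stride = 1L, pad = 1L, in_ch = 256L, out_ch = 384L, pool = FALSE),
    conv4 = list(k = 3L,  stride = 1L, pad = 1L, in_ch = 384L, out_ch = 384L, pool = FALSE),
    conv5 = list(k = 3L,  stride = 1L, pad = 1L, in_ch = 384L, out_ch = 256L, pool = TRUE))
  # spatial side after each stage
  side <- input_side
  for (nm in names(arch)) {
    l <- arch[[nm]]
    side <- (side + 2L * l$pad - l$k) %/% l$stride + 1L
    if (l$pool) side <- (side - 3L) %/% 2L + 1L
    arch[[nm]]$out_side <- side
    if (side < 1L)
      stop_validation("input_side %d is too small for the architecture",
                      input_side)
  }
  flat_dim <- side^2 * arch$conv5$out_ch
  if (is.null(weights)) {
    weights <- with_seed(seed, {
      w <- list()
      for (nm in names(arch)) {
        l <- arch[[nm]]
        fan_in <- l$k^2 * l$in_ch
        w[[nm]] <- list(W = matrix(rnorm(fan_in * l$out_ch,
                                         sd = sqrt(2 / fan_in)),
                                   fan_in, l$out_ch),
                        b = numeric(l$out_ch))
      }
      w$fc6 <- list(W = matrix(rnorm(flat_dim * 4096L, sd = sqrt(2 / flat_dim)),
                               flat_dim, 4096L), b = numeric(4096L))
      w$fc7 <- list(W = matrix(rnorm(4096L * 4096L, sd = sqrt(2 / 4096)),
                               4096L, 4096L), b = numeric(4096L))
      w
    })
  } else {
    if (nrow(weights$fc6$W) != flat_dim)
      stop_validation("supplied fc6 weights expect input %d, architecture yields %d",
                      nrow(weights$fc6$W), flat_dim)
  }
  structure(list(name = sprintf("alexnet(seed=%d,%s-activation)",
                                as.integer(seed), activation),
                 output_dim = 8192L, input_side = input_side,
                 deterministic = TRUE,
                 layers = list(list(name = "fc6", dim = 4096L),
                               list(name = "fc7", dim = 4096L)),
                 arch = arch, weights = weights, activation = activation,
                 imagenet_mean = c(0.485, 0.456, 0.406),
                 imagenet_sd = c(0.229, 0.224, 0.225)),
            class = c("alexnet_extractor", "pdfe_extractor"))
}

# im2col convolution on an H x W x C array; returns array o x o x F.
conv_forward <- function(x, layer, wts) {
  h <- dim(x)[1]; k <- layer$k; s <- layer$stride; p <- layer$pad
  cch <- dim(x)[3]
  if (p > 0L) {
    xp <- array(0, dim(x) + c(2L * p, 2L * p, 0L))
    xp[(p + 1L):(p + h), (p + 1L):(p + h), ] <- x
    x <- xp
    h <- h + 2L * p
  }
  o <- (h - k) %/% s + 1L
  starts <- (seq_len(o) - 1L) * s + 1L
  # receptive-field linear indices: rows = output positions (row-major over
  # (out_row, out_col) is not required here; any fixed order works because the
  # same order is used to reshape back)
  off <- as.vector(outer(seq_len(k), (seq_len(k) - 1L) * h, "+"))  # k*k offsets
  base <- outer(starts, (starts - 1L) * h, "+")                     # o x o anchors
  idx2d <- outer(as.vector(base), off - 1L, "+")                    # (o*o) x (k*k)
  plane <- h * h
  cols <- matrix(0, o * o, k * k * cch)
  for (ch in seq_len(cch))
    cols[, ((ch - 1L) * k * k + 1L):(ch * k * k)] <- x[idx2d + (ch - 1L) * plane]
  out <- cols %*% wts$W
  out <- sweep(out, 2L, wts$b, "+")
  out[out < 0] <- 0  # ReLU
  array(out, c(o, o, ncol(wts$W)))
}

# 3x3 stride-2 max pooling (valid) on H x W x C.
maxpool3s2 <- function(x) {
  h <- dim(x)[1]
  o <- (h - 3L) %/% 2L + 1L
  starts <- (seq_len(o) - 1L) * 2L + 1L
  out <- array(-Inf, c(o, o, dim(x)[3]))
  for (dr in 0:2) for (dc in 0:2)
    out <- pmax(out, x[starts + dr, starts + dc, , drop = FALSE])
  out
}

alexnet_forward <- function(ex, img01) {
  m <- resize_matrix(img01, ex$input_side)
  x <- array(0, c(ex$input_side, ex$input_side, 3L))
  for (ch in 1:3) x[, , ch] <- (m - ex$imagenet_mean[ch]) / ex$imagenet_sd[ch]
  for (nm in names(ex$arch)) {
    x <- conv_forward(x, ex$arch[[nm]], ex$weights[[nm]])
    if (ex$arch[[nm]]$pool) x <- maxpool3s2(x)
  }
  flat <- as.vector(x)
  fc6_pre <- as.vector(flat %*% ex$weights$fc6$W) + ex$weights$fc6$b
  fc6 <- pmax(fc6_pre, 0)
  fc7_pre <- as.vector(fc6 %*% ex$weights$fc7$W) + ex$weights$fc7$b
  fc7 <- pmax(fc7_pre, 0)
  out <- if (ex$activation == "post") c(fc6, fc7) else c(fc6_pre, fc7_pre)
  if (any(!is.finite(fc6_pre)))
    stop_numerical("non-finite activation in layer fc6")
  if (any(!is.finite(fc7_pre)))
    stop_numerical("non-finite activation in layer fc7")
  out
}

#' Extract deep features from a single input grid
#'
#' Applies the extractor to one 2-D intensity grid in \[0, 1\] (a raw image
#' or a patch) and returns the feature vector of length `output_dim`. For the
#' AlexNet backend this is the concatenation of the fc6 (first 4096) and fc7
#' (last 4096) activations after the forward pass with frozen weights.
#'
#' @param extractor A `pdfe_extractor`.
#' @param input_img Numeric matrix with values in \[0, 1\].
#' @return Numeric vector of length `extractor$output_dim`.
#' @export
extract_input_features <- function(extractor, input_img) {
  UseMethod("extract_input_features")
}

#' @export
extract_input_features.fallback_extractor <- function(extractor, input_img) {
  check_input_grid(input_img)
  m <- resize_matrix(input_img, extractor$input_side)
  v <- as.vector(as.vector(m) %*% extractor$W)
  pmax(v, 0)
}

#' @export
extract_input_features.alexnet_extractor <- function(extractor, input_img) {
  check_input_grid(input_img)
  alexnet_forward(extractor, input_img)
}

#' @export
extract_input_features.default <- function(extractor, input_img) {
  stop_validation("extractor is not a loaded pdfe_extractor (got class '%s')",
                  paste(class(extractor), collapse = "/"))
}

check_input_grid <- function(m) {
  if (!is.matrix(m) || nrow(m) < 1L || ncol(m) < 1L)
    stop_validation("extractor input must be a non-empty numeric matrix")
  if (anyNA(m) || min(m) < 0 || max(m) > 1)
    stop_validation("extractor input intensities must lie in [0, 1]")
  invisible(m)
}

# Batched extraction of many grids; the fallback backend stacks them into one
# matrix multiply, other backends fall back to a loop.
extract_batch <- function(extractor, grids) {
  if (inherits(extractor, "fallback_extractor")) {
    X <- matrix(0, length(grids), extractor$input_side^2)
    for (i in seq_along(grids))
      X[i, ] <- as.vector(resize_matrix(grids[[i]], extractor$input_side))
    V <- X %*% extractor$W
    V[V < 0] <- 0
    V
  } else {
    t(vapply(grids, function(g) extract_input_features(extractor, g),
             numeric(extractor$output_dim)))
  }
}
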