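#' Configuration for the synthetic two-class phantom generator
#'
#' Builds the configuration for a seeded generator of two-class grayscale
#' phantoms that emulate the statistical structure the pipeline assumes: an
#' elliptical "brain" region bounded by a bright "skull" rim, containing a
#' disk of elevated intensity (the occlusion analogue) at a seeded location,
#' plus i.i.d. Gaussian pixel noise clipped to \[0, 1\]. The two classes share
#' every parameter except the lesion radius: class 0 (the large-occlusion
#' analogue) carries a large disk, class 1 a small one.
#'
#' The class-discriminating signal strength is `effect_size * lesion_contrast`;
#' at `effect_size = 0` the lesion amplitude vanishes and the per-class pixel
#' distributions are identical by construction.
#'
#' @param n_class0,n_class1 Number of images per class (defaults 159 / 165).
#' @param image_size Side of the square image in pixels before any resizing
#'   (default 256).
#' @param lesion_radius_class0,lesion_radius_class1 Lesion disk radii in
#'   pixels for the two classes (defaults 28 and 8).
#' @param lesion_contrast Intensity offset of the lesion disk above the brain
#'   parenchyma, in \[0, 1\] units (default 0.15).
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise
#'   (default 0.05).
#' @param effect_size Nonnegative scalar multiplying `lesion_contrast`;
#'   0 makes the classes identically distributed (default 1).
#' @param seed Integer seed from which all per-image seeds are derived.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_class0 = 159L, n_class1 = 165L,
                         image_size = 256L,
                         lesion_radius_class0 = 28,
                         lesion_radius_class1 = 8,
                         lesion_contrast = 0.15,
                         noise_sd = 0.05,
                         effect_size = 1,
                         seed = 1L) {
  cfg <- list(n_class0 = as.integer(n_class0), n_class1 = as.integer(n_class1),
              image_size = as.integer(image_size),
              lesion_radius_class0 = lesion_radius_class0,
              lesion_radius_class1 = lesion_radius_class1,
              lesion_contrast = lesion_contrast, noise_sd = noise_sd,
              effect_size = effect_size, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (!is_count(cfg$n_class0)) stop_validation("n_class0 must be a count >= 1")
  if (!is_count(cfg$n_class1)) stop_validation("n_class1 must be a count >= 1")
  if (!is_count(cfg$image_size, 32L))
    stop_validation("image_size must be >= 32, got %s", cfg$image_size)
  for (f in c("lesion_radius_class0", "lesion_radius_class1")) {
    r <- cfg[[f]]
    if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= cfg$image_size / 2)
      stop_validation("%s must lie in (0, image_size/2), got %s", f, r)
  }
  if (!is.numeric(cfg$lesion_contrast) || cfg$lesion_contrast < 0 ||
      cfg$lesion_contrast > 1)
    stop_validation("lesion_contrast must lie in [0, 1], got %s",
                    cfg$lesion_contrast)
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0)
    stop_validation("noise_sd must be >= 0, got %s", cfg$noise_sd)
  if (!is.numeric(cfg$effect_size) || cfg$effect_size < 0)
    stop_validation("effect_size must be >= 0, got %s", cfg$effect_size)
  invisible(cfg)
}

# Phantom geometry shared by both classes. Semi-axes of the brain ellipse and
# the skull rim are fixed fractions of the image side; intensities are chosen
# to mimic an 8-bit soft-tissue windowed head CT (dark air background, bright
# skull rim, mid-gray parenchyma).
phantom_geometry <- function(image_size) {
  s <- image_size
  list(cx = (s + 1) / 2, cy = (s + 1) / 2,
       a = 0.36 * s, b = 0.44 * s,        # brain ellipse semi-axes (x, y)
       rim = 0.035 * s,                   # skull rim thickness
       bg = 0.02, skull = 0.90, brain = 0.45)
}

#' Generate one synthetic phantom image
#'
#' Deterministically renders a single phantom for the given class label and
#' seed: brain ellipse plus skull rim, a lesion disk of the class radius at a
#' seeded uniform location strictly inside the brain, amplitude
#' `effect_size * lesion_contrast`, then Gaussian noise, clipped to \[0, 1\].
#'
#' @param label Class label, 0 (large lesion) or 1 (small lesion).
#' @param seed Integer seed; fixed `(label, seed, config)` gives bitwise
#'   identical output.
#' @param config A [synth_config()].
#' @return An `image_record`: list with `id`, `pixels` (matrix in \[0, 1\],
#'   rows = image rows), `label`, `source = "synthetic"`.
#' @export
generate_image <- function(label, seed, config) {
  validate_synth_config(config)
  if (!label %in% c(0L, 1L)) stop_validation("label must be 0 or 1, got %s", label)
  s <- config$image_size
  g <- phantom_geometry(s)
  r <- if (label == 0L) config$lesion_radius_class0 else config$lesion_radius_class1
  amp <- config$effect_size * config$lesion_contrast

  # template: background, skull rim, brain interior
  xs <- matrix(rep(seq_len(s), each = s), nrow = s)   # column index per pixel
  ys <- matrix(rep(seq_len(s), times = s), nrow = s)  # row index per pixel
  e_in <- ((xs - g$cx) / g$a)^2 + ((ys - g$cy) / g$b)^2
  e_out <- ((xs - g$cx) / (g$a + g$rim))^2 + ((ys - g$cy) / (g$b + g$rim))^2
  img <- matrix(g$bg, s, s)
  img[e_out <= 1] <- g$skull
  img[e_in <= 1] <- g$brain

  with_seed(seed, {
    # lesion center uniform over the shrunken ellipse in which the full disk
    # fits inside the brain; rejection sampling from the bounding box
    a2 <- g$a - r; b2 <- g$b - r
    repeat {
      lx <- g$cx + runif(1, -a2, a2)
      ly <- g$cy + runif(1, -b2, b2)
      if (((lx - g$cx) / a2)^2 + ((ly - g$cy) / b2)^2 <= 1) break
    }
    lesion <- ((xs - lx)^2 + (ys - ly)^2) <= r^2
    img[lesion] <- img[lesion] + amp
    if (config$noise_sd > 0)
      img <- img + matrix(rnorm(s * s, 0, config$noise_sd), s, s)
  })
  img[img < 0] <- 0
  img[img > 1] <- 1
  image_record(id = sprintf("class%d_seed%d", label, seed), pixels = img,
               label = as.integer(label), source = "synthetic")
}

#' Construct an image record
#'
#' Light container for one grayscale image: a pixel matrix in \[0, 1\]
#' (rows = image rows, columns = image columns), an id, a binary label and a
#' provenance tag.
#'
#' @param id Character id.
#' @param pixels Numeric matrix with all values in \[0, 1\].
#' @param label Integer 0/1 or NA when unlabeled.
#' @param source `"synthetic"` or `"file"`.
#' @return An object of class `image_record`.
#' @export
image_record <- function(id, pixels, label = NA_integer_, source = "file") {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_validation("pixels must be a non-empty matrix (image '%s')", id)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop_validation("pixel intensities must lie in [0, 1] (image '%s')", id)
  structure(list(id = as.character(id), pixels = pixels,
                 label = if (is.na(label)) NA_integer_ else as.integer(label),
                 source = source),
            class = "image_record")
}

#' Generate a full two-class synthetic dataset
#'
#' Renders `n_class0 + n_class1` phantoms with per-image seeds derived
#' deterministically from `config$seed` and the image index, so the whole
#' dataset is a pure function of the configuration. When `out_dir` is given,
#' images are written as 8-bit grayscale PNG under `out_dir/images/` along
#' with a manifest CSV (`id,path,label`, paths relative to the manifest).
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory, or `NULL` to keep the dataset in memory
#'   only.
#' @return List with `records` (list of `image_record`), `manifest`
#'   (data.frame `id, path, label`) and `manifest_path` (`NA` when `out_dir`
#'   is `NULL`).
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  validate_synth_config(config)
  labels <- c(rep(0L, config$n_class0), rep(1L, config$n_class1))
  n <- length(labels)
  records <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    rec <- generate_image(labels[i], seed = config$seed + i, config = config)
    rec$id <- sprintf("class%d_%04d", labels[i], i)
    ids[i] <- rec$id
    records[[i]] <- rec
  }
  manifest <- data.frame(id = ids,
                         path = file.path("images", paste0(ids, ".png")),
                         label = labels, stringsAsFactors = FALSE)
  manifest_path <- NA_character_
  if (!is.null(out_dir)) {
    img_dir <- file.path(out_dir, "images")
    ok <- dir.exists(img_dir) || dir.create(img_dir, recursive = TRUE,
                                            showWarnings = FALSE)
    if (!ok || file.access(img_dir, 2L) != 0L)
      stop_io("cannot create or write output directory '%s'", img_dir)
    for (i in seq_len(n)) {
      # EBImage stores images as (x, y); transpose from row/col convention
      EBImage::writeImage(EBImage::Image(t(records[[i]]$pixels)),
                          file.path(out_dir, manifest$path[i]),
                          type = "png", bits = 8L)
    }
    manifest_path <- file.path(out_dir, "manifest.csv")
    write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  }
  list(records = records, manifest = manifest, manifest_path = manifest_path)
}
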