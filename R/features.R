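#' Build the fused patch-and-raw feature matrix
#'
#' For every record: resize to `resize_side` (default 224), tile into
#' `patch_side` patches (default 16, giving 196), then extract one feature
#' vector from the raw resized image and one per patch, and concatenate them
#' into a single fused row. Rows follow the order of `records`; extraction is
#' streamed record by record so peak memory is dominated by the output
#' matrix.
#'
#' Column order is fixed for reproducible feature indices: the raw image
#' block first, then patches in row-major order; within each input, the
#' extractor's layer blocks in order (fc6 units then fc7 units for the
#' AlexNet backend). With the defaults the fused width is
#' (1 + 196) x 8192 = 1,613,824.
#'
#' @param extractor A `pdfe_extractor`.
#' @param records List of `image_record`s with binary labels; at least two
#'   records and both classes must be present.
#' @param patch_side Patch side in pixels (default 16).
#' @param resize_side Grid side to which images are resized first
#'   (default 224).
#' @return A `feature_matrix`: list with `values` (n_samples x n_features),
#'   `sample_ids`, `labels`, `n_patches`, `extractor_name`, `layer_blocks`
#'   and a `provenance()`-compatible layout description.
#' @export
build_feature_matrix <- function(extractor, records, patch_side = 16L,
                                 resize_side = 224L) {
  if (!inherits(extractor, "pdfe_extractor"))
    stop_validation("extractor must be a pdfe_extractor")
  if (length(records) < 2L)
    stop_validation("need at least 2 records, got %d", length(records))
  labels <- vapply(records, function(r) {
    if (is.null(r$label) || is.na(r$label))
      stop_validation("record '%s' has no label", r$id)
    as.integer(r$label)
  }, integer(1))
  if (length(unique(labels)) < 2L)
    stop_validation("both classes must be present (labels seen: %s)",
                    paste(unique(labels), collapse = ","))
  n_patches <- (as.integer(resize_side) %/% as.integer(patch_side))^2
  d <- extractor$output_dim
  n_features <- (1L + n_patches) * d
  values <- matrix(0, length(records), n_features)
  ids <- character(length(records))
  for (i in seq_along(records)) {
    rec <- resize_image(records[[i]], resize_side)
    ps <- tile_patches(rec, patch_side)
    grids <- c(list(rec$pixels), ps$patches)
    values[i, ] <- as.vector(t(extract_batch(extractor, grids)))
    ids[i] <- rec$id
  }
  if (any(!is.finite(values)))
    stop_numerical("feature matrix contains non-finite values")
  structure(list(values = values, sample_ids = ids, labels = labels,
                 n_patches = n_patches, patch_side = as.integer(patch_side),
                 resize_side = as.integer(resize_side),
                 extractor_name = extractor$name,
                 layer_blocks = extractor$layers,
                 output_dim = d),
            class = "feature_matrix")
}

#' Per-column provenance of a feature matrix
#'
#' Returns, for each fused column, the source input (`"raw"` or
#' `"patch <p>"` with patches 0-based in row-major order), the extractor
#' layer block and the 0-based unit index within that block.
#'
#' @param fm A `feature_matrix`.
#' @param columns Integer vector of 1-based column indices (default: all).
#' @return A data.frame with columns `column`, `input`, `layer`, `unit`.
#' @export
feature_provenance <- function(fm, columns = seq_len(ncol(fm$values))) {
  stopifnot(inherits(fm, "feature_matrix"))
  d <- fm$output_dim
  block_names <- vapply(fm$layer_blocks, `[[`, character(1), "name")
  block_dims <- vapply(fm$layer_blocks, `[[`, integer(1), "dim")
  block_ends <- cumsum(block_dims)
  col0 <- as.integer(columns) - 1L
  if (any(col0 < 0L) || any(col0 >= (1L + fm$n_patches) * d))
    stop_validation("column index out of range")
  input_idx <- col0 %/% d          # 0 = raw, 1.. = patches
  within <- col0 %% d
  blk <- findInterval(within, block_ends) + 1L  # within < end => block
  unit <- within - c(0L, block_ends)[blk]
  data.frame(column = as.integer(columns),
             input = ifelse(input_idx == 0L, "raw",
                            sprintf("patch %d", input_idx - 1L)),
             layer = block_names[blk],
             unit = as.integer(unit),
             stringsAsFactors = FALSE)
}

#' Write / read a feature matrix container
#'
#' The matrix is stored as a compressed binary container (RDS) with a JSON
#' sidecar recording the layout, labels and extraction configuration, so the
#' provenance of every column can be audited without loading the matrix.
#'
#' @param fm A `feature_matrix`.
#' @param path Path of the container (`.rds`); the sidecar is written next to
#'   it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  saveRDS(fm, path, compress = "gzip")
  sidecar <- list(sample_ids = fm$sample_ids, labels = fm$labels,
                  n_patches = fm$n_patches, patch_side = fm$patch_side,
                  resize_side = fm$resize_side, output_dim = fm$output_dim,
                  extractor = fm$extractor_name,
                  layer_blocks = fm$layer_blocks,
                  n_features = ncol(fm$values),
                  column_order = "raw first, then patches row-major; layer blocks in order within each input")
  jsonlite::write_json(sidecar, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop_io("feature container '%s' does not exist", path)
  fm <- readRDS(path)
  if (!inherits(fm, "feature_matrix"))
    stop_io("'%s' is not a feature_matrix container", path)
  fm
}
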