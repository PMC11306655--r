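#' Load a grayscale image from disk
#'
#' Reads a PNG or TIFF raster and returns an `image_record` with intensities
#' in \[0, 1\] (8- or 16-bit codes are mapped to \[0, 1\] by the decoder's
#' native bit-depth scaling; no min-max renormalization is applied, so an
#' 8-bit code of 255 maps to exactly 1.0). Multi-channel images are reduced
#' to luminance; an alpha channel is ignored. A zero-dynamic-range (constant)
#' image is returned as-is with a warning.
#'
#' @param path Path to a PNG or TIFF file.
#' @param id Id recorded on the result; defaults to the file name.
#' @return An `image_record` with `source = "file"` and `label = NA`.
#' @export
load_image <- function(path, id = basename(path)) {
  if (!file.exists(path)) stop_io("cannot read image: '%s' does not exist", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop_io("failed to decode '%s': %s",
                                              path, conditionMessage(e)))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    nch <- dim(dat)[3]
    if (nch >= 3L) {
      # Rec.709 luminance; alpha (4th channel) dropped
      dat <- 0.2126 * dat[, , 1] + 0.7152 * dat[, , 2] + 0.0722 * dat[, , 3]
    } else {
      dat <- dat[, , 1]
    }
  }
  dat <- t(dat)  # EBImage is (x, y); records use rows = image rows
  dat[dat < 0] <- 0
  dat[dat > 1] <- 1
  if (max(dat) == min(dat))
    warning(sprintf("image '%s' has zero dynamic range (constant value %.4g)",
                    path, dat[1]), call. = FALSE)
  image_record(id = id, pixels = dat, label = NA_integer_, source = "file")
}

#' Resize an image to a square grid
#'
#' Bilinear resize to `side` x `side` pixels (default 224, the network input
#' grid). An image already at the target size is returned unchanged, bit for
#' bit. Interpolated intensities are clipped back to \[0, 1\].
#'
#' @param img An `image_record`.
#' @param side Target side in pixels; must be at least 16.
#' @return The resized `image_record`.
#' @export
resize_image <- function(img, side = 224L) {
  stopifnot(inherits(img, "image_record"))
  if (!is_count(side, 16L))
    stop_validation("resize side must be an integer >= 16, got %s", side)
  side <- as.integer(side)
  if (nrow(img$pixels) == side && ncol(img$pixels) == side) return(img)
  out <- EBImage::imageData(
    EBImage::resize(EBImage::Image(t(img$pixels)), w = side, h = side,
                    filter = "bilinear"))
  out <- t(out)
  out[out < 0] <- 0
  out[out > 1] <- 1
  img$pixels <- out
  img
}

#' Tile an image into fixed-size square patches
#'
#' Splits a square image into non-overlapping `patch_side` x `patch_side`
#' pixel patches in row-major order: patch index `p = r * grid_cols + c`
#' (0-based) covers pixel rows `[patch_side*r, patch_side*(r+1))` and columns
#' `[patch_side*c, patch_side*(c+1))`, half-open. A 224 x 224 image with the
#' default patch side yields a 14 x 14 grid of 196 patches.
#'
#' @param img An `image_record` whose side is divisible by `patch_side`.
#' @param patch_side Patch side in pixels (default 16).
#' @return A `patch_set`: list with `source_id`, `patches` (list of matrices,
#'   row-major order), `grid_rows`, `grid_cols`, `patch_side`,
#'   `ordering = "row-major"`.
#' @export
tile_patches <- function(img, patch_side = 16L) {
  stopifnot(inherits(img, "image_record"))
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (!is_count(patch_side, 1L))
    stop_validation("patch_side must be a positive integer, got %s", patch_side)
  patch_side <- as.integer(patch_side)
  if (nr %% patch_side != 0L || nc %% patch_side != 0L)
    stop_validation("image size %d x %d is not divisible by patch side %d",
                    nr, nc, patch_side)
  gr <- nr %/% patch_side; gc <- nc %/% patch_side
  patches <- vector("list", gr * gc)
  for (r in seq_len(gr) - 1L) {
    rows <- (r * patch_side + 1L):((r + 1L) * patch_side)
    for (c in seq_len(gc) - 1L) {
      cols <- (c * patch_side + 1L):((c + 1L) * patch_side)
      patches[[r * gc + c + 1L]] <- img$pixels[rows, cols]
    }
  }
  structure(list(source_id = img$id, patches = patches, grid_rows = gr,
                 grid_cols = gc, patch_side = patch_side,
                 ordering = "row-major"),
            class = "patch_set")
}

#' Reassemble a patch set into the source image
#'
#' Inverse of [tile_patches()]: places the row-major patches back on the grid
#' and returns the pixel matrix. Round-tripping any valid image through
#' tile/reassemble is exactly the identity.
#'
#' @param ps A `patch_set`.
#' @return The reassembled pixel matrix.
#' @export
reassemble_patches <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  side <- ps$patch_side
  out <- matrix(NA_real_, ps$grid_rows * side, ps$grid_cols * side)
  for (r in seq_len(ps$grid_rows) - 1L) {
    rows <- (r * side + 1L):((r + 1L) * side)
    for (c in seq_len(ps$grid_cols) - 1L) {
      cols <- (c * side + 1L):((c + 1L) * side)
      out[rows, cols] <- ps$patches[[r * ps$grid_cols + c + 1L]]
    }
  }
  out
}
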