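write_png <- function(pixels, name) {
  path <- file.path(tempdir(), name)
  EBImage::writeImage(EBImage::Image(t(pixels)), path, type = "png", bits = 8L)
  path
}

test_that("load_image maps 8-bit codes to [0,1] without renormalizing", {
  px <- matrix(0, 8, 8)
  px[3, 5] <- 1          # code 255
  px[1, 1] <- 128 / 255  # mid gray stays mid gray
  rec <- load_image(write_png(px, "codes.png"))
  expect_equal(rec$pixels[3, 5], 1.0)
  expect_equal(rec$pixels[1, 1], 128 / 255, tolerance = 1e-12)
  expect_equal(rec$pixels[2, 2], 0)
  expect_identical(rec$source, "file")
})

test_that("constant images load unchanged with a warning", {
  px <- matrix(128 / 255, 6, 6)
  expect_warning(rec <- load_image(write_png(px, "flat.png")),
                 "zero dynamic range")
  expect_true(all(rec$pixels == rec$pixels[1, 1]))
})

test_that("RGB images reduce to luminance; black stays black", {
  path <- file.path(tempdir(), "rgb0.png")
  EBImage::writeImage(EBImage::Image(array(0, c(5, 5, 3)), colormode = "Color"),
                      path, type = "png", bits = 8L)
  expect_warning(rec <- load_image(path), "zero dynamic range")
  expect_true(all(rec$pixels == 0))
})

test_that("missing or unreadable files raise I/O errors with the path", {
  expect_error(load_image("/nonexistent/img.png"), "nonexistent",
               class = "pdfe_io_error")
  bad <- file.path(tempdir(), "broken.png")
  writeLines("not a png", bad)
  expect_error(load_image(bad), "broken.png", class = "pdfe_io_error")
})

test_that("resize is identity at the target size and preserves constants", {
  set.seed(1)
  px <- matrix(runif(224 * 224), 224, 224)
  rec <- image_record("a", px)
  expect_identical(resize_image(rec, 224L)$pixels, px)
  cst <- resize_image(image_record("c", matrix(0.5, 448, 448)), 224L)
  expect_true(all(cst$pixels == 0.5))
  expect_equal(dim(cst$pixels), c(224L, 224L))
  expect_error(resize_image(rec, 8L), class = "pdfe_validation_error")
})

test_that("bilinear upsampling preserves the image mean", {
  set.seed(2)
  px <- matrix(runif(112 * 112), 112, 112)
  out <- resize_image(image_record("m", px), 224L)
  expect_equal(dim(out$pixels), c(224L, 224L))
  expect_lt(abs(mean(out$pixels) - mean(px)), 1e-3)
  # a monotone horizontal ramp stays monotone along rows after resizing
  ramp <- matrix(rep(seq(0, 1, length.out = 112), each = 112), 112, 112)
  rout <- resize_image(image_record("r", ramp), 224L)$pixels
  expect_true(all(diff(rout[112, ]) >= -1e-9))
})

test_that("tiling follows the row-major 0-based half-open convention", {
  set.seed(3)
  px <- matrix(runif(224 * 224), 224, 224)
  ps <- tile_patches(image_record("t", px), 16L)
  expect_equal(length(ps$patches), 196L)
  expect_equal(c(ps$grid_rows, ps$grid_cols), c(14L, 14L))
  expect_identical(ps$ordering, "row-major")
  expect_identical(ps$patches[[1]], px[1:16, 1:16])
  # patch index p = r*grid_cols + c: p = 17 (0-based 16) is r=1, c=2 (0-based)
  expect_identical(ps$patches[[1 * 14 + 2 + 1]], px[17:32, 33:48])
})

test_that("tile/reassemble round trip is the identity for any valid image", {
  set.seed(4)
  for (case in list(c(64, 16), c(48, 8), c(224, 28))) {
    px <- matrix(runif(case[1]^2), case[1], case[1])
    ps <- tile_patches(image_record("x", px), case[2])
    expect_identical(reassemble_patches(ps), px)
    expect_equal(length(ps$patches), (case[1] / case[2])^2)
  }
  expect_error(tile_patches(image_record("y", matrix(0.1, 50, 50)), 16L),
               "50 x 50", class = "pdfe_validation_error")
})
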