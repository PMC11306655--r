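test_that("phantom generation is a pure function of (label, seed, config)", {
  cfg <- small_synth()
  a <- generate_image(0L, seed = 7L, config = cfg)
  b <- generate_image(0L, seed = 7L, config = cfg)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels,
                         generate_image(0L, seed = 8L, config = cfg)$pixels))
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(lapply(ds1$records, `[[`, "pixels"),
                   lapply(ds2$records, `[[`, "pixels"))
})

test_that("written datasets are byte-identical across runs and load back", {
  cfg <- small_synth(n0 = 2L, n1 = 2L)
  d1 <- file.path(tempdir(), "synth_a"); d2 <- file.path(tempdir(), "synth_b")
  ds1 <- generate_dataset(cfg, d1)
  ds2 <- generate_dataset(cfg, d2)
  expect_equal(nrow(ds1$manifest), 4L)
  f1 <- file.path(d1, ds1$manifest$path)
  f2 <- file.path(d2, ds2$manifest$path)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  recs <- load_manifest(ds1$manifest_path)
  expect_length(recs, 4L)
  # PNG round trip loses only the 8-bit quantization
  q <- round(ds1$records[[1]]$pixels * 255) / 255
  expect_equal(recs[[1]]$pixels, q, tolerance = 1e-12)
  expect_identical(vapply(recs, `[[`, integer(1), "label"), ds1$manifest$label)
})

test_that("default class sizes give a 324-image manifest with both labels", {
  cfg <- synth_config()
  expect_equal(cfg$n_class0, 159L)
  expect_equal(cfg$n_class1, 165L)
  ds <- generate_dataset(small_synth(n0 = 159L, n1 = 165L))
  expect_equal(nrow(ds$manifest), 324L)
  expect_equal(as.integer(table(ds$manifest$label)), c(159L, 165L))
  tiny <- generate_dataset(small_synth(n0 = 1L, n1 = 1L))
  expect_equal(nrow(tiny$manifest), 2L)
  expect_setequal(tiny$manifest$label, c(0L, 1L))
})

test_that("effect_size 0 makes the class pixel distributions identical", {
  cfg <- small_synth(effect = 0)
  n_draw <- 120L
  m0 <- m1 <- matrix(0, cfg$image_size, cfg$image_size)
  for (s in seq_len(n_draw)) {
    m0 <- m0 + generate_image(0L, seed = 100L + s, config = cfg)$pixels
    m1 <- m1 + generate_image(1L, seed = 900L + s, config = cfg)$pixels
  }
  # Monte-Carlo error of a per-pixel mean difference: sd ~ noise_sd*sqrt(2/n);
  # allow a generous multiple for the maximum over all pixels
  tol <- 6 * cfg$noise_sd * sqrt(2 / n_draw)
  expect_lt(max(abs(m0 - m1)) / n_draw, tol)
})

test_that("noiseless phantom has the analytic template intensities", {
  cfg <- small_synth(noise = 0, effect = 1)
  img <- generate_image(0L, seed = 5L, config = cfg)$pixels
  vals <- sort(unique(as.vector(img)))
  # background, brain, brain + lesion_contrast, skull and nothing else
  expect_length(vals, 4L)
  lesion_val <- 0.45 + cfg$lesion_contrast
  expect_true(lesion_val %in% vals)
  # lesion pixels exceed the surrounding parenchyma by exactly the contrast
  lesion_px <- sum(img == lesion_val)
  expect_gt(lesion_px, pi * (cfg$lesion_radius_class0 - 1)^2)
  expect_lt(lesion_px, pi * (cfg$lesion_radius_class0 + 1)^2)
  # small-lesion class: same template, smaller disk
  img1 <- generate_image(1L, seed = 5L, config = cfg)$pixels
  expect_lt(sum(img1 == lesion_val), lesion_px)
})

test_that("invalid configurations name the offending field", {
  expect_error(synth_config(n_class0 = 0), "n_class0",
               class = "pdfe_validation_error")
  expect_error(synth_config(image_size = 16), "image_size",
               class = "pdfe_validation_error")
  expect_error(synth_config(lesion_radius_class0 = 200),
               "lesion_radius_class0", class = "pdfe_validation_error")
  expect_error(synth_config(effect_size = -1), "effect_size",
               class = "pdfe_validation_error")
  expect_error(generate_image(2L, 1L, small_synth()), "label",
               class = "pdfe_validation_error")
  expect_error(generate_dataset(small_synth(), "/proc/nope/dir"),
               class = "pdfe_io_error")
})
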