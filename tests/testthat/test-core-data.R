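# Core containers, image/mask I/O, color conversion, and tiling.

test_that("rgb_image validates shape, channels, and range", {
  img <- rgb_image(array(128, dim = c(4, 5, 3)))
  expect_s3_class(img, "rgb_image")
  expect_identical(dim(img), c(4L, 5L, 3L))
  expect_type(unclass(img), "integer")

  expect_error(rgb_image(matrix(0, 4, 4)), class = "bagseg_channel_error")
  err <- expect_error(rgb_image(array(0, dim = c(4, 4, 4))),
                      class = "bagseg_channel_error")
  expect_match(conditionMessage(err), "4")
  expect_error(rgb_image(array(-1, dim = c(4, 4, 3))),
               class = "bagseg_range_error")
  expect_error(rgb_image(array(256, dim = c(4, 4, 3))),
               class = "bagseg_range_error")
})

test_that("label_mask validates labels against num_classes", {
  m <- label_mask(matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_identical(num_classes(m), 2L)
  expect_error(label_mask(matrix(2L, 2, 2), num_classes = 2L),
               class = "bagseg_range_error")
  expect_error(label_mask(matrix(-1L, 2, 2)), class = "bagseg_range_error")
  expect_error(label_mask(array(0L, dim = c(2, 2, 1))),
               class = "bagseg_shape_error")
  expect_identical(num_classes(label_mask(matrix(0:3, 2, 2), 4L)), 4L)
})

test_that("PNG image round trip is bit-exact", {
  path <- withr::local_tempfile(fileext = ".png")
  img <- with_seed(1L, rgb_image(array(sample(0:255, 5 * 7 * 3, TRUE),
                                       dim = c(5, 7, 3))))
  save_rgb(img, path)
  expect_identical(unclass(load_rgb(path)), unclass(img))
})

test_that("load_rgb rejects non-3-channel files and bad paths", {
  gray <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), gray)
  err <- expect_error(load_rgb(gray), class = "bagseg_channel_error")
  expect_match(conditionMessage(err), "1 channel")

  rgba <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(0.5, dim = c(4, 4, 4)), rgba)
  err <- expect_error(load_rgb(rgba), class = "bagseg_channel_error")
  expect_match(conditionMessage(err), "4 channel")

  expect_error(load_rgb(file.path(tempdir(), "missing.png")),
               class = "bagseg_io_error")
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", txt)
  expect_error(load_rgb(txt), class = "bagseg_io_error")
})

test_that("JPEG decoding via EBImage yields a 3-channel image", {
  skip_if_not_installed("EBImage")
  path <- withr::local_tempfile(fileext = ".jpg")
  img <- flat_image(200, 100, 50, 16, 16)
  EBImage::writeImage(EBImage::Image(aperm(unclass(img) / 255, c(2, 1, 3)),
                                     colormode = "Color"), path, quality = 95)
  back <- load_rgb(path)
  expect_identical(dim(back), c(16L, 16L, 3L))
  # lossy codec: channels near the originals, not exact
  expect_lt(max(abs(unclass(back) - unclass(img))), 12)
})

test_that("mask PNG round trip is bit-exact and rejects labels >= 256", {
  path <- withr::local_tempfile(fileext = ".png")
  m <- label_mask(matrix(c(0L, 1L, 1L, 0L, 1L, 0L), 2, 3))
  save_mask(m, path)
  back <- load_mask(path)
  expect_identical(unclass(back), unclass(m))
  expect_identical(num_classes(back), 2L)

  m255 <- label_mask(matrix(c(0L, 255L), 1, 2), num_classes = 256L)
  save_mask(m255, path)
  expect_identical(as.integer(load_mask(path)), c(0L, 255L))

  expect_error(save_mask(label_mask(matrix(c(0L, 256L), 1, 2), 257L), path),
               class = "bagseg_encoding_error")
})

test_that("rgb_to_hsv matches known colors and inverts", {
  expect_equal(rgb_to_hsv(flat_image(255, 0, 0, 1, 1))[1, 1, ], c(0, 1, 1))
  expect_equal(rgb_to_hsv(flat_image(0, 255, 0, 1, 1))[1, 1, ], c(120, 1, 1))
  expect_equal(rgb_to_hsv(flat_image(0, 0, 255, 1, 1))[1, 1, ], c(240, 1, 1))
  gray <- rgb_to_hsv(flat_image(77, 77, 77, 1, 1))[1, 1, ]
  expect_equal(gray[1], 0)  # achromatic hue convention
  expect_equal(gray[2], 0)
  # hue stays in [0, 360)
  img <- with_seed(2L, rgb_image(array(sample(0:255, 300, TRUE), c(10, 10, 3))))
  h <- rgb_to_hsv(img)[, , 1]
  expect_true(all(h >= 0 & h < 360))
})

test_that("rgb_to_hsv round-trips through the base hsv converter", {
  img <- with_seed(3L, rgb_image(array(sample(0:255, 60, TRUE), c(4, 5, 3))))
  hsv <- rgb_to_hsv(img)
  back <- grDevices::col2rgb(grDevices::hsv(hsv[, , 1] / 360,
                                            hsv[, , 2], hsv[, , 3]))
  expect_equal(back[1, ], as.numeric(img[, , 1]), tolerance = 1e-8)
  expect_equal(back[2, ], as.numeric(img[, , 2]), tolerance = 1e-8)
  expect_equal(back[3, ], as.numeric(img[, , 3]), tolerance = 1e-8)
})

test_that("crop_to_patches lays the documented top-left grid", {
  img <- flat_image(10, 20, 30, 600, 300)
  msk <- label_mask(matrix(0L, 600, 300))
  tiles <- crop_to_patches(img, msk, 256, source_id = "s1")
  expect_length(tiles, 2)  # floor(600/256) * floor(300/256) = 2 * 1
  expect_identical(tiles[[1]]$grid_pos, c(0L, 0L))
  expect_identical(tiles[[2]]$grid_pos, c(1L, 0L))
  expect_identical(dim(tiles[[1]]$image), c(256L, 256L, 3L))
  expect_identical(tiles[[1]]$source_id, "s1")
})

test_that("tiles reassemble the cropped region exactly", {
  scene <- generate_field(field_scenario(seed = 7L), 40, 72)
  tiles <- crop_to_patches(scene$image, scene$mask, 16)
  expect_length(tiles, 2 * 4)
  recon <- array(NA_integer_, dim = c(32, 64, 3))
  for (tl in tiles) {
    rs <- tl$grid_pos[1] * 16 + 1:16
    cs <- tl$grid_pos[2] * 16 + 1:16
    recon[rs, cs, ] <- unclass(tl$image)
  }
  expect_identical(recon, unclass(scene$image)[1:32, 1:64, ])
})

test_that("patch counts follow floor arithmetic for random shapes", {
  set.seed(11)
  for (i in 1:10) {
    h <- sample(16:50, 1); w <- sample(16:50, 1); p <- sample(c(8L, 16L), 1)
    if (h < p || w < p) next
    img <- flat_image(1, 2, 3, h, w)
    msk <- label_mask(matrix(0L, h, w))
    expect_length(crop_to_patches(img, msk, p), (h %/% p) * (w %/% p))
  }
  expect_error(crop_to_patches(flat_image(0, 0, 0, 8, 8),
                               label_mask(matrix(0L, 8, 8)), 16),
               class = "bagseg_size_error")
  expect_error(crop_to_patches(flat_image(0, 0, 0, 16, 16),
                               label_mask(matrix(0L, 8, 8)), 8),
               class = "bagseg_shape_error")
})

test_that("patch_pair enforces matching dims", {
  expect_error(patch_pair(flat_image(0, 0, 0, 4, 4),
                          label_mask(matrix(0L, 4, 5))),
               class = "bagseg_shape_error")
})

test_that("manifest round trip preserves splits and exclusions", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- tibble::tibble(image = c("a.png", "b.png"), mask = c("am.png", "bm.png"),
                      split = c("train", "test"), excluded = c(FALSE, TRUE))
  write_manifest(m, path)
  back <- read_manifest(path)
  expect_identical(back$image, m$image)
  expect_identical(back$split, m$split)
  expect_identical(back$excluded, m$excluded)
  expect_error(read_manifest(file.path(tempdir(), "none.csv")),
               class = "bagseg_io_error")
})

test_that("print methods describe the containers", {
  expect_output(print(flat_image(0, 0, 0, 3, 4)), "rgb_image 3 x 4")
  expect_output(print(label_mask(matrix(0L, 2, 2))), "label_mask 2 x 2")
})
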