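# GLCM texture features and the random-forest pixel classifier.

test_that("quantize_gray maps [0, 255] onto 0..levels-1", {
  g <- matrix(c(0, 31.9, 32, 128, 255), 1)
  q <- quantize_gray(g, 8L)
  expect_identical(as.integer(q), c(0L, 0L, 1L, 4L, 7L))
  expect_true(all(quantize_gray(matrix(0:255, 16), 8L) <= 7L))
})

test_that("extract_window crops interiors and replicates borders", {
  m <- matrix(1:64, 8, 8)
  expect_identical(extract_window(m, 4, 4, 3), m[3:5, 3:5])
  # corner: indices clamp to the nearest edge
  w <- extract_window(m, 1, 1, 7)
  rows <- pmin(pmax((1 - 3):(1 + 3), 1), 8)
  expect_identical(w, m[rows, rows])
  expect_identical(dim(w), c(7L, 7L))
  # constant image stays constant
  expect_true(all(extract_window(matrix(5, 8, 8), 1, 8, 7) == 5))
  expect_error(extract_window(m, 4, 4, 4), class = "bagseg_parameter_error")
  expect_error(extract_window(m, 0, 4, 3), class = "bagseg_range_error")
})

test_that("compute_glcm counts, symmetrizes, and normalizes pairs", {
  const <- matrix(3L, 4, 4)
  g <- compute_glcm(const, 8L)
  expect_equal(sum(g), 1)
  expect_equal(g[4, 4], 1)

  alt <- matrix(c(0L, 1L, 0L, 1L), 1, 4)
  g2 <- compute_glcm(alt, 2L, list(c(0L, 1L)))
  expect_equal(g2[1, 2], 0.5)
  expect_equal(g2[2, 1], 0.5)
  expect_equal(g2[1, 1] + g2[2, 2], 0)

  expect_error(compute_glcm(matrix(9L, 3, 3), 8L), class = "bagseg_range_error")
  expect_error(compute_glcm(matrix(0L, 2, 2), 8L, list(c(0L, 5L))),
               class = "bagseg_normalization_error")
  expect_error(compute_glcm(matrix(0L, 2, 2), 8L, list()),
               class = "bagseg_parameter_error")
})

test_that("glcm_stats matches hand values on pinned matrices", {
  # constant window: a single diagonal cell
  s <- glcm_stats(compute_glcm(matrix(2L, 4, 4), 8L))
  expect_equal(unname(s), c(0, 0, 1, 1, 1))

  # perfectly alternating 2-level pattern
  s2 <- glcm_stats(compute_glcm(matrix(c(0L, 1L, 0L, 1L), 1, 4), 2L,
                                list(c(0L, 1L))))
  expect_equal(s2[["contrast"]], 1)
  expect_equal(s2[["dissimilarity"]], 1)
  expect_equal(s2[["homogeneity"]], 0.5)
  expect_equal(s2[["correlation"]], -1)
  expect_equal(s2[["asm"]], 0.5)

  expect_error(glcm_stats(matrix(1, 2, 2)), class = "bagseg_contract_error")
})

test_that("glcm_stats equals a double-loop oracle on random GLCMs", {
  set.seed(41)
  for (rep in 1:5) {
    L <- sample(3:8, 1)
    raw <- matrix(runif(L * L), L, L)
    raw <- raw + t(raw)
    p <- raw / sum(raw)
    s <- glcm_stats(p)
    contrast <- dissim <- homog <- asm <- 0
    mu_i <- mu_j <- 0
    for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
      pij <- p[i + 1, j + 1]
      contrast <- contrast + pij * (i - j)^2
      dissim <- dissim + pij * abs(i - j)
      homog <- homog + pij / (1 + (i - j)^2)
      asm <- asm + pij^2
      mu_i <- mu_i + pij * i
      mu_j <- mu_j + pij * j
    }
    v_i <- v_j <- cov_ij <- 0
    for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
      pij <- p[i + 1, j + 1]
      v_i <- v_i + pij * (i - mu_i)^2
      v_j <- v_j + pij * (j - mu_j)^2
      cov_ij <- cov_ij + pij * (i - mu_i) * (j - mu_j)
    }
    oracle <- c(contrast, dissim, homog, cov_ij / sqrt(v_i * v_j), asm)
    expect_equal(unname(s), oracle, tolerance = 1e-12)
    expect_lte(s[["homogeneity"]], 1)
    expect_lte(s[["asm"]], 1)
    expect_true(abs(s[["correlation"]]) <= 1 + 1e-12)
  }
})

test_that("featurize_pixel returns named RGB + texture features", {
  img <- flat_image(0, 255, 0, 9, 9)
  f <- featurize_pixel(img, 5, 5)
  expect_named(f, c("r", "g", "b", "contrast", "dissimilarity",
                    "homogeneity", "correlation", "asm"))
  # constant image: no texture, correlation degenerates to 1
  expect_equal(unname(f), c(0, 255, 0, 0, 0, 1, 1, 1))
  # border replication makes corner features equal interior ones here
  expect_equal(featurize_pixel(img, 1, 1), f)
})

test_that("the compiled batch featurizer equals the per-pixel path", {
  img <- generate_field(field_scenario(seed = 13L), 32, 32)$image
  batch <- featurize_image(img)
  expect_identical(dim(batch), c(32L * 32L, 8L))
  set.seed(17)
  picks <- rbind(c(1, 1), c(1, 32), c(32, 1), c(32, 32),
                 cbind(sample(32, 6), sample(32, 6)))
  for (i in seq_len(nrow(picks))) {
    r <- picks[i, 1]; c <- picks[i, 2]
    lin <- (c - 1) * 32 + r
    expect_equal(unname(batch[lin, ]),
                 unname(featurize_pixel(img, r, c)), tolerance = 1e-12)
  }
})

test_that("sample_training_pixels draws distinct, reproducible positions", {
  scenes <- generate_dataset(3, seed = 19L, height = 32, width = 32)
  rows <- sample_training_pixels(scenes, 50, seed = 4L)
  expect_identical(nrow(rows), 150L)
  expect_true(all(c("image_id", "row", "col", "label", "r", "asm") %in% names(rows)))
  for (i in 1:3) {
    sub <- rows[rows$image_id == i, ]
    expect_identical(anyDuplicated(paste(sub$row, sub$col)), 0L)
  }
  # labels agree with the mask at the sampled positions
  sub <- rows[rows$image_id == 2, ]
  expect_identical(sub$label,
                   unclass(scenes[[2]]$mask)[cbind(sub$row, sub$col)])
  again <- sample_training_pixels(scenes, 50, seed = 4L)
  expect_identical(rows, again)
  # positions-only fast path
  pos <- sample_training_pixels(scenes, 50, seed = 4L, features = FALSE)
  expect_identical(pos[c("image_id", "row", "col", "label")],
                   rows[c("image_id", "row", "col", "label")])
  expect_false("r" %in% names(pos))
  expect_error(sample_training_pixels(scenes, 32 * 32 + 1, seed = 1L),
               class = "bagseg_sampling_error")
  expect_error(sample_training_pixels(list(), 5), class = "bagseg_input_error")
})

test_that("train_rf rejects single-class training data", {
  scenes <- list(generate_field(field_scenario(plant_count = 0, weed_count = 0,
                                               seed = 1L), 32, 32))
  rows <- sample_training_pixels(scenes, 100, seed = 1L)
  expect_error(train_rf(rows, rf_config(n_trees = 5L)),
               class = "bagseg_degenerate_training_error")
  expect_error(train_rf(rows[, c("label", "r")], rf_config()),
               class = "bagseg_input_error")
})

test_that("the RF learns a color-separable scene almost perfectly", {
  scenes <- separable_dataset(3, seed = 23L, height = 32, width = 32)
  rows <- sample_training_pixels(scenes, 300, seed = 2L)
  rf <- train_rf(rows, rf_config(n_trees = 25L, max_depth = 12L, seed = 3L))
  test_scene <- separable_dataset(4, seed = 23L, height = 32, width = 32)[[4]]
  pred <- predict_patch_rf(rf, test_scene$image)
  expect_gt(miou(pred, test_scene$mask)$miou, 0.9)
})

test_that("predict_patch_rf classifies every pixel exactly once", {
  scenes <- separable_dataset(2, seed = 29L, height = 32, width = 32)
  rows <- sample_training_pixels(scenes, 200, seed = 2L)
  rf <- train_rf(rows, rf_config(n_trees = 10L, seed = 3L))
  mask <- predict_patch_rf(rf, scenes[[1]]$image)
  expect_identical(attr(mask, "n_classifications"), 32L * 32L)
  expect_identical(dim(mask), c(32L, 32L))
  expect_true(all(unclass(mask) %in% 0:1))
  expect_error(predict_patch_rf(list(), scenes[[1]]$image),
               class = "bagseg_state_error")
})

test_that("RF training is reproducible in the config seed", {
  scenes <- separable_dataset(2, seed = 37L, height = 32, width = 32)
  rows <- sample_training_pixels(scenes, 150, seed = 2L)
  m1 <- predict_patch_rf(train_rf(rows, rf_config(10L, seed = 7L)),
                         scenes[[1]]$image)
  m2 <- predict_patch_rf(train_rf(rows, rf_config(10L, seed = 7L)),
                         scenes[[1]]$image)
  expect_identical(unclass(m1), unclass(m2))
})

test_that("pixel_rf accessors report the fit", {
  scenes <- separable_dataset(2, seed = 43L, height = 32, width = 32)
  rows <- sample_training_pixels(scenes, 100, seed = 2L)
  rf <- train_rf(rows, rf_config(5L, seed = 1L))
  expect_output(print(rf), "5 trees")
  td <- tidy(rf)
  expect_setequal(td$feature, c("r", "g", "b", "contrast", "dissimilarity",
                                "homogeneity", "correlation", "asm"))
  g <- glance(rf)
  expect_identical(g$n_trees, 5L)
  expect_identical(g$n_training_pixels, 200L)
})
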